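# 32-bit values are carried as doubles (exact up to 2^53); these helpers keep
# hex formatting/parsing off base R's 32-bit signed-integer limits.

MAX32 <- 4294967295

#' Format a 32-bit value as a hex constant
#'
#' @param x numeric vector of non-negative integers below 2^32.
#' @return character vector like \code{"0xEDB88320"}.
#' @examples
#' hex32(3988292384)
#' @export
hex32 <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0), all(x <= MAX32), all(x == floor(x)))
  sprintf("0x%04X%04X", x %/% 65536, x %% 65536)
}

#' Parse hex constants into numeric 32-bit values
#'
#' @param s character vector of hex strings, with or without a \code{0x}
#'   prefix.
#' @return numeric vector.
#' @examples
#' parseHex32("0xEDB88320")
#' @export
parseHex32 <- function(s) {
  stopifnot(is.character(s))
  vapply(s, function(one) {
    one <- sub("^0[xX]", "", one)
    if (!nzchar(one) || grepl("[^0-9A-Fa-f]", one) || nchar(one) > 8)
      stop("not a 32-bit hex constant: '", one, "'")
    d <- match(strsplit(toupper(one), "")[[1]],
               c(as.character(0:9), LETTERS[1:6])) - 1
    sum(d * 16^(rev(seq_along(d)) - 1))
  }, numeric(1), USE.NAMES = FALSE)
}

# Coerce a polynomial given as numeric or hex string to a numeric 32-bit value.
as_u32 <- function(x, what = "value") {
  if (is.character(x)) x <- parseHex32(x)
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > MAX32 ||
      x != floor(x))
    stop(what, " must be an integer in [0, 2^32)")
  as.numeric(x)
}

# Evaluate expr under a temporary RNG state seeded with `seed` (NULL = use the
# current stream).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

check_k <- function(k, max = 16) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k > max ||
      k != floor(k))
    stop("k must be a single integer in 1..", max)
  as.integer(k)
}
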