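#' Random k-mer workload
#'
#' Uniform i.i.d. k-mers: every base drawn independently and uniformly from
#' \code{\{A, C, G, T\}}. Deterministic under \code{seed}.
#'
#' @param n number of k-mers.
#' @param k k-mer length in bases.
#' @param seed optional RNG seed.
#' @return character vector of \code{n} k-mers.
#' @examples
#' randomKmers(3, 8, seed = 1)
#' @export
randomKmers <- function(n, k, seed = NULL) {
  stopifnot(n >= 1)
  k <- check_k(k, max = 64)
  with_seed(seed, {
    digits <- sample.int(4L, n * k, replace = TRUE) - 1L
    cpp_digits_to_kmers(digits, as.integer(n), k)
  })
}

#' Similar (near-neighbor) k-mer workload
#'
#' A chain of near neighbors: the first element is uniform random and each
#' subsequent element is a single-base substitution of its predecessor
#' (Hamming distance 1 between consecutive elements). Duplicates may occur;
#' they are a property of the workload and are kept.
#'
#' @inheritParams randomKmers
#' @return character vector of \code{n} k-mers.
#' @examples
#' similarChain(4, 8, seed = 1)
#' @export
similarChain <- function(n, k, seed = NULL) {
  stopifnot(n >= 1)
  k <- check_k(k, max = 64)
  with_seed(seed, {
    first <- paste(c("A", "C", "G", "T")[sample.int(4L, k, replace = TRUE)],
                   collapse = "")
    if (n == 1) {
      first
    } else {
      pos <- 1L + as.integer(floor(stats::runif(n - 1) * k))
      alt <- sample.int(3L, n - 1, replace = TRUE)
      cpp_similar_chain(first, pos, alt)
    }
  })
}

#' Sliding-window k-mer workload from a FASTA file
#'
#' Step-1 overlapping windows taken record by record from the start of each
#' sequence (0-based position 0 onward); windows containing any non-ACGT
#' character are skipped, windows never span records, and the first \code{n}
#' admissible windows are returned.
#'
#' @param fasta path to a FASTA file (multi-record, wrapped or unwrapped,
#'   case-insensitive).
#' @param k window width in bases.
#' @param n number of windows wanted.
#' @return character vector of \code{n} k-mers (uppercase).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' syntheticGenome(fa, length = 2000, seed = 1)
#' windowKmers(fa, 16, 5)
#' @export
windowKmers <- function(fasta, k, n) {
  k <- check_k(k, max = 64)
  stopifnot(n >= 1)
  seqs <- Biostrings::readDNAStringSet(fasta)
  out <- character(0)
  for (i in seq_along(seqs)) {
    s <- toupper(as.character(seqs[[i]]))
    L <- nchar(s)
    if (L < k) next
    nw <- L - k + 1
    # windows covering any non-ACGT position are inadmissible
    chars <- charToRaw(s)
    bad <- !(chars %in% charToRaw("ACGT"))
    badcum <- c(0, cumsum(bad))
    ok <- (badcum[(1:nw) + k] - badcum[1:nw]) == 0
    starts <- which(ok)
    if (length(out) + length(starts) > n)
      starts <- starts[seq_len(n - length(out))]
    if (length(starts))
      out <- c(out, substring(s, starts, starts + k - 1))
    if (length(out) >= n) break
  }
  if (length(out) < n)
    stop("only ", length(out), " admissible windows available; ", n,
         " requested (short by ", n - length(out), ")")
  out
}

#' Write a synthetic single-record genome FASTA
#'
#' An i.i.d. synthetic genome standing in for a bacterial reference so that
#' sliding-window workloads need no download: bases are drawn independently
#' with P(G) + P(C) = \code{gc}, split evenly within the GC and AT pairs.
#' The defaults (4.6 Mb, GC 0.508) echo the \emph{E. coli} K-12 MG1655
#' chromosome. The FASTA header records the generating parameters; output
#' is wrapped at 70 columns and byte-identical under a fixed seed.
#'
#' @param path output FASTA path.
#' @param length genome length in bases.
#' @param gc GC fraction in \eqn{[0, 1]}.
#' @param seed optional RNG seed.
#' @return \code{path}, invisibly.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' syntheticGenome(fa, length = 500, gc = 0.5, seed = 7)
#' @export
syntheticGenome <- function(path, length = 4.6e6, gc = 0.508, seed = NULL) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  digits <- with_seed(seed, {
    sample.int(4L, length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)) - 1L
  })
  s <- paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
  x <- Biostrings::DNAStringSet(s)
  names(x) <- sprintf("synthetic_genome length=%d gc=%s seed=%s",
                      as.integer(length), format(gc),
                      if (is.null(seed)) "NA" else format(seed))
  Biostrings::writeXStringSet(x, path, width = 70)
  invisible(path)
}
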