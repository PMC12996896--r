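#' Parameters of one reflected CRC32 variant
#'
#' A reversed-form (LSB-first) 32-bit polynomial together with the register
#' initialization and final-XOR constants. The package convention — matching
#' the standard-library CRC32 most implementations expose — is
#' \code{init = xorOut = 0xFFFFFFFF}.
#'
#' @slot poly numeric; the reversed-form polynomial, nonzero, below 2^32.
#' @slot init numeric; register initialization constant.
#' @slot xorOut numeric; final XOR constant.
#' @export
setClass("CrcParams",
  representation(poly = "numeric", init = "numeric", xorOut = "numeric"),
  prototype(init = 4294967295, xorOut = 4294967295))

setValidity("CrcParams", function(object) {
  msgs <- character()
  for (nm in c("poly", "init", "xorOut")) {
    v <- slot(object, nm)
    if (length(v) != 1 || is.na(v) || v < 0 || v > MAX32 || v != floor(v))
      msgs <- c(msgs, paste0(nm, " must be a single integer in [0, 2^32)"))
  }
  if (length(msgs) == 0 && object@poly == 0)
    msgs <- c(msgs, "poly must be nonzero")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CrcParams Constructor; \code{poly}, \code{init} and
#'   \code{xorOut} accept numeric values or hex strings like
#'   \code{"0x8741C726"}.
#' @param poly,init,xorOut see slots.
#' @return a \code{CrcParams} object.
#' @examples
#' CrcParams("0xEDB88320")
#' @export
CrcParams <- function(poly, init = 0xFFFFFFFF, xorOut = 0xFFFFFFFF) {
  new("CrcParams", poly = as_u32(poly, "poly"), init = as_u32(init, "init"),
      xorOut = as_u32(xorOut, "xorOut"))
}

setClassUnion("CrcParamsOrNULL", c("CrcParams", "NULL"))

#' One benchmarked hashing configuration
#'
#' The unit of everything the evaluation battery measures: a preprocessing
#' mode (\code{"none"} hashes the uppercase ASCII k-mer bytes, \code{"gen32"}
#' hashes the nibble-packed bytes) combined with a 32-bit hash family.
#'
#' @slot preprocessing \code{"none"} or \code{"gen32"}.
#' @slot family \code{"crc32"}, \code{"murmur3_32"} or \code{"xxhash32"}.
#' @slot params \code{\link{CrcParams}} when family is \code{"crc32"},
#'   otherwise \code{NULL}.
#' @slot seed numeric; seed for the third-party families (ignored by CRC32).
#' @export
setClass("HashConfig",
  representation(preprocessing = "character", family = "character",
                 params = "CrcParamsOrNULL", seed = "numeric"),
  prototype(preprocessing = "gen32", family = "crc32", params = NULL,
            seed = 0))

setValidity("HashConfig", function(object) {
  msgs <- character()
  if (!identical(length(object@preprocessing), 1L) ||
      !object@preprocessing %in% c("none", "gen32"))
    msgs <- c(msgs, "preprocessing must be 'none' or 'gen32'")
  if (!identical(length(object@family), 1L) ||
      !object@family %in% c("crc32", "murmur3_32", "xxhash32"))
    msgs <- c(msgs, "family must be 'crc32', 'murmur3_32' or 'xxhash32'")
  else if (object@family == "crc32" && is.null(object@params))
    msgs <- c(msgs, "family 'crc32' requires params")
  else if (object@family != "crc32" && !is.null(object@params))
    msgs <- c(msgs, "params are only meaningful for family 'crc32'")
  if (length(object@seed) != 1 || is.na(object@seed) || object@seed < 0 ||
      object@seed > MAX32 || object@seed != floor(object@seed))
    msgs <- c(msgs, "seed must be a single integer in [0, 2^32)")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn HashConfig Constructor. \code{params} accepts a
#'   \code{CrcParams}, a polynomial as numeric/hex string, or \code{NULL}.
#' @param preprocessing,family,params,seed see slots.
#' @return a \code{HashConfig} object.
#' @examples
#' HashConfig("gen32", "crc32", "0x8741C726")
#' HashConfig("none", "murmur3_32")
#' @export
HashConfig <- function(preprocessing = c("gen32", "none"),
                       family = c("crc32", "murmur3_32", "xxhash32"),
                       params = NULL, seed = 0) {
  preprocessing <- match.arg(preprocessing)
  family <- match.arg(family)
  if (!is.null(params) && !is(params, "CrcParams"))
    params <- CrcParams(params)
  new("HashConfig", preprocessing = preprocessing, family = family,
      params = params, seed = as_u32(seed, "seed"))
}

#' Result of an exhaustive collision audit
#'
#' @slot configLabel identity string of the audited configuration.
#' @slot k k-mer length in bases.
#' @slot total number of inputs hashed (\eqn{4^k}).
#' @slot distinct count of distinct 32-bit hash values.
#' @slot collisions \code{total - distinct}.
#' @slot replicates audit repetitions performed.
#' @slot consistent TRUE iff all replicates returned the same count.
#' @slot backend \code{"sort"} or \code{"bitset"}.
#' @export
setClass("CollisionReport",
  representation(configLabel = "character", k = "integer", total = "numeric",
                 distinct = "numeric", collisions = "numeric",
                 replicates = "integer", consistent = "logical",
                 backend = "character"))

setValidity("CollisionReport", function(object) {
  msgs <- character()
  if (object@collisions < 0) msgs <- c(msgs, "collisions must be >= 0")
  if (object@distinct > min(object@total, 2^32))
    msgs <- c(msgs, "distinct exceeds min(total, 2^32)")
  if (object@total - object@distinct != object@collisions)
    msgs <- c(msgs, "collisions must equal total - distinct")
  if (length(msgs)) msgs else TRUE
})

#' Bucket-occupancy uniformity result for one bucket count
#'
#' @slot configLabel identity string of the hashing configuration.
#' @slot dataset workload regime: \code{"random"}, \code{"similar"},
#'   \code{"window"} or \code{"custom"}.
#' @slot m bucket count.
#' @slot counts occupancy vector of length \code{m}.
#' @slot chi2 Pearson chi-squared statistic against the uniform expectation.
#' @slot df degrees of freedom, \code{m - 1}.
#' @slot p upper-tail probability.
#' @export
setClass("UniformityReport",
  representation(configLabel = "character", dataset = "character",
                 m = "integer", counts = "numeric", chi2 = "numeric",
                 df = "integer", p = "numeric"))

setValidity("UniformityReport", function(object) {
  msgs <- character()
  if (object@df != object@m - 1L) msgs <- c(msgs, "df must equal m - 1")
  if (length(object@counts) != object@m)
    msgs <- c(msgs, "counts must have length m")
  if (is.na(object@p) || object@p < 0 || object@p > 1)
    msgs <- c(msgs, "p must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Avalanche (mean bit-flip) measurement result
#'
#' @slot configLabel identity string of the hashing configuration.
#' @slot nPairs number of origin-mutant pairs measured.
#' @slot b hash width in bits (32 for every in-scope family).
#' @slot meanFlip average flipped-bit fraction over all pairs.
#' @slot flipSD standard deviation of the per-pair flip fraction.
#' @slot seed RNG seed the mutants were drawn under (NA if none given).
#' @export
setClass("AvalancheReport",
  representation(configLabel = "character", nPairs = "numeric",
                 b = "integer", meanFlip = "numeric", flipSD = "numeric",
                 seed = "numeric"))

setValidity("AvalancheReport", function(object) {
  msgs <- character()
  if (is.na(object@meanFlip) || object@meanFlip < 0 || object@meanFlip > 1)
    msgs <- c(msgs, "meanFlip must be in [0, 1]")
  if (object@b != 32L) msgs <- c(msgs, "b must be 32 for in-scope families")
  if (length(msgs)) msgs else TRUE
})
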