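#' Encode nucleotides as 4-bit gen32 codes
#'
#' Masks each character's ASCII byte with \code{0x0E}, which isolates bits
#' 1-3 and yields identical codes for upper and lower case:
#' A/a \eqn{\to} 0x0, C/c \eqn{\to} 0x2, G/g \eqn{\to} 0x6, T/t \eqn{\to} 0x4.
#' The trick is only injective on the four nucleotides, so strict mode
#' (the default) rejects anything outside \code{ACGTacgt}.
#'
#' @param bases character vector of single characters.
#' @param strict reject non-ACGT characters (default); when \code{FALSE} the
#'   masked value is returned unchecked.
#' @return integer vector of 4-bit codes.
#' @examples
#' encodeNibble(c("A", "c", "G", "t"))
#' @export
encodeNibble <- function(bases, strict = TRUE) {
  cpp_encode_nibble(as.character(bases), isTRUE(strict))
}

#' Pack a DNA k-mer into gen32 bytes
#'
#' Converts a k-mer over \code{ACGT} (case-insensitive) into
#' \eqn{\lceil k/2 \rceil} bytes: each base becomes a 4-bit code (see
#' \code{\link{encodeNibble}}) and consecutive codes are packed two per byte
#' by shifting the byte left four bits and OR-ing in the new code. For odd
#' \eqn{k} the final lone code occupies the low nibble of the last byte.
#'
#' @param kmer a single k-mer string, \eqn{1 \le k \le 64}.
#' @param strict reject non-ACGT characters (default).
#' @return raw vector of \eqn{\lceil k/2 \rceil} bytes.
#' @examples
#' gen32Pack("ACGT")   # 02 64
#' gen32Pack("acgt")   # identical: case-insensitive by construction
#' @export
gen32Pack <- function(kmer, strict = TRUE) {
  stopifnot(is.character(kmer), length(kmer) == 1, !is.na(kmer))
  cpp_gen32_pack(kmer, isTRUE(strict))
}

#' Pack many same-length k-mers in one pass
#'
#' Vectorized counterpart of \code{\link{gen32Pack}}: column \code{i} of the
#' result holds the packed bytes of \code{kmers[i]}.
#'
#' @param kmers character vector of k-mers, all the same length.
#' @param strict reject non-ACGT characters (default).
#' @return raw matrix with \eqn{\lceil k/2 \rceil} rows and one column per
#'   k-mer.
#' @examples
#' gen32PackBatch(c("ACGT", "TTTT"))
#' @export
gen32PackBatch <- function(kmers, strict = TRUE) {
  stopifnot(is.character(kmers), !anyNA(kmers))
  cpp_gen32_pack_batch(kmers, isTRUE(strict))
}
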