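#' The complete k-mer space
#'
#' Descriptor of the exhaustive, lexicographically ordered (A<C<G<T) space of
#' all \eqn{4^k} k-mers; indices run over \eqn{[0, 4^k)}.
#'
#' @param k k-mer length in bases, 1..16.
#' @return a list with elements \code{k}, \code{total} (\eqn{4^k}) and
#'   \code{order}.
#' @examples
#' kmerSpace(8)$total  # 65536
#' @export
kmerSpace <- function(k) {
  k <- check_k(k)
  list(k = k, total = 4^k, order = "lexicographic A<C<G<T")
}

#' Convert between k-mer indices and sequences
#'
#' \code{indexToKmer} maps an index to the k-mer whose base-4 digits it
#' spells, most-significant base first, with A=0, C=1, G=2, T=3;
#' \code{kmerToIndex} is its inverse. Both are vectorized.
#'
#' @param idx numeric vector of indices in \eqn{[0, 4^k)}.
#' @param k k-mer length in bases, 1..16.
#' @param kmers character vector of k-mers (case-insensitive).
#' @return \code{indexToKmer}: character vector; \code{kmerToIndex}: numeric
#'   vector of indices.
#' @examples
#' indexToKmer(c(0, 255), 4)  # "AAAA" "TTTT"
#' kmerToIndex("ACGT")
#' @export
indexToKmer <- function(idx, k) {
  cpp_index_to_kmer(as.numeric(idx), check_k(k))
}

#' @rdname indexToKmer
#' @export
kmerToIndex <- function(kmers) {
  stopifnot(is.character(kmers), !anyNA(kmers))
  cpp_kmer_to_index(kmers)
}

#' Materialize every k-mer of a small space
#'
#' Convenience enumeration of all \eqn{4^k} k-mers as ASCII strings, in index
#' order. Guarded to \eqn{k \le 10} (1,048,576 strings); larger spaces should
#' go through \code{\link{enumeratePacked}} or the streaming audit.
#'
#' @param k k-mer length in bases, 1..10.
#' @return character vector of \eqn{4^k} k-mers.
#' @examples
#' enumerateKmers(2)
#' @export
enumerateKmers <- function(k) {
  k <- check_k(k, max = 10)
  cpp_enumerate_block(k, 0, 4^k, 0L)
}

#' Stream the complete k-mer space in bounded-memory chunks
#'
#' Returns an iterator over the full \eqn{4^k} enumeration: each call to the
#' returned function yields the next block — a raw matrix of gen32-packed
#' bytes (one column per k-mer) or a character vector of ASCII k-mers — and
#' \code{NULL} once the space is exhausted. Blocks concatenate to exactly the
#' unchunked enumeration regardless of the chunk size.
#'
#' @param k k-mer length in bases, 1..16.
#' @param chunkSize maximum k-mers per block (default \eqn{2^{22}}, keeping
#'   each packed block under 64 MB).
#' @param mode \code{"gen32"} for packed bytes or \code{"ascii"} for strings.
#' @return a function of no arguments; call repeatedly for successive blocks.
#' @examples
#' it <- enumeratePacked(3, chunkSize = 50)
#' b1 <- it(); b2 <- it()
#' ncol(b1) + ncol(b2)  # 64
#' @export
enumeratePacked <- function(k, chunkSize = 2^22, mode = c("gen32", "ascii")) {
  k <- check_k(k)
  mode <- match.arg(mode)
  stopifnot(chunkSize >= 1)
  total <- 4^k
  pos <- 0
  mcode <- if (mode == "ascii") 0L else 1L
  function() {
    if (pos >= total) return(NULL)
    hi <- min(pos + chunkSize, total)
    block <- cpp_enumerate_block(k, pos, hi, mcode)
    pos <<- hi
    block
  }
}
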