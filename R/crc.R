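#' Lookup table of a reflected CRC32 variant
#'
#' The 256-entry table used by the byte-at-a-time reflected CRC32: entry
#' \code{i} is the result of eight shift-reduce steps (right shift, XOR the
#' reversed polynomial when the dropped bit is set) applied to byte \code{i}.
#'
#' @param params a \code{\link{CrcParams}} object, or a polynomial accepted
#'   by \code{CrcParams()}.
#' @return numeric vector of 256 values in \eqn{[0, 2^{32})}.
#' @examples
#' hex32(crcTable("0xEDB88320")[2])  # entry for byte 0x01
#' @export
crcTable <- function(params) {
  if (!is(params, "CrcParams")) params <- CrcParams(params)
  cpp_crc_table(params@poly)
}

#' Reflected CRC32 of a byte or character message
#'
#' Table-driven reflected CRC32 parameterized by an arbitrary reversed-form
#' polynomial: the register starts at \code{init}, each byte indexes the
#' table on the low 8 bits of \code{register XOR byte} with a right-shift-8
#' update, and the final register is XORed with \code{xorOut}.
#'
#' @param data a raw vector (hashed as-is) or a character vector (each
#'   element hashed as its ASCII bytes, vectorized).
#' @param params a \code{\link{CrcParams}} object or a polynomial accepted
#'   by \code{CrcParams()}; defaults to the ubiquitous \code{0xEDB88320}.
#' @return numeric: one 32-bit value per message.
#' @examples
#' hex32(crc32("123456789"))                  # 0xCBF43926, the check value
#' hex32(crc32("123456789", "0x82F63B78"))    # 0xE3069283 (CRC-32C)
#' @export
crc32 <- function(data, params = CrcParams(0xEDB88320)) {
  if (!is(params, "CrcParams")) params <- CrcParams(params)
  if (is.raw(data))
    return(cpp_crc32_raw(data, params@poly, params@init, params@xorOut))
  stopifnot(is.character(data), !anyNA(data))
  vapply(data, function(s) cpp_crc32_raw(charToRaw(s), params@poly,
                                         params@init, params@xorOut),
         numeric(1), USE.NAMES = FALSE)
}

#' genCRC32: hash a DNA k-mer via gen32 packing + CRC32
#'
#' The composed scheme: \code{crc32(gen32Pack(kmer), params)}. Vectorized
#' over k-mers (which need not share a length).
#'
#' @param kmers character vector of k-mers over \code{ACGT}
#'   (case-insensitive).
#' @param params a \code{\link{CrcParams}} or polynomial; defaults to
#'   \code{0x8741C726}, one of the eight polynomials that are collision-free
#'   for every k-mer length up to 16.
#' @return numeric vector of 32-bit hash values.
#' @examples
#' genCrc32("ACGT")
#' genCrc32("acgt") == genCrc32("ACGT")
#' @export
genCrc32 <- function(kmers, params = CrcParams(0x8741C726)) {
  if (!is(params, "CrcParams")) params <- CrcParams(params)
  stopifnot(is.character(kmers), !anyNA(kmers))
  vapply(kmers, function(s) cpp_crc32_raw(cpp_gen32_pack(s, TRUE),
                                          params@poly, params@init,
                                          params@xorOut),
         numeric(1), USE.NAMES = FALSE)
}

#' Reference 32-bit MurmurHash3 / xxHash32 of a byte message
#'
#' Comparator hashes used by the evaluation battery, operating on raw bytes.
#'
#' @param data raw vector.
#' @param seed numeric 32-bit seed (default 0, the upstream library default).
#' @return numeric 32-bit value.
#' @examples
#' hex32(murmur3_32(charToRaw("hello")))  # 0x248BFA47
#' hex32(xxhash32(raw(0)))                # 0x02CC5D05
#' @export
murmur3_32 <- function(data, seed = 0) {
  stopifnot(is.raw(data))
  cpp_murmur3_raw(data, as_u32(seed, "seed"))
}

#' @rdname murmur3_32
#' @export
xxhash32 <- function(data, seed = 0) {
  stopifnot(is.raw(data))
  cpp_xxhash32_raw(data, as_u32(seed, "seed"))
}
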