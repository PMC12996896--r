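# Independent oracles and fixtures shared across tests. The CRC oracle below
# is a bit-at-a-time reflected CRC written in plain R (vectorized across
# messages), deliberately sharing no code with the package's table-driven
# C++ path.

# XOR of 32-bit values carried as doubles, via 16-bit halves.
xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
}

popcount32 <- function(x) {
  sum(as.integer(intToBits(x %/% 65536))) +
    sum(as.integer(intToBits(x %% 65536)))
}

# msgs: integer matrix (one row per message, one column per byte).
crcBitwiseOracle <- function(msgs, poly, init = 0xFFFFFFFF,
                             xorout = 0xFFFFFFFF) {
  reg <- rep(init, nrow(msgs))
  for (j in seq_len(ncol(msgs))) {
    reg <- xor32(reg, msgs[, j])
    for (b in 1:8) {
      odd <- reg %% 2 == 1
      reg <- reg %/% 2
      if (any(odd)) reg[odd] <- xor32(reg[odd], poly)
    }
  }
  xor32(reg, xorout)
}

# All 4^k ASCII k-mers built in plain R (lexicographic, A<C<G<T).
allKmersR <- function(k) {
  g <- do.call(expand.grid,
               c(rep(list(c("A", "C", "G", "T")), k),
                 list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
  # expand.grid varies the first factor fastest; reverse for MSB-first order
  do.call(paste0, rev(g))
}

GEN32_CFG <- function(poly) HashConfig("gen32", "crc32", poly)
RAW_CFG <- function(poly) HashConfig("none", "crc32", poly)
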