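test_that("crc tables agree with the bitwise shift-reduce definition", {
  t1 <- crcTable("0xEDB88320")
  expect_identical(t1[1], 0)                      # zero byte, zero register
  expect_identical(hex32(t1[2]), "0x77073096")
  for (poly in c(crcPolynomials()[["0x82F63B78"]],
                 crcPolynomials()[["0x8741C726"]])) {
    tab <- crcTable(CrcParams(poly))
    bytes <- matrix(0:255, ncol = 1)
    expect_identical(tab, crcBitwiseOracle(bytes, poly, init = 0, xorout = 0))
  }
})

test_that("canonical CRC32 check values reproduce", {
  expect_identical(hex32(crc32("123456789")), "0xCBF43926")
  expect_identical(hex32(crc32("123456789", "0x82F63B78")), "0xE3069283")
  # empty input: register passes through, init XOR xorout
  expect_identical(crc32(raw(0)), 0)
  expect_identical(crc32(raw(0), CrcParams(1, init = 0xABCD, xorOut = 0)),
                   0xABCD)
})

test_that("genCrc32 is the composition of packing and CRC32", {
  p <- CrcParams("0x8741C726")
  expect_identical(genCrc32("ACGT", p), crc32(as.raw(c(0x02, 0x64)), p))
  expect_identical(genCrc32("acgt", p), genCrc32("ACGT", p))
  set.seed(3)
  for (rep in 1:20) {
    km <- paste(sample(c("A", "C", "G", "T"), sample(1:16, 1),
                       replace = TRUE), collapse = "")
    expect_identical(genCrc32(km, p), crc32(gen32Pack(km), p))
  }
})

test_that("all 4-mers hash distinctly under gen32+CRC32(0x8741C726)", {
  h <- genCrc32(allKmersR(4), CrcParams("0x8741C726"))
  expect_length(unique(h), 256)
})

test_that("MurmurHash3-32 and xxHash32 reproduce reference vectors", {
  # frozen from the upstream reference implementations (seed 0)
  expect_identical(hex32(murmur3_32(raw(0))), "0x00000000")
  expect_identical(hex32(murmur3_32(charToRaw("a"))), "0x3C2569B2")
  expect_identical(hex32(murmur3_32(charToRaw("ACGT"))), "0x33B09BA2")
  expect_identical(hex32(murmur3_32(charToRaw("hello"))), "0x248BFA47")
  expect_identical(hex32(murmur3_32(charToRaw(strrep("ACGT", 4)))),
                   "0x49046C97")
  expect_identical(hex32(murmur3_32(as.raw(c(0x02, 0x64)))), "0x6185D7AC")
  expect_identical(hex32(xxhash32(raw(0))), "0x02CC5D05")
  expect_identical(hex32(xxhash32(charToRaw("a"))), "0x550D7456")
  expect_identical(hex32(xxhash32(charToRaw("ACGT"))), "0x23CF84DA")
  expect_identical(hex32(xxhash32(charToRaw("hello"))), "0xFB0077F9")
  expect_identical(hex32(xxhash32(charToRaw(strrep("ACGT", 4)))),
                   "0x6A00069B")
  expect_identical(hex32(xxhash32(as.raw(c(0x02, 0x64)))), "0x565F1176")
  expect_identical(
    hex32(xxhash32(charToRaw("Nobody inspects the spammish repetition"))),
    "0xE2293B2F")
  # seed changes the mapping
  expect_false(murmur3_32(charToRaw("ACGT"), seed = 1) ==
               murmur3_32(charToRaw("ACGT")))
  expect_false(xxhash32(charToRaw("ACGT"), seed = 1) ==
               xxhash32(charToRaw("ACGT")))
})

test_that("crc output XOR depends only on the input XOR-delta", {
  set.seed(17)
  p <- CrcParams("0x9D9947FD")
  for (rep in 1:25) {
    L <- sample(1:12, 1)
    x <- as.raw(sample(0:255, L, replace = TRUE))
    y <- as.raw(sample(0:255, L, replace = TRUE))
    z <- as.raw(sample(0:255, L, replace = TRUE))
    w <- as.raw(bitwXor(bitwXor(as.integer(x), as.integer(y)),
                        as.integer(z)))  # so x^y == z^w
    expect_identical(xor32(crc32(x, p), crc32(y, p)),
                     xor32(crc32(z, p), crc32(w, p)))
  }
})

test_that("invalid CRC parameters are rejected", {
  expect_error(CrcParams(0), "nonzero")
  expect_error(CrcParams(2^32), "32")
  expect_error(CrcParams(-1), "32")
  expect_error(parseHex32("0xGG"), "hex")
})
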