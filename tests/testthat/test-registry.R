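test_that("labels round-trip and are unique across the benchmark grid", {
  grid <- benchmarkGrid()
  expect_length(grid, 44)  # 20 polys x 2 preps + 2 families x 2 preps
  labels <- names(grid)
  expect_identical(anyDuplicated(labels), 0L)
  for (lab in labels)
    expect_identical(configLabel(parseConfigLabel(lab)), lab)
  # non-default registers are spelled out and recovered
  cfg <- HashConfig("gen32", "crc32", CrcParams("0x8741C726", init = 0,
                                                xorOut = 1))
  expect_identical(configLabel(parseConfigLabel(configLabel(cfg))),
                   configLabel(cfg))
  # third-party seeds are part of the identity
  m42 <- HashConfig("none", "murmur3_32", seed = 42)
  expect_match(configLabel(m42), "seed=42")
  expect_identical(hashSeed(parseConfigLabel(configLabel(m42))), 42)
})

test_that("invalid configurations are rejected", {
  expect_error(HashConfig("gen32", "crc32", NULL), "requires params")
  expect_error(new("HashConfig", preprocessing = "gen32",
                   family = "murmur3_32", params = CrcParams(1), seed = 0),
               "only meaningful")
  expect_error(parseConfigLabel("gen32+sha1:0x01"), "cannot parse")
})

test_that("raw mode hashes uppercase ASCII; gen32 mode hashes packed bytes", {
  polys <- c("0x8741C726", "0xEDB88320")
  set.seed(23)
  kmers <- replicate(10, paste(sample(c("A", "C", "G", "T"), 12,
                                      replace = TRUE), collapse = ""))
  for (poly in polys) {
    p <- CrcParams(poly)
    expect_identical(hashKmer(RAW_CFG(p), kmers), crc32(kmers, p))
    expect_identical(hashKmer(GEN32_CFG(p), kmers), genCrc32(kmers, p))
  }
  for (fam in c("murmur3_32", "xxhash32")) {
    fn <- if (fam == "murmur3_32") murmur3_32 else xxhash32
    raw_cfg <- HashConfig("none", fam)
    gen_cfg <- HashConfig("gen32", fam)
    expect_identical(hashKmer(raw_cfg, kmers),
                     vapply(kmers, function(s) fn(charToRaw(s)), numeric(1),
                            USE.NAMES = FALSE))
    expect_identical(hashKmer(gen_cfg, kmers),
                     vapply(kmers, function(s) fn(gen32Pack(s)), numeric(1),
                            USE.NAMES = FALSE))
  }
  # lowercase input is uppercased before raw hashing
  cfg <- HashConfig("none", "xxhash32")
  expect_identical(hashKmer(cfg, "acgt"), hashKmer(cfg, "ACGT"))
})

test_that("batch hashing preserves order and is deterministic", {
  cfg <- HashConfig("gen32", "crc32", "0x945D045D")
  kmers <- allKmersR(5)[sample(1:1024, 200)]
  h <- hashBatch(cfg, kmers)
  expect_identical(hashBatch(cfg, kmers[1]), h[1])
  perm <- sample(seq_along(kmers))
  expect_identical(hashBatch(cfg, kmers[perm]), h[perm])
  for (r in 1:10) expect_identical(hashBatch(cfg, kmers), h)
  expect_error(hashBatch(cfg, c("ACGT", "ACGTA")), "mixed lengths")
  expect_identical(hashBatch(cfg, character(0)), numeric(0))
})
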