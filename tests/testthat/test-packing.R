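test_that("nibble codes come from ASCII masking and ignore case", {
  expect_identical(encodeNibble(c("A", "C", "G", "T")),
                   c(0x00L, 0x02L, 0x06L, 0x04L))
  expect_identical(encodeNibble(c("a", "c", "g", "t")),
                   encodeNibble(c("A", "C", "G", "T")))
  expect_error(encodeNibble("N"), "invalid base")
  # permissive mode returns the masked byte unchecked
  expect_identical(encodeNibble("N", strict = FALSE),
                   bitwAnd(utf8ToInt("N"), 0x0E))
})

test_that("gen32 packing matches the hand-traced byte layout", {
  expect_identical(gen32Pack("AC"), as.raw(0x02))
  expect_identical(gen32Pack("ACGT"), as.raw(c(0x02, 0x64)))
  expect_identical(gen32Pack("acgt"), gen32Pack("ACGT"))
  expect_length(gen32Pack(strrep("ACGT", 4)), 8)  # 16-mer -> 8 bytes
  expect_error(gen32Pack(""), "empty")
  expect_error(gen32Pack("ACGN"), "position 4")
})

test_that("packed size is ceiling(k/2) and odd k leaves a zero high nibble", {
  for (k in 1:16) {
    km <- substr(strrep("TGCA", 8), 1, k)
    p <- gen32Pack(km)
    expect_length(p, ceiling(k / 2))
    if (k %% 2 == 1) expect_lt(as.integer(p[length(p)]), 0x10)
  }
})

test_that("even-k packed bytes hold two codes from {0,2,4,6} per byte", {
  set.seed(11)
  for (rep in 1:20) {
    k <- 2 * sample(1:8, 1)
    km <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                collapse = "")
    b <- as.integer(gen32Pack(km))
    expect_true(all(b %/% 16 %in% c(0, 2, 4, 6)))
    expect_true(all(b %% 16 %in% c(0, 2, 4, 6)))
  }
})

test_that("packing is injective on complete spaces up to k = 8", {
  for (k in c(4, 6, 8)) {
    kmers <- allKmersR(k)
    packed <- gen32PackBatch(kmers)
    keys <- apply(packed, 2, paste, collapse = "")
    expect_identical(anyDuplicated(keys), 0L)
    expect_length(keys, 4^k)
  }
})

test_that("case folding never changes the packed bytes", {
  set.seed(5)
  for (rep in 1:50) {
    k <- sample(1:16, 1)
    up <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                collapse = "")
    mixed <- chartr("ACGT", "acgt", up)
    expect_identical(gen32Pack(mixed), gen32Pack(up))
  }
})

test_that("batch packing equals elementwise packing", {
  set.seed(7)
  kmers <- replicate(25, paste(sample(c("A", "C", "G", "T"), 10,
                                      replace = TRUE), collapse = ""))
  batch <- gen32PackBatch(kmers)
  for (i in seq_along(kmers))
    expect_identical(batch[, i], gen32Pack(kmers[i]))
  expect_error(gen32PackBatch(c("ACGT", "ACGTA")), "mixed lengths")
})
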