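test_that("bucket counts implement h mod m and sum to n", {
  expect_identical(bucketCounts(c(0, 1, 2, 3), 2), c(2, 2))
  expect_identical(bucketCounts(c(7, 7, 7), 1), 3)
  set.seed(2)
  h <- floor(runif(500) * 2^32)
  counts <- bucketCounts(h, 67)
  expect_identical(sum(counts), 500)
  expect_identical(bucketCounts(sample(h), 67), counts)
  # pre-reducing the hashes changes nothing
  expect_identical(bucketCounts(h %% 67, 67), counts)
  expect_error(bucketCounts(h, 0), "m")
})

test_that("chi-squared statistic and p value match the hand formula", {
  perfect <- chi2Uniformity(c(8, 8))
  expect_identical(perfect$chi2, 0)
  expect_identical(perfect$p, 1)
  fit <- chi2Uniformity(c(10, 6))
  expect_equal(fit$chi2, 1.0)
  expect_identical(fit$df, 1L)
  expect_equal(fit$p, 0.3173, tolerance = 1e-3)
  fit2 <- chi2Uniformity(c(12, 4))
  expect_equal(fit2$chi2, 4.0)
  expect_equal(fit2$p, 0.0455, tolerance = 1e-2)
  expect_error(chi2Uniformity(c(3, 3)), "above 5")
  expect_error(chi2Uniformity(10), "2 buckets")
})

test_that("the panel suppresses bucketings with expected counts <= 5", {
  cfg <- GEN32_CFG("0x8741C726")
  kmers <- randomKmers(400, 12, seed = 4)
  pan <- uniformityPanel(cfg, kmers, mPanel = c(64, 67, 256, 4096),
                         dataset = "random")
  ms <- vapply(pan$reports, function(r) r@m, integer(1))
  expect_identical(ms, c(64L, 67L))  # 400/256 and 400/4096 are <= 5
  expect_true(all(vapply(pan$reports,
                         function(r) sum(r@counts) == 400, logical(1))))
  expect_identical(pan$summaryP,
                   median(vapply(pan$reports, function(r) r@p, numeric(1))))
  # identical inputs give identical reports
  pan2 <- uniformityPanel(cfg, kmers, mPanel = c(64, 67, 256, 4096),
                          dataset = "random")
  expect_identical(lapply(pan$reports, function(r) r@p),
                   lapply(pan2$reports, function(r) r@p))
})

test_that("hashed uniform workloads are not systematically rejected", {
  # chi-squared null behavior: uniform random 32-bit integers bucketed at
  # m = 1024 should reject at alpha = 0.01 only at the nominal rate
  rejections <- 0
  for (s in 1:20) {
    set.seed(s)
    u <- floor(runif(2e4) * 2^32)
    p <- chi2Uniformity(bucketCounts(u, 1024))$p
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 3)
})

test_that("single-base mutation is Hamming distance 1, uniform over sites", {
  set.seed(6)
  kmers <- randomKmers(200, 9, seed = 60)
  mut <- mutateSingleBase(kmers, seed = 61)
  dist1 <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, kmers, mut)
  expect_true(all(dist1 == 1))
  expect_identical(mutateSingleBase(kmers, seed = 61), mut)
  # positions approximately uniform: 10,000 mutants of "AAAA", each site
  # expected 2,500 times, binomial 3-sigma band
  m <- mutateSingleBase(rep("AAAA", 10000), seed = 62)
  pos <- vapply(strsplit(m, ""), function(ch) which(ch != "A"), integer(1))
  tol <- 3 * sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(tabulate(pos, 4) - 2500) < tol))
})

test_that("avalanche Monte Carlo matches the exact linearity-derived value", {
  n <- 30000
  origins <- randomKmers(n, 16, seed = 8)
  for (case in list(list(poly = "0x8741C726", prep = "gen32"),
                    list(poly = "0x8741C726", prep = "none"),
                    list(poly = "0x8EFD4BCD", prep = "gen32"))) {
    cfg <- HashConfig(case$prep, "crc32", case$poly)
    av <- avalanche(cfg, origins, mutantsPerOrigin = 3, seed = 9)
    exact <- exactCrcMeanFlip(case$poly, 16, case$prep)
    se <- av@flipSD / sqrt(av@nPairs)
    expect_lt(abs(av@meanFlip - exact), 3 * se)
    expect_identical(av@nPairs, 3 * n)
    expect_identical(av@b, 32L)
  }
})

test_that("flip fractions are origin-independent for CRC schemes", {
  # CRC linearity: the same position/substitution delta must flip the same
  # bits whatever the origin k-mer
  cfg <- GEN32_CFG("0x9D9947FD")
  delta_flip <- function(origin) {
    h0 <- hashKmer(cfg, origin)
    mutated <- paste0("C", substr(origin, 2, 12))  # A -> C at position 1
    popcount32(xor32(h0, hashKmer(cfg, mutated)))
  }
  origins <- paste0("A", substr(randomKmers(20, 12, seed = 10), 2, 12))
  flips <- vapply(origins, delta_flip, numeric(1))
  expect_identical(length(unique(flips)), 1L)
})
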