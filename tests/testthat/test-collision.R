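test_that("audit counts match a naive per-string dictionary for small k", {
  configs <- list(GEN32_CFG("0x8741C726"), RAW_CFG("0xEDB88320"),
                  HashConfig("none", "murmur3_32"),
                  HashConfig("gen32", "xxhash32"))
  for (cfg in configs) {
    for (k in c(4, 6)) {
      naive <- length(unique(hashKmer(cfg, allKmersR(k))))
      rep <- countCollisions(cfg, k)
      expect_identical(rep@distinct, as.numeric(naive))
      expect_identical(rep@collisions, 4^k - naive)
    }
  }
})

test_that("injective configs report distinct == 256 at k = 4", {
  for (poly in names(collisionFreePolynomials())) {
    rep <- countCollisions(GEN32_CFG(poly), 4)
    expect_identical(rep@distinct, 256)
    expect_identical(rep@collisions, 0)
  }
})

test_that("sort and bitset backends agree on every tested configuration", {
  configs <- list(GEN32_CFG("0x8741C726"), GEN32_CFG("0x82F63B78"),
                  RAW_CFG("0xD2C0EF07"), HashConfig("none", "murmur3_32"),
                  HashConfig("none", "xxhash32"))
  for (cfg in configs) {
    for (k in c(4, 8)) {
      a <- countCollisions(cfg, k, backend = "sort")
      b <- countCollisions(cfg, k, backend = "bitset")
      expect_identical(a@distinct, b@distinct)
    }
  }
})

test_that("replicated audits with shuffled order are deterministic", {
  rep <- replicateAudit(GEN32_CFG("0x8741C726"), 8, reps = 10, orderSeed = 7)
  expect_true(rep@consistent)
  expect_identical(rep@collisions, 0)
  expect_identical(rep@replicates, 10L)
  # reps = 1 equals the plain audit
  one <- replicateAudit(RAW_CFG("0xEDB88320"), 6, reps = 1)
  expect_identical(one@distinct, countCollisions(RAW_CFG("0xEDB88320"),
                                                 6)@distinct)
  # a colliding config is equally stable under shuffling
  m <- replicateAudit(HashConfig("none", "murmur3_32"), 9, reps = 3,
                      orderSeed = 3)
  expect_true(m@consistent)
  expect_gte(m@collisions, 1)
})

test_that("resource guards refuse oversized audits without force", {
  cfg <- GEN32_CFG("0x8741C726")
  expect_error(countCollisions(cfg, 14), "force")
  expect_error(countCollisions(cfg, 14, backend = "sort", force = TRUE),
               "force|bitset")
  expect_error(countCollisions(cfg, 17), "1..16")
})

test_that("first-collision scan reconstructs onsets from per-k audits", {
  # a config that never collides in range returns NA
  expect_identical(firstCollisionK(GEN32_CFG("0x8741C726"), 4, 8),
                   NA_integer_)
  # MurmurHash3 collides first at k = 9 and not before
  expect_identical(firstCollisionK(HashConfig("none", "murmur3_32"), 4, 9),
                   9L)
})

test_that("rank certificate agrees with exhaustive audits where both run", {
  for (poly in c("0x8741C726", "0x82F63B78", "0x93B39B1B", "0xEDB88320")) {
    for (k in c(4, 6, 8)) {
      cert <- crcInjectivityRank(poly, k)
      audited <- countCollisions(GEN32_CFG(poly), k)@collisions == 0
      expect_identical(cert$injective, audited)
    }
  }
})

test_that("rank certificate reproduces the published onset structure", {
  # gen32+CRC32 onsets implied by the collision table: eight polynomials
  # stay injective through k = 16; the others fail at known k
  onset_rank <- function(poly) {
    for (k in 4:16)
      if (!crcInjectivityRank(poly, k)$injective) return(k)
    NA_integer_
  }
  eight <- names(collisionFreePolynomials())
  for (hex in eight) expect_identical(onset_rank(hex), NA_integer_)
  expect_identical(onset_rank("0x82F63B78"), 12L)
  expect_identical(onset_rank("0x93B39B1B"), 14L)
  expect_identical(onset_rank("0xB338ADD6"), 15L)
  rest <- setdiff(names(crcPolynomials()),
                  c(eight, "0x82F63B78", "0x93B39B1B", "0xB338ADD6"))
  for (hex in rest) expect_identical(onset_rank(hex), 16L)
})

test_that("polynomial screening keeps exactly the survivors, in order", {
  polys <- crcPolynomials()
  # every candidate survives a k <= 4 screen
  expect_identical(screenPolynomials(polys, kMax = 4), polys)
  # audit-based and rank-based screens agree at desk scale
  expect_identical(screenPolynomials(polys, kMax = 8),
                   screenPolynomials(polys, kMax = 8, method = "rank"))
  # the k = 16 rank screen returns exactly the eight published survivors
  expect_identical(sort(names(screenPolynomials(polys, kMax = 16,
                                                method = "rank"))),
                   sort(names(collisionFreePolynomials())))
})
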