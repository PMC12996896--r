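#' Bucket occupancies of 32-bit hash values
#'
#' Maps hash values to \code{m} buckets via \code{bucket = h mod m} and
#' tallies occupancies; \code{counts[j]} is the number of hashes congruent
#' to \code{j - 1}, and the counts sum to the input length.
#'
#' @param hashes numeric vector of non-negative integer hash values.
#' @param m bucket count (\eqn{\ge 1}).
#' @return numeric vector of length \code{m}.
#' @examples
#' bucketCounts(c(0, 1, 2, 3), 2)  # 2 2
#' @export
bucketCounts <- function(hashes, m) {
  stopifnot(is.numeric(hashes), length(m) == 1, !is.na(m), m >= 1)
  cpp_bucket_counts(hashes, m)
}

#' Pearson chi-squared test of bucket uniformity
#'
#' Scores an occupancy vector against the uniform expectation \eqn{n/m}:
#' \eqn{\chi^2 = \sum_j (counts_j - n/m)^2 / (n/m)} on \eqn{m - 1} degrees
#' of freedom, with the upper-tail probability. The chi-squared
#' approximation needs expected counts above 5, so smaller expectations are
#' rejected rather than silently reported.
#'
#' @param counts occupancy vector (length \eqn{m \ge 2}).
#' @return list with \code{chi2}, \code{df} and \code{p}.
#' @examples
#' chi2Uniformity(c(10, 6))  # chi2 = 1, p ~ 0.317
#' @export
chi2Uniformity <- function(counts) {
  stopifnot(is.numeric(counts), !anyNA(counts), all(counts >= 0))
  m <- length(counts)
  if (m < 2) stop("need at least 2 buckets")
  n <- sum(counts)
  expected <- n / m
  if (expected <= 5)
    stop("expected count n/m = ", format(expected),
         " is not above 5; chi-squared approximation invalid")
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, df = m - 1L,
       p = stats::pchisq(chi2, df = m - 1, lower.tail = FALSE))
}

#' Default bucket-count panel
#'
#' Powers of two and nearby odd primes spanning typical hash-table sizes.
#'
#' @return numeric vector of bucket counts.
#' @export
defaultBucketPanel <- function() {
  c(64, 67, 256, 257, 1021, 1024, 4093, 4096, 16381, 16384, 65521, 65536)
}

#' Bucket-uniformity panel for one configuration and dataset
#'
#' Hashes the k-mers once, buckets them at every admissible bucket count in
#' the panel (those with expected count \eqn{n/m > 5}), and scores each with
#' the Pearson chi-squared test. The dataset-level summary is the median of
#' the admissible p values — a stable order statistic, reported alongside
#' the full per-m table.
#'
#' @param config a \code{\link{HashConfig}}.
#' @param kmers character vector of k-mers, all the same length.
#' @param mPanel bucket counts to try (default
#'   \code{\link{defaultBucketPanel}}).
#' @param dataset regime tag recorded in the reports (\code{"random"},
#'   \code{"similar"}, \code{"window"} or \code{"custom"}).
#' @return list with \code{reports} (one \code{\link{UniformityReport}} per
#'   admissible m) and \code{summaryP} (median admissible p).
#' @examples
#' cfg <- HashConfig("gen32", "crc32", "0x8741C726")
#' pan <- uniformityPanel(cfg, randomKmers(2000, 12, seed = 1),
#'                        mPanel = c(64, 67))
#' pan$summaryP
#' @export
uniformityPanel <- function(config, kmers, mPanel = defaultBucketPanel(),
                            dataset = c("custom", "random", "similar",
                                        "window")) {
  dataset <- match.arg(dataset)
  stopifnot(length(kmers) >= 1)
  h <- hashBatch(config, kmers)
  n <- length(h)
  label <- configLabel(config)
  admissible <- mPanel[n / mPanel > 5 & mPanel >= 2]
  reports <- lapply(admissible, function(m) {
    counts <- bucketCounts(h, m)
    fit <- chi2Uniformity(counts)
    new("UniformityReport", configLabel = label, dataset = dataset,
        m = as.integer(m), counts = counts, chi2 = fit$chi2,
        df = fit$df, p = fit$p)
  })
  ps <- vapply(reports, function(r) r@p, numeric(1))
  list(reports = reports,
       summaryP = if (length(ps)) stats::median(ps) else NA_real_)
}

#' Substitute a single base in each k-mer
#'
#' Draws, per k-mer, a position uniform over \eqn{k} and a replacement base
#' uniform over the three alternatives to the original, so the output is at
#' Hamming distance exactly 1 from the input.
#'
#' @param kmers character vector of k-mers over \code{ACGT}.
#' @param seed optional RNG seed for reproducible mutants.
#' @return character vector of mutated k-mers.
#' @examples
#' mutateSingleBase("AAAA", seed = 1)
#' @export
mutateSingleBase <- function(kmers, seed = NULL) {
  stopifnot(is.character(kmers), length(kmers) >= 1, !anyNA(kmers))
  k <- nchar(kmers)
  with_seed(seed, {
    pos <- 1L + as.integer(floor(stats::runif(length(kmers)) * k))
    alt <- sample.int(3L, length(kmers), replace = TRUE)
    cpp_mutate_kmers(kmers, pos, alt)
  })
}

#' Avalanche (mean bit-flip) measurement
#'
#' For each origin k-mer, generates \code{mutantsPerOrigin} independent
#' single-base substitutions, hashes origin and mutant under the
#' configuration, and records the fraction of the 32 output bits flipped
#' (popcount of the XOR divided by 32). Ideal diffusion gives a mean flip
#' of 0.5.
#'
#' @param config a \code{\link{HashConfig}}.
#' @param originals character vector of origin k-mers, all the same length.
#' @param mutantsPerOrigin mutants per origin (\eqn{\ge 1}; the evaluation
#'   protocol uses 3).
#' @param seed optional RNG seed governing the mutant draws.
#' @return an \code{\link{AvalancheReport}}.
#' @examples
#' cfg <- HashConfig("gen32", "crc32", "0x8741C726")
#' avalanche(cfg, randomKmers(1000, 16, seed = 1), seed = 2)
#' @export
avalanche <- function(config, originals, mutantsPerOrigin = 3, seed = NULL) {
  stopifnot(is.character(originals), length(originals) >= 1,
            mutantsPerOrigin >= 1)
  n <- length(originals)
  m <- as.integer(mutantsPerOrigin)
  k <- nchar(originals[1])
  a <- config_args(config)
  flips <- with_seed(seed, {
    pos <- 1L + as.integer(floor(stats::runif(n * m) * k))
    alt <- sample.int(3L, n * m, replace = TRUE)
    cpp_avalanche_flips(originals, pos, alt, m, a$family, a$prep, a$poly,
                        a$init, a$xorout, a$seed)
  })
  new("AvalancheReport", configLabel = configLabel(config),
      nPairs = as.numeric(length(flips)), b = 32L, meanFlip = mean(flips),
      flipSD = stats::sd(flips),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Exact avalanche mean flip for CRC configurations
#'
#' A CRC is GF(2)-linear up to its (constant) init/xor-out terms, so the
#' output XOR of an origin-mutant pair depends only on the XOR-difference of
#' the (preprocessed) inputs — never on the origin itself. Under the
#' single-base substitution protocol on uniformly random origins, the mean
#' flip is therefore an exact finite average over position \eqn{\times}
#' base-pair deltas, computed here without any sampling. This is the
#' analytic oracle the Monte Carlo estimate of \code{\link{avalanche}} must
#' match to within Monte Carlo error.
#'
#' @param params a \code{\link{CrcParams}} or polynomial constant.
#' @param k k-mer length in bases.
#' @param preprocessing \code{"gen32"} or \code{"none"} (raw uppercase
#'   ASCII).
#' @return the exact mean flipped-bit fraction.
#' @examples
#' exactCrcMeanFlip("0x8741C726", 16)            # ~0.484
#' exactCrcMeanFlip("0x8741C726", 16, "none")    # ~0.503
#' @export
exactCrcMeanFlip <- function(params, k, preprocessing = c("gen32", "none")) {
  if (!is(params, "CrcParams")) params <- CrcParams(params)
  preprocessing <- match.arg(preprocessing)
  k <- check_k(k, max = 64)
  cpp_exact_mean_flip(k, params@poly, PREP_CODE[[preprocessing]])
}
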