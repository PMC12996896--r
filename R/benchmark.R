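#' Wall-clock hashing throughput
#'
#' Hashes \code{n} k-mers (cycling through an enumerated block of the k-mer
#' space) after a short warm-up and reports hashes per second. Throughput is
#' hardware- and build-dependent: it is reported for orientation and never
#' compared against published figures.
#'
#' @param config a \code{\link{HashConfig}}.
#' @param k k-mer length in bases.
#' @param n number of k-mers to hash.
#' @return list with \code{hashesPerSecond}, \code{n} and \code{elapsed}
#'   (seconds).
#' @examples
#' cfg <- HashConfig("gen32", "crc32", "0x8741C726")
#' measureThroughput(cfg, 12, n = 1e5)$hashesPerSecond > 0
#' @export
measureThroughput <- function(config, k, n = 1e6) {
  k <- check_k(k)
  stopifnot(n >= 1)
  block <- cpp_enumerate_block(k, 0, min(n, 4^k), 0L)
  kmers <- rep_len(block, n)
  invisible(hashBatch(config, kmers[seq_len(min(n, 1e4))]))  # warm-up
  t0 <- proc.time()[["elapsed"]]
  invisible(hashBatch(config, kmers))
  elapsed <- max(proc.time()[["elapsed"]] - t0, .Machine$double.eps)
  list(hashesPerSecond = n / elapsed, n = n, elapsed = elapsed)
}

#' Run the full evaluation battery and write report files
#'
#' Ties the modules together into one reproducible run: exhaustive collision
#' audits over a k range (a collision table laid out configuration-by-k),
#' bucket-uniformity summaries and avalanche mean flips on shared generated
#' workloads (a metrics table), optional throughput, and a manifest
#' capturing every parameter and seed needed to re-run the audits exactly
#' and the stochastic tasks bit-identically. TSV and JSON forms of each
#' table are written under \code{outDir}.
#'
#' @param configs list of \code{\link{HashConfig}} objects (or labels).
#' @param tasks subset of \code{c("audit", "uniformity", "avalanche",
#'   "throughput")}.
#' @param kRange k values audited (audit task).
#' @param k k-mer length for the workload tasks.
#' @param n workload size for uniformity/avalanche/throughput.
#' @param mutantsPerOrigin mutants per origin for the avalanche task.
#' @param seed master seed; workload seeds are derived from it and recorded.
#' @param fasta optional FASTA for the window regime; when \code{NULL} a
#'   synthetic genome is generated under the derived seed.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the collision table, the metrics table and
#'   the manifest.
#' @examples
#' \donttest{
#' cfg <- list(HashConfig("gen32", "crc32", "0x8741C726"))
#' out <- runBenchmark(cfg, tasks = "audit", kRange = 4:6,
#'                     outDir = tempfile())
#' out$audit
#' }
#' @export
runBenchmark <- function(configs,
                         tasks = c("audit", "uniformity", "avalanche",
                                   "throughput"),
                         kRange = 4:10, k = 16, n = 1e5,
                         mutantsPerOrigin = 3, seed = 1, fasta = NULL,
                         outDir = "gencrc32-reports") {
  tasks <- match.arg(tasks, several.ok = TRUE)
  if (!is.list(configs)) configs <- list(configs)
  configs <- lapply(configs, function(cfg) {
    if (is.character(cfg)) parseConfigLabel(cfg) else cfg
  })
  labels <- vapply(configs, configLabel, character(1))
  if (anyDuplicated(labels)) stop("duplicate configuration labels")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    tool = paste0("genCRC32 ",
                  as.character(utils::packageVersion("genCRC32"))),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    configs = labels, tasks = tasks, k_range = kRange, k = k, n = n,
    mutants_per_origin = mutantsPerOrigin, seed = seed,
    fasta = if (is.null(fasta)) "synthetic" else fasta)
  auditTab <- metricsTab <- NULL

  if ("audit" %in% tasks) {
    rows <- list()
    for (cfg in configs) {
      for (kk in kRange) {
        rep <- countCollisions(cfg, kk)
        rows <- c(rows, list(as.data.frame(rep)))
      }
    }
    auditTab <- do.call(rbind, rows)
    utils::write.table(auditTab, file.path(outDir, "collisions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(auditTab, file.path(outDir, "collisions.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }

  workload_tasks <- intersect(tasks, c("uniformity", "avalanche",
                                       "throughput"))
  if (length(workload_tasks)) {
    datasets <- list()
    if ("uniformity" %in% tasks) {
      if (is.null(fasta)) {
        fasta <- file.path(outDir, "synthetic_genome.fa")
        syntheticGenome(fasta, length = max(2 * n, n + k), gc = 0.508,
                        seed = seed + 3)
      }
      datasets <- list(random = randomKmers(n, k, seed = seed),
                       similar = similarChain(n, k, seed = seed + 1),
                       window = windowKmers(fasta, k, n))
    } else if ("avalanche" %in% tasks) {
      datasets <- list(random = randomKmers(n, k, seed = seed))
    }
    rows <- list()
    for (i in seq_along(configs)) {
      cfg <- configs[[i]]
      row <- data.frame(config_label = labels[i], stringsAsFactors = FALSE)
      if ("uniformity" %in% tasks) {
        for (ds in c("random", "similar", "window")) {
          pan <- uniformityPanel(cfg, datasets[[ds]], dataset = ds)
          row[[paste0("p_", ds)]] <- pan$summaryP
        }
      }
      if ("avalanche" %in% tasks) {
        av <- avalanche(cfg, datasets$random,
                        mutantsPerOrigin = mutantsPerOrigin,
                        seed = seed + 2)
        row$mean_flip <- av@meanFlip
        row$flip_sd <- av@flipSD
      }
      if ("throughput" %in% tasks) {
        # hardware-dependent: not comparable across machines or builds
        row$speed_mhs_hardware_dependent <-
          measureThroughput(cfg, k, n)$hashesPerSecond / 1e6
      }
      rows <- c(rows, list(row))
    }
    metricsTab <- do.call(rbind, rows)
    utils::write.table(metricsTab, file.path(outDir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(metricsTab, file.path(outDir, "metrics.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(audit = auditTab, metrics = metricsTab,
                 manifest = manifest))
}
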