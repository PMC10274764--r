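# End-to-end orchestration of one case: a shared monosomic/haploid
# reference plus one or more disomic test embryos on a chromosome.

#' Run a full crossover-mapping case
#'
#' Scores reads, checks the reference's window coverage, scans every
#' reference/test pair, classifies bins, detects per-embryo crossovers
#' and attributes them to the reference or the test embryos. Deterministic
#' given `seed`: the scan of test embryo `i` uses `seed + i`.
#'
#' @param mono reference [SampleReads-class] (ploidy 1).
#' @param siblings named list of test [SampleReads-class] (ploidy 2).
#' @param panel a [ReferencePanel-class].
#' @param composition an [AncestryComposition-class] or list of two.
#' @param chromLength chromosome length in bp (for the coverage fraction).
#' @param spec a [windowSpec()].
#' @param m bootstrap subsample count.
#' @param cap resampling cap per homolog.
#' @param f0 priority-score frequency cutoff.
#' @param binSize bin size for classification (bp).
#' @param zClassify bin-classification z-score.
#' @param zCall crossover-calling threshold.
#' @param delta minimum windows per crossover flank.
#' @param clusterL sibling-clustering region size (bp).
#' @param minC minimum window-coverage fraction of the reference.
#' @param seed integer seed (required: every stochastic stage derives its
#'   seed from it).
#' @param outDir when non-NULL, per-stage TSV/BED outputs are written
#'   there.
#' @return list with `status` (`"ok"` or `"skipped"`), `coverage`,
#'   per-embryo `scans` / `bins` / `calls`, `clusters`, `attribution`,
#'   and `log` (per-stage counts).
#' @export
runCase <- function(mono, siblings, panel, composition, chromLength,
                    spec = windowSpec(), m = 100L, cap = 6L, f0 = 0.05,
                    binSize = 2e6, zClassify = 1.96, zCall = 1.96,
                    delta = 15L, clusterL = 5e6, minC = 0.5,
                    seed, outDir = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is required for reproducibility")
  if (!is.list(siblings) || !length(siblings)) stop("need >= 1 test embryo")
  if (is.null(names(siblings))) {
    names(siblings) <- vapply(siblings, sampleId, "")
  }
  log <- list()

  if (anyNA(mono@reads$score)) mono <- scoreReads(mono, panel, composition, f0)
  siblings <- lapply(siblings, function(s) {
    if (anyNA(s@reads$score)) scoreReads(s, panel, composition, f0) else s
  })
  log$reads_in <- c(mono = nrow(mono@reads),
                    vapply(siblings, function(s) nrow(s@reads), 0L))

  # reference coverage: windows against the best-covered sibling layout
  # are what matter downstream; use the per-pair windows and require the
  # mean coverage fraction to clear minC
  covs <- vapply(siblings, function(s) {
    coverageFraction(buildWindows(mono, s, spec), chromLength)$C
  }, 0)
  coverage <- mean(covs)
  if (coverage < minC) {
    return(list(status = "skipped",
                reason = sprintf("window coverage %.3f below %.2f",
                                 coverage, minC),
                coverage = coverage, log = log))
  }

  scans <- list(); bins <- list(); calls <- list()
  for (i in seq_along(siblings)) {
    sc <- scanChromosome(mono, siblings[[i]], panel, composition, spec,
                         m = m, cap = cap, f0 = f0, seed = seed + i)
    scans[[i]] <- sc
    bins[[i]] <- binSummaries(sc$estimates, binSize, zClassify)
    track <- cumulativeTrack(sc$estimates)
    calls[[i]] <- detectCrossovers(track, z = zCall, delta = delta)
  }
  names(scans) <- names(bins) <- names(calls) <- names(siblings)
  log$windows <- vapply(scans, function(s) nrow(s$estimates), 0L)
  log$calls <- vapply(calls, nrow, 0L)

  if (length(siblings) >= 2L) {
    clustering <- clusterCrossovers(calls, l = clusterL)
    attribution <- attributeCrossovers(calls, clustering)
  } else {
    clustering <- NULL
    attribution <- list(reference = NULL, residual = calls)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(scans)) {
      writeLlrTrack(scans[[id]]$estimates,
                    file.path(outDir, paste0(id, ".llr.tsv")))
      cs <- calls[[id]]
      if (nrow(cs)) {
        cs$sample_id <- id
        writeCrossoverBed(cs, file.path(outDir, paste0(id, ".crossovers.bed")))
      }
    }
    if (!is.null(clustering) && nrow(clustering$clusters)) {
      writeClusterTsv(clustering$clusters, file.path(outDir, "clusters.tsv"))
    }
  }
  list(status = "ok", coverage = coverage, scans = scans, bins = bins,
       calls = calls, clusters = clustering, attribution = attribution,
       log = log)
}
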