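# Balanced ROC curves for the trinomial (matched / unmatched / ambiguous)
# classifier, used to benchmark performance on simulated pairs.

#' Balanced true and false positive rates at one z threshold
#'
#' Positives are truth-unmatched instances, negatives truth-matched.
#' `BTPR = (TPR + TNR) / 2` and `BFPR = (FPR + FNR) / 2`; instances
#' classified ambiguous count toward neither numerator, deflating all four
#' rates alike — the balanced curve rewards confident correct calls and
#' penalises confident wrong ones, while abstention costs sensitivity
#' only.
#'
#' @param truth character vector in `{"matched", "unmatched"}`.
#' @param classes character vector in
#'   `{"matched", "unmatched", "ambiguous"}`.
#' @return named numeric vector with `btpr` and `bfpr`.
#' @export
balancedRates <- function(truth, classes) {
  stopifnot(length(truth) == length(classes))
  nPos <- sum(truth == "unmatched")
  nNeg <- sum(truth == "matched")
  if (nPos == 0L || nNeg == 0L) {
    stop("truth must contain both matched and unmatched instances")
  }
  tpr <- sum(truth == "unmatched" & classes == "unmatched") / nPos
  tnr <- sum(truth == "matched" & classes == "matched") / nNeg
  fpr <- sum(truth == "matched" & classes == "unmatched") / nNeg
  fnr <- sum(truth == "unmatched" & classes == "matched") / nPos
  c(btpr = (tpr + tnr) / 2, bfpr = (fpr + fnr) / 2)
}

#' Balanced ROC curve over a z grid
#'
#' Reclassifies each instance at every z in the grid from its normalized
#' bin LLR and variance (see [classifyBin()]), computes the balanced
#' rates, and integrates the area under the curve by the trapezoid rule
#' over points sorted by BFPR, with anchor points (0,0) and (1,1)
#' appended (the balanced curve need not reach them on its own).
#'
#' @param truth character vector in `{"matched", "unmatched"}`.
#' @param gammaBin,varBin per-instance normalized LLR means and variances.
#' @param zGrid z thresholds (default 0 to 5 in steps of 0.05).
#' @return list with `points` (data.frame `z`, `btpr`, `bfpr`) and `auc`.
#' @export
balancedRoc <- function(truth, gammaBin, varBin, zGrid = seq(0, 5, by = 0.05)) {
  pts <- t(vapply(zGrid, function(z) {
    balancedRates(truth, classifyBin(gammaBin, varBin, z))
  }, c(btpr = 0, bfpr = 0)))
  points <- data.frame(z = zGrid, btpr = pts[, "btpr"], bfpr = pts[, "bfpr"])
  list(points = points, auc = .rocAuc(points$bfpr, points$btpr))
}

#' Simulate monosomy/disomy pairs and classify fixed bins
#'
#' Benchmark harness: simulates breakpoint-free pairs (alternating matched
#' and unmatched scenarios), scans each against its panel, and summarises
#' every 2 Mbp-style bin over a fixed grid spanning the whole chromosome.
#' Bins without any genomic window get `NA` statistics and classify as
#' ambiguous at every z — a bin that produced no windows is
#' unclassifiable.
#'
#' @param panels list of [ReferencePanel-class] objects, recycled over
#'   replicates.
#' @param nPairs number of simulated pairs (half matched, half unmatched).
#' @param coverage depth per homolog (x).
#' @param chromLength chromosome length in bp.
#' @param binSize bin size in bp (default 2 Mbp).
#' @param spec a [windowSpec()].
#' @param m bootstrap subsample count.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @return data.frame with one row per (pair, bin): `pair`, `truth`,
#'   `bin_start`, `gamma_bin`, `var_bin`.
#' @export
pairBenchmark <- function(panels, nPairs, coverage, chromLength,
                          binSize = 2e6, spec = windowSpec(), m = 100L,
                          seed = 1L) {
  if (!is.list(panels)) panels <- list(panels)
  grid <- seq(0, chromLength - 1, by = binSize)
  out <- vector("list", nPairs)
  for (r in seq_len(nPairs)) {
    pan <- panels[[(r - 1L) %% length(panels) + 1L]]
    scn <- if (r %% 2L == 1L) "matched" else "unmatched"
    pair <- simulatePair(pan, scn, coverage = coverage,
                         chromLength = chromLength, seed = seed + 2L * r)
    sc <- scanChromosome(pair$mono, pair$di, pan, pair$composition,
                         spec = spec, m = m, seed = seed + 2L * r + 1L)
    gb <- rep(NA_real_, length(grid))
    vb <- rep(NA_real_, length(grid))
    if (nrow(sc$estimates)) {
      b <- binSummaries(sc$estimates, binSize)
      hit <- match(b$bin_start, grid)
      gb[hit] <- b$gamma_bin
      vb[hit] <- b$var_bin
    }
    out[[r]] <- data.frame(pair = r, truth = scn, bin_start = grid,
                           gamma_bin = gb, var_bin = vb)
  }
  do.call(rbind, out)
}

# trapezoid AUC with (0,0) and (1,1) anchors
.rocAuc <- function(bfpr, btpr) {
  x <- c(0, bfpr, 1)
  y <- c(0, btpr, 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
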