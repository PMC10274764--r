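# Per-window bootstrap LLR estimation, bin aggregation and classification,
# cumulative LLR track, and crossover detection from its local extrema.

.drawIdx <- function(n, cap) {
  if (n > cap) sample.int(n, cap) else seq_len(n)
}

# core bootstrap over precomputed, population-grouped masks (compiled)
.bootstrapMasks <- function(masksA, masksB, ctx, m, cap,
                            maxAttempts = 10L * m) {
  res <- .cpp_bootstrap_window(masksA, masksB, ctx$grp$sizes, ctx$a1,
                               ctx$a2, ctx$floorVal,
                               as.integer(m), as.integer(cap),
                               as.integer(2L * cap),
                               as.integer(maxAttempts))
  if (res$flagged) return(list(flagged = TRUE))
  list(flagged = FALSE, gammaMean = mean(res$gamma),
       gammaVar = var(res$gamma), m = m)
}

#' Bootstrap the window log-likelihood ratio
#'
#' m-out-of-n bootstrap of the matched/unmatched LLR within one genomic
#' window: in each of `m` iterations, up to `cap` monosomy reads and up to
#' `2 * cap` disomy reads are sampled without replacement with equal
#' probabilities, and the LLR of that subsample is computed. Returns the
#' sample mean and the Bessel-corrected sample variance. Subsamples for
#' which both hypotheses have probability zero are redrawn (capped at
#' `10 * m` attempts, after which the window is flagged).
#'
#' @param monoReads,diReads lists of per-read observation data.frames for
#'   the window's informative monosomy / disomy reads.
#' @param panel a [ReferencePanel-class].
#' @param composition an [AncestryComposition-class] or list of two.
#' @param m number of bootstrap subsamples (>= 2).
#' @param cap resampling cap per homolog (default 6).
#' @return list with `gammaMean`, `gammaVar`, `m`, `flagged`.
#' @export
bootstrapWindow <- function(monoReads, diReads, panel, composition,
                            m = 100L, cap = 6L) {
  if (m < 2L) stop("m must be >= 2 (variance undefined otherwise)")
  ctx <- .pairContext(panel, composition)
  rows <- ctx$grp$order
  masksA <- .readMasks(panel, monoReads)[rows, , drop = FALSE]
  masksB <- .readMasks(panel, diReads)[rows, , drop = FALSE]
  res <- .bootstrapMasks(masksA, masksB, ctx, m, cap)
  if (res$flagged) return(list(gammaMean = NA_real_, gammaVar = NA_real_,
                               m = m, flagged = TRUE))
  list(gammaMean = res$gammaMean, gammaVar = res$gammaVar, m = m,
       flagged = FALSE)
}

#' Scan a chromosome: windows plus per-window bootstrap LLR estimates
#'
#' Scores reads if necessary, builds adaptive windows and bootstraps the
#' LLR in each. Windows in which every subsample is uninformative are
#' dropped (a message reports the count).
#'
#' @param mono,di [SampleReads-class] objects (ploidy 1 and 2).
#' @param panel a [ReferencePanel-class].
#' @param composition an [AncestryComposition-class] or list of two.
#' @param spec a [windowSpec()].
#' @param m bootstrap subsample count (default 100).
#' @param cap resampling cap per homolog (default 6).
#' @param f0 score frequency cutoff (default 0.05).
#' @param seed optional integer seed (set before any resampling).
#' @return list with `windows` (`GRanges`) and `estimates` (data.frame
#'   `window`, `chrom`, `start`, `end`, `gamma_mean`, `gamma_var`, `m`;
#'   coordinates 0-based half-open).
#' @export
scanChromosome <- function(mono, di, panel, composition,
                           spec = windowSpec(), m = 100L, cap = 6L,
                           f0 = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (anyNA(mono@reads$score)) mono <- scoreReads(mono, panel, composition, f0)
  if (anyNA(di@reads$score)) di <- scoreReads(di, panel, composition, f0)
  windows <- buildWindows(mono, di, spec)

  ctx <- .pairContext(panel, composition)
  rows <- ctx$grp$order
  withIdx <- function(obs) {
    obs <- obs[, c("read_id", "pos", "allele")]
    obs$idx <- match(obs$pos, panel@positions)
    if (anyNA(obs$idx)) {
      stop("observation position(s) not in panel: ",
           paste(head(obs$pos[is.na(obs$idx)]), collapse = ", "))
    }
    split(obs[, c("pos", "allele", "idx")], obs$read_id)
  }
  obsM <- withIdx(mono@observations)
  obsD <- withIdx(di@observations)
  empty <- data.frame(pos = integer(), allele = integer(), idx = integer())

  nw <- length(windows)
  gm <- numeric(nw); gv <- numeric(nw); flg <- logical(nw)
  monoL <- as.list(windows$monoReads)
  diL <- as.list(windows$diReads)
  nmM <- names(obsM); nmD <- names(obsD)
  for (w in seq_len(nw)) {
    iM <- match(monoL[[w]], nmM)
    iD <- match(diL[[w]], nmD)
    mr <- ifelse(is.na(iM), list(empty), obsM[pmax(iM, 1L)])
    dr <- ifelse(is.na(iD), list(empty), obsD[pmax(iD, 1L)])
    masksA <- .readMasks(panel, mr)[rows, , drop = FALSE]
    masksB <- .readMasks(panel, dr)[rows, , drop = FALSE]
    res <- .bootstrapMasks(masksA, masksB, ctx, m, cap)
    if (res$flagged) { flg[w] <- TRUE; next }
    gm[w] <- res$gammaMean; gv[w] <- res$gammaVar
  }
  if (any(flg)) message(sum(flg), " window(s) flagged uninformative and dropped")
  keep <- which(!flg)
  estimates <- data.frame(
    window = seq_along(keep),
    chrom = as.character(GenomicRanges::seqnames(windows))[keep],
    start = GenomicRanges::start(windows)[keep] - 1L,
    end = GenomicRanges::end(windows)[keep],
    gamma_mean = gm[keep], gamma_var = gv[keep], m = m)
  list(windows = windows[keep], estimates = estimates)
}

#' Aggregate window LLR estimates within a bin
#'
#' `Gamma_bin` is the sum of the windows' mean LLRs and its variance the
#' sum of their variances (independent windows); the normalized mean per
#' window is `Gamma_bin / g` with variance `Var(Gamma_bin) / g^2`.
#'
#' @param gammaMeans,gammaVars per-window means and variances in the bin.
#' @return list with `Gamma`, `VarGamma`, `g`, `gammaBin`, `varBin`.
#' @export
aggregateBin <- function(gammaMeans, gammaVars) {
  g <- length(gammaMeans)
  if (g < 1L) stop("empty bin")
  Gamma <- sum(gammaMeans)
  VarGamma <- sum(gammaVars)
  list(Gamma = Gamma, VarGamma = VarGamma, g = g,
       gammaBin = Gamma / g, varBin = VarGamma / g^2)
}

#' Classify a bin from its normalized LLR confidence interval
#'
#' The confidence interval is `gammaBin +/- z * sqrt(varBin)`: entirely
#' positive supports the unmatched-haplotypes hypothesis, entirely
#' negative the matched hypothesis, and an interval spanning zero is
#' ambiguous (positive LLR = evidence of non-matching).
#'
#' @param gammaBin,varBin normalized bin mean and variance (vectorized).
#' @param z z-score of the confidence interval (default 1.96, i.e. 95%).
#' @return character vector in `{"matched", "unmatched", "ambiguous"}`.
#' @export
classifyBin <- function(gammaBin, varBin, z = 1.96) {
  if (z < 0) stop("z must be >= 0")
  half <- z * sqrt(varBin)
  out <- ifelse(gammaBin - half > 0, "unmatched",
                ifelse(gammaBin + half < 0, "matched", "ambiguous"))
  out[is.na(gammaBin)] <- "ambiguous"   # bins with no genomic windows
  out
}

#' Summarise and classify fixed-size bins along a chromosome
#'
#' Windows are assigned to consecutive bins of `binSize` bp by midpoint;
#' each non-empty bin is aggregated with [aggregateBin()] and classified
#' with [classifyBin()].
#'
#' @param estimates the estimates data.frame from [scanChromosome()].
#' @param binSize bin size in bp (default 2 Mbp).
#' @param z classification z-score (default 1.96).
#' @return data.frame with one row per non-empty bin: `bin_start`,
#'   `bin_end`, `g`, `gamma_bin`, `var_bin`, `class`.
#' @export
binSummaries <- function(estimates, binSize = 2e6, z = 1.96) {
  mid <- (estimates$start + estimates$end) / 2
  bin <- floor(mid / binSize)
  out <- lapply(sort(unique(bin)), function(bb) {
    sel <- bin == bb
    a <- aggregateBin(estimates$gamma_mean[sel], estimates$gamma_var[sel])
    data.frame(bin_start = bb * binSize, bin_end = (bb + 1) * binSize,
               g = a$g, gamma_bin = a$gammaBin, var_bin = a$varBin)
  })
  out <- do.call(rbind, out)
  out$class <- classifyBin(out$gamma_bin, out$var_bin, z)
  out
}

#' Cumulative LLR track
#'
#' Prefix sums of the per-window mean LLRs (`y`) and of their variances
#' (`v`), ordered along the chromosome — the substrate of crossover
#' detection: local maxima of `y` mark transitions from unmatched to
#' matched haplotypes, local minima the reverse.
#'
#' @param estimates the estimates data.frame from [scanChromosome()],
#'   sorted by window start.
#' @return data.frame `window`, `chrom`, `start`, `end`, `mid`, `y`, `v`.
#' @export
cumulativeTrack <- function(estimates) {
  if (is.unsorted(estimates$start)) stop("estimates must be sorted by start")
  data.frame(window = seq_len(nrow(estimates)),
             chrom = estimates$chrom,
             start = estimates$start, end = estimates$end,
             mid = (estimates$start + estimates$end) / 2,
             y = cumsum(estimates$gamma_mean),
             v = cumsum(estimates$gamma_var))
}

# flank z-score with a 0/0 -> 0 and x/0 -> +/-Inf convention
.flankScore <- function(dy, dv) {
  ifelse(dv > 0, dy / sqrt(dv), ifelse(dy > 0, Inf, ifelse(dy < 0, -Inf, 0)))
}

# best flank z-scores for an extremum candidate at j; type +1 = maximum,
# -1 = minimum. Returns min of the best left and right flank scores, or
# -Inf when no admissible flank exists.
.kappaAt <- function(y, v, j, delta, type) {
  N <- length(y)
  s <- type * y
  # left: interior (i, j) must stay strictly below s[j] (ties left of j
  # disqualify j as the first regional argmax)
  iLow <- 1L
  if (j > 1L) {
    geq <- which(s[seq_len(j - 1L)] >= s[j])
    if (length(geq)) iLow <- max(geq)
  }
  iHi <- j - delta
  if (iHi < iLow) return(-Inf)
  ii <- iLow:iHi
  left <- max(.flankScore(type * (y[j] - y[ii]), v[j] - v[ii]))
  # right: interior (j, k) must stay at or below s[j]
  kHi <- N
  if (j < N) {
    gt <- which(s[(j + 1L):N] > s[j])
    if (length(gt)) kHi <- j + min(gt)
  }
  kLo <- j + delta
  if (kLo > kHi) return(-Inf)
  kk <- kLo:kHi
  right <- max(.flankScore(type * (y[j] - y[kk]), v[kk] - v[j]))
  min(left, right)
}

#' Detect meiotic crossovers from a cumulative LLR track
#'
#' A crossover is called at window `j` when `j` is the extremum of the
#' cumulative LLR within a region `(i, k)` whose two flanks each rise (for
#' a maximum; fall for a minimum) by at least `z` standard deviations of
#' the accumulated variance, with at least `delta` windows on each flank.
#' The call confidence `kappa` is the smaller of the two flank z-scores.
#' When two consecutive accepted extrema share a type, the skipped
#' opposite extremum between them is recovered with [recoverSkipped()]
#' (such recovered calls may carry `kappa < z` and are flagged).
#'
#' A local maximum is a transition from unmatched to matched haplotypes; a
#' local minimum the reverse.
#'
#' @param track data.frame from [cumulativeTrack()].
#' @param z calling threshold (> 0; default 1.96).
#' @param delta minimum windows per flank (>= 1; default 15).
#' @return data.frame of calls ordered along the chromosome: `window`,
#'   `chrom`, `start`, `end`, `mid`, `direction`
#'   (`"unmatched_to_matched"` or `"matched_to_unmatched"`), `kappa`,
#'   `recovered`. Zero rows when fewer than `2 * delta + 1` windows.
#' @export
detectCrossovers <- function(track, z = 1.96, delta = 15L) {
  if (z <= 0) stop("z must be > 0")
  if (delta < 1L) stop("delta must be >= 1")
  N <- nrow(track)
  emptyCalls <- data.frame(window = integer(), chrom = character(),
                           start = numeric(), end = numeric(),
                           mid = numeric(), direction = character(),
                           kappa = numeric(), recovered = logical())
  if (N < 2L * delta + 1L) return(emptyCalls)
  y <- track$y; v <- track$v

  cand <- list()
  for (j in (delta + 1L):(N - delta)) {
    for (type in c(1, -1)) {
      kap <- .kappaAt(y, v, j, delta, type)
      if (is.finite(kap) && kap >= z || is.infinite(kap) && kap > 0) {
        cand[[length(cand) + 1L]] <- list(j = j, type = type, kappa = kap,
                                          recovered = FALSE)
      }
    }
  }
  if (!length(cand)) return(emptyCalls)
  cand <- cand[order(vapply(cand, `[[`, 0, "j"))]

  # recover skipped opposite extrema between consecutive same-type calls
  final <- list(cand[[1]])
  for (c2 in cand[-1]) {
    c1 <- final[[length(final)]]
    if (c1$type == c2$type && c2$j > c1$j + 1L) {
      jr <- recoverSkipped(track, c1$j, c2$j,
                           type = if (c1$type > 0) "max" else "min")
      kapL <- .flankScore(-c2$type * (y[jr] - y[c1$j]), v[jr] - v[c1$j])
      kapR <- .flankScore(-c2$type * (y[jr] - y[c2$j]), v[c2$j] - v[jr])
      final[[length(final) + 1L]] <- list(j = jr, type = -c1$type,
                                          kappa = min(kapL, kapR),
                                          recovered = TRUE)
    }
    final[[length(final) + 1L]] <- c2
  }

  j <- vapply(final, `[[`, 0, "j")
  type <- vapply(final, `[[`, 0, "type")
  data.frame(window = j,
             chrom = track$chrom[j],
             start = track$start[j], end = track$end[j], mid = track$mid[j],
             direction = ifelse(type > 0, "unmatched_to_matched",
                                "matched_to_unmatched"),
             kappa = vapply(final, `[[`, 0, "kappa"),
             recovered = vapply(final, `[[`, TRUE, "recovered"))
}

#' Recover a skipped extremum between two same-type extrema
#'
#' Between two accepted maxima at windows `i < k`, the skipped minimum is
#' the interior window maximising the difference of the two flank
#' z-scores, `(y_k - y_n)/sqrt(v_k - v_n) - (y_n - y_i)/sqrt(v_n - v_i)`;
#' between two minima the argmin of the same expression is taken. Ties
#' break to the lowest window index.
#'
#' @param track data.frame from [cumulativeTrack()].
#' @param i,k window indices of the two same-type extrema (`k > i + 1`).
#' @param type `"max"` when `i` and `k` are maxima, `"min"` for minima.
#' @return the interior window index of the recovered extremum.
#' @export
recoverSkipped <- function(track, i, k, type = c("max", "min")) {
  type <- match.arg(type)
  if (k <= i + 1L) stop("no interior window between i and k")
  y <- track$y; v <- track$v
  nn <- (i + 1L):(k - 1L)
  obj <- .flankScore(y[k] - y[nn], v[k] - v[nn]) -
    .flankScore(y[nn] - y[i], v[nn] - v[i])
  if (type == "max") nn[which.max(obj)] else nn[which.min(obj)]
}
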