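# Shared fixtures and independent oracle implementations used across the
# test files. Oracles are deliberately naive (plain loops over haplotype
# rows and homolog assignments) so they share no code path with the
# package's bit-packed implementation.

# tiny panel from an explicit haplotype matrix
makePanel <- function(hap, pops = rep("P", nrow(hap)), positions = NULL,
                      chrom = "cT") {
  hap <- as.matrix(hap)
  if (is.null(positions)) positions <- seq_len(ncol(hap)) * 100L
  ref <- rep("A", ncol(hap))
  alt <- rep("G", ncol(hap))
  ReferencePanel(chrom, positions, ref, alt, hap, pops)
}

obs1 <- function(pos, allele) data.frame(pos = as.integer(pos),
                                         allele = as.integer(allele))

# naive joint frequency: loop over rows of one population
oracleJointFrequency <- function(panel, pop, observations) {
  hap <- haplotypeMatrix(panel)
  rows <- which(panelPopulations(panel) == pop)
  if (NROW(observations) == 0L) return(1)
  idx <- match(observations$pos, panelPositions(panel))
  hits <- 0L
  for (r in rows) {
    ok <- TRUE
    for (k in seq_along(idx)) {
      if (hap[r, idx[k]] != observations$allele[k]) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits / length(rows)
}

oracleEffFrequency <- function(panel, weights, observations) {
  sum(vapply(names(weights), function(p) {
    weights[[p]] * oracleJointFrequency(panel, p, observations)
  }, 0))
}

# union of observation frames
obsUnion <- function(reads) {
  if (!length(reads)) return(data.frame(pos = integer(), allele = integer()))
  u <- unique(do.call(rbind, lapply(reads, function(o) o[, c("pos", "allele")])))
  u
}

# exhaustive enumeration over homolog assignments of the disomy reads;
# w1/w2 are named weight vectors for the two homolog distributions (the
# first also governs the monosomy reads)
oracleLikelihoods <- function(aReads, bReads, panel, w1, w2 = w1) {
  n <- length(bReads)
  ssets <- if (n) lapply(0:(2^n - 1), function(s) which(bitwAnd(s, 2^(seq_len(n) - 1)) > 0)) else list(integer())
  matched <- 0; disomy <- 0
  for (S in ssets) {
    comp <- setdiff(seq_len(n), S)
    matched <- matched +
      oracleEffFrequency(panel, w1, obsUnion(c(aReads, bReads[S]))) *
      oracleEffFrequency(panel, w2, obsUnion(bReads[comp]))
    disomy <- disomy +
      oracleEffFrequency(panel, w1, obsUnion(bReads[S])) *
      oracleEffFrequency(panel, w2, obsUnion(bReads[comp]))
  }
  matched <- matched / 2^n
  disomy <- disomy / 2^n
  fA <- oracleEffFrequency(panel, w1, obsUnion(aReads))
  list(matched = matched, unmatched = fA * disomy, disomy = disomy)
}

# random small read set over a panel for property-style checks
randomReads <- function(panel, k, maxObs = 2L) {
  lapply(seq_len(k), function(i) {
    nObs <- sample.int(maxObs, 1L)
    idx <- sort(sample.int(nSites(panel), nObs))
    data.frame(pos = panelPositions(panel)[idx],
               allele = sample(0:1, nObs, replace = TRUE))
  })
}

# exhaustive (i, j, k) search for crossover candidates on a cumulative track
oracleDetect <- function(track, z, delta) {
  y <- track$y; v <- track$v; N <- length(y)
  out <- list()
  for (type in c(1, -1)) {
    s <- type * y
    for (j in seq_len(N)) {
      found <- FALSE
      for (i in seq_len(N)) {
        if (found || j - i < delta) next
        for (k in seq_len(N)) {
          if (found || k - j < delta || k > N) next
          inner <- if (i + 1 <= k - 1) (i + 1):(k - 1) else integer()
          if (!length(inner)) next
          am <- inner[which.max(s[inner])]
          if (am != j) next
          dv1 <- v[j] - v[i]; dv2 <- v[k] - v[j]
          r1 <- type * (y[j] - y[i]); r2 <- type * (y[j] - y[k])
          z1 <- if (dv1 > 0) r1 / sqrt(dv1) else ifelse(r1 > 0, Inf, -Inf)
          z2 <- if (dv2 > 0) r2 / sqrt(dv2) else ifelse(r2 > 0, Inf, -Inf)
          if (z1 >= z && z2 >= z) {
            out[[length(out) + 1L]] <- data.frame(window = j, type = type)
            found <- TRUE
          }
        }
      }
    }
  }
  if (!length(out)) return(data.frame(window = integer(), type = numeric()))
  unique(do.call(rbind, out))
}

# straight-line reimplementation of the meiotic-error decision tree
oracleErrorCall <- function(bph, sph, periBph, periSph) {
  if (bph >= 0.10) {
    if (periBph >= 0.50) "MI"
    else if (periSph >= 0.50) "MII"
    else "ambiguous"
  } else if (sph >= 0.50) "mitotic" else "ambiguous"
}

# small track constructor for detector tests
stepTrack <- function(gammas, vars = rep(0.01, length(gammas)),
                      width = 1e5) {
  est <- data.frame(window = seq_along(gammas), chrom = "cT",
                    start = (seq_along(gammas) - 1) * width,
                    end = seq_along(gammas) * width,
                    gamma_mean = gammas, gamma_var = vars,
                    m = 100L)
  cumulativeTrack(est)
}
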