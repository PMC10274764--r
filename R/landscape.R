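# Downstream analyses: meiotic-origin classification of trisomies from
# BPH/SPH tract tracks, and comparison of crossover landscapes via eCDFs
# and a permutation Kolmogorov-Smirnov test.
#
# BPH ("both parental homologs") and SPH ("single parental homolog")
# describe the haplotype configuration of the two chromosomes a trisomic
# sample inherited from one parent. Pericentromeric BPH indicates a
# meiosis I error, pericentromeric SPH with BPH elsewhere a meiosis II
# error, and chromosome-wide SPH a potentially mitotic origin. The
# per-region z-score track is an input here (produced by a
# haplotype-counting ploidy scan, which is outside this package's scope).

#' Label crossover-bounded regions as BPH / SPH / ambiguous
#'
#' Regions with z above 1.96 are BPH, below -1.96 SPH, otherwise
#' ambiguous.
#'
#' @param regions data.frame with columns `start`, `end` (bp,
#'   non-overlapping, sorted) and `z`.
#' @param zThreshold threshold (default 1.96).
#' @return `regions` with a `label` column.
#' @export
labelRegions <- function(regions, zThreshold = 1.96) {
  regions$label <- ifelse(regions$z > zThreshold, "BPH",
                          ifelse(regions$z < -zThreshold, "SPH", "ambiguous"))
  regions
}

#' Pericentromeric interval of a chromosome
#'
#' A region spanning 20% of the chromosome length centered on the
#' centromere midpoint, clipped to the chromosome. For acrocentric
#' chromosomes only the q-arm half is meaningful, so the region is the
#' 10% of the chromosome length immediately distal to the centromere's
#' q-side edge.
#'
#' @param L chromosome length in bp.
#' @param centromere numeric length-2 vector `(start, end)` of the
#'   centromere, bp.
#' @param acrocentric logical.
#' @return numeric length-2 vector `(start, end)`.
#' @export
pericentromericInterval <- function(L, centromere, acrocentric = FALSE) {
  if (centromere[1] < 0 || centromere[2] > L) stop("centromere outside [0, L)")
  if (acrocentric) {
    lo <- centromere[2]
    hi <- lo + 0.1 * L
  } else {
    c0 <- mean(centromere)
    lo <- c0 - 0.1 * L
    hi <- c0 + 0.1 * L
  }
  c(max(0, lo), min(L, hi))
}

.overlapLen <- function(s, e, lo, hi) pmax(0, pmin(e, hi) - pmax(s, lo))

#' Classify a trisomy's meiotic origin from labeled tracts
#'
#' Decision tree over length-weighted tract fractions: a chromosome with
#' at least 10% BPH is a meiotic error; otherwise at least 50% SPH is a
#' mitotic error; otherwise ambiguous. A meiotic error with at least 50%
#' of the pericentromeric region BPH is a meiosis I (MI) error; otherwise
#' at least 50% pericentromeric SPH gives meiosis II (MII); otherwise
#' ambiguous. Chromosome fractions are normalized by `L`; pericentromeric
#' fractions by the length of the pericentromeric interval covered by
#' labeled regions. Samples whose genomic windows cover less than half
#' the chromosome are excluded (error).
#'
#' @param regions labeled regions from [labelRegions()].
#' @param L chromosome length in bp.
#' @param peri pericentromeric interval from [pericentromericInterval()].
#' @param C window-coverage fraction of the underlying scan (must be
#'   >= 0.5).
#' @return list with `call` in `{"MI", "MII", "mitotic", "ambiguous"}` and
#'   the supporting fractions `bph_frac`, `sph_frac`, `peri_bph_frac`,
#'   `peri_sph_frac`.
#' @export
classifyMeioticError <- function(regions, L, peri, C) {
  if (C < 0.5) stop("window coverage below 0.5; sample excluded")
  lenBy <- function(lab) sum(regions$end[regions$label == lab] -
                               regions$start[regions$label == lab])
  bphFrac <- lenBy("BPH") / L
  sphFrac <- lenBy("SPH") / L
  periCov <- sum(.overlapLen(regions$start, regions$end, peri[1], peri[2]))
  periBy <- function(lab) {
    sel <- regions$label == lab
    if (periCov == 0) return(0)
    sum(.overlapLen(regions$start[sel], regions$end[sel], peri[1], peri[2])) /
      periCov
  }
  periBph <- periBy("BPH")
  periSph <- periBy("SPH")
  call <- if (bphFrac >= 0.10) {
    if (periBph >= 0.50) "MI" else if (periSph >= 0.50) "MII" else "ambiguous"
  } else if (sphFrac >= 0.50) "mitotic" else "ambiguous"
  list(call = call, bph_frac = bphFrac, sph_frac = sphFrac,
       peri_bph_frac = periBph, peri_sph_frac = periSph)
}

#' Empirical CDF of a crossover landscape
#'
#' The right-continuous step function tracing the cumulative fraction of
#' crossovers from the beginning to the end of a chromosome — the
#' bin-free summary of a recombination landscape (physical map vs genetic
#' map).
#'
#' @param positions crossover positions in bp (>= 1 position).
#' @param L chromosome length (positions must lie in `[0, L)`).
#' @return a step function (as from [stats::ecdf()]).
#' @export
crossoverEcdf <- function(positions, L = NULL) {
  if (!length(positions)) stop("no crossover positions")
  if (!is.null(L) && (any(positions < 0) || any(positions >= L))) {
    stop("positions outside [0, L)")
  }
  ecdf(positions)
}

.ksStat <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
}

#' Two-sample Kolmogorov-Smirnov test with a permutation p-value
#'
#' `D` is the supremum distance between the two empirical CDFs. The null
#' distribution is generated by reassigning the pooled observations to
#' two groups of the original sizes: exhaustively over all
#' `choose(n1 + n2, n1)` assignments (`mode = "exact"`), or by Monte
#' Carlo sampling. The p-value is the proportion of assignments with a
#' statistic at least as extreme as the observed one; the observed
#' assignment is included (exact mode enumerates it; Monte Carlo adds it
#' as the `+1` term).
#'
#' @param x,y numeric samples (both non-empty).
#' @param mode `"exact"` or `"monte-carlo"`.
#' @param nPerm number of Monte Carlo permutations (default 2000).
#' @param exactLimit refuse exact enumeration beyond this many
#'   assignments (default 2e5).
#' @param seed optional integer seed for Monte Carlo mode.
#' @return list with `D` and `p.value`.
#' @examples
#' ksPermutation(c(1, 2, 3), c(7, 8, 9), mode = "exact")
#' @export
ksPermutation <- function(x, y, mode = c("exact", "monte-carlo"),
                          nPerm = 2000L, exactLimit = 2e5, seed = NULL) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  D <- .ksStat(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  nTot <- length(pooled)
  eps <- 1e-12
  if (mode == "exact") {
    nComb <- choose(nTot, n1)
    if (nComb > exactLimit) {
      stop("choose(", nTot, ", ", n1, ") = ", nComb,
           " assignments exceed exactLimit; use mode = 'monte-carlo'")
    }
    idx <- combn(nTot, n1)
    dPerm <- apply(idx, 2L, function(ii) .ksStat(pooled[ii], pooled[-ii]))
    p <- mean(dPerm >= D - eps)
  } else {
    if (!is.null(seed)) set.seed(seed)
    dPerm <- vapply(seq_len(nPerm), function(i) {
      ii <- sample.int(nTot, n1)
      .ksStat(pooled[ii], pooled[-ii])
    }, 0)
    p <- (1 + sum(dPerm >= D - eps)) / (nPerm + 1)
  }
  list(D = D, p.value = p)
}
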