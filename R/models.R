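# Matched / unmatched haplotype-hypothesis likelihoods.
#
# The monosomic reference sample contributes reads A_1..A_m, all from one
# homolog; the disomic test sample contributes reads B_1..B_n from two
# homologs with equal prior odds. Under the matched hypothesis the
# monosomy haplotype is identical to one of the disomy homologs, so the
# first homolog's frequency function is the conditional g(X) = F(A_all, X);
# under the unmatched hypothesis the monosomy is an independent haplotype
# and its joint frequency simply multiplies the plain disomy model.

# rows restricted to the populations referenced by the two homolog
# distributions, grouped by population
.grouping <- function(panel, pops) {
  bad <- setdiff(pops, unique(panel@populations))
  if (length(bad)) stop("population(s) not in panel: ", paste(bad, collapse = ", "))
  sizes <- vapply(pops, function(p) sum(panel@populations == p), 0L)
  if (any(sizes < 2L)) {
    stop("population(s) with fewer than 2 haplotypes: ",
         paste(pops[sizes < 2L], collapse = ", "))
  }
  ord <- unlist(lapply(pops, function(p) which(panel@populations == p)),
                use.names = FALSE)
  list(pops = pops, sizes = unname(sizes), order = ord)
}

# composition -> the two homolog distributions (named weight vectors).
# A single AncestryComposition applies to both homologs and the monosomy
# reads (non-admixed or distant admixture); a list of two compositions
# models recent admixture: the first is the shared parent's distribution
# (monosomy reads + matched homolog), the second the other parent's.
.resolvePair <- function(composition) {
  asw <- function(x) {
    stopifnot(is(x, "AncestryComposition"))
    validObject(x)
    setNames(x@weights, x@populations)
  }
  if (is(composition, "AncestryComposition")) {
    w <- asw(composition)
    return(list(a1 = w, a2 = w))
  }
  if (is.list(composition) && length(composition) == 2L) {
    return(list(a1 = asw(composition[[1]]), a2 = asw(composition[[2]])))
  }
  stop("'composition' must be an AncestryComposition or a list of two")
}

# per-read haplotype compatibility masks, rows in panel-native order;
# observation frames may carry a precomputed site-index column `idx`
.readMasks <- function(panel, reads) {
  H <- nrow(panel@haplotypes)
  out <- matrix(TRUE, nrow = H, ncol = length(reads))
  for (j in seq_along(reads)) {
    obs <- reads[[j]]
    if (NROW(obs) == 0L) next
    idx <- obs$idx %||% .obsSiteIndex(panel, obs)
    sub <- panel@haplotypes[, idx, drop = FALSE]
    hit <- sub == matrix(as.integer(obs$allele), nrow = H, ncol = length(idx),
                         byrow = TRUE)
    out[, j] <- rowSums(hit) == length(idx)
  }
  out
}

.pairContext <- function(panel, composition) {
  pair <- .resolvePair(composition)
  pops <- union(names(pair$a1)[pair$a1 > 0], names(pair$a2)[pair$a2 > 0])
  grp <- .grouping(panel, pops)
  a1 <- unname(pair$a1[match(grp$pops, names(pair$a1))])
  a2 <- unname(pair$a2[match(grp$pops, names(pair$a2))])
  a1[is.na(a1)] <- 0
  a2[is.na(a2)] <- 0
  list(grp = grp, a1 = a1, a2 = a2,
       floorVal = 1 / (2 * nrow(panel@haplotypes)))
}

# low-level entry used by tests: masks already subset to grouped rows
.pairLik <- function(masksA, masksB, ctx) {
  .cpp_pair_likelihoods(masksA, masksB, ctx$grp$sizes, ctx$a1, ctx$a2)
}

.checkReads <- function(reads, what) {
  stopifnot(is.list(reads))
  for (obs in reads) {
    if (!all(c("pos", "allele") %in% names(obs))) {
      stop(what, " must be a list of data.frames with columns pos, allele")
    }
  }
}

.likCore <- function(aReads, bReads, panel, composition, cap) {
  ctx <- .pairContext(panel, composition)
  rows <- ctx$grp$order
  masksA <- .readMasks(panel, aReads)[rows, , drop = FALSE]
  masksB <- .readMasks(panel, bReads)[rows, , drop = FALSE]
  lik <- .pairLik(masksA, masksB, ctx)
  lik$floorVal <- ctx$floorVal
  lik
}

#' Disomy likelihood for a set of test-sample reads
#'
#' Probability of the alleles observed on `reads` under a disomic sample
#' whose two homologs follow the distributions implied by `composition`:
#' the exact `(1/2)^n` sum over all `2^n` assignments of the reads to the
#' two homologs, each term a product of joint haplotype frequencies.
#'
#' @param reads list of per-read observation data.frames (`pos`, `allele`);
#'   may be empty (likelihood 1).
#' @param panel a [ReferencePanel-class].
#' @param composition an [AncestryComposition-class], or a list of two for
#'   homolog-specific distributions (recent admixture).
#' @param cap maximum reads per homolog for the exact enumeration;
#'   `length(reads)` may not exceed `2 * cap`.
#' @return probability in `[0, 1]`.
#' @export
disomyLikelihood <- function(reads, panel, composition, cap = 6L) {
  .checkReads(reads, "reads")
  if (length(reads) > 2L * cap) {
    stop("more than ", 2L * cap, " disomy reads; enumeration cap exceeded")
  }
  .likCore(list(), reads, panel, composition, cap)$disomy
}

#' Matched-haplotypes likelihood
#'
#' Likelihood that the monosomy reads `aReads` and the disomy reads
#' `bReads` were generated with the monosomy haplotype identical to one of
#' the disomy homologs: the disomy model with the first homolog's
#' frequency function replaced by `g(X) = F(A_1..A_m, X)`.
#'
#' @param aReads list of monosomy-read observation data.frames (m >= 1).
#' @param bReads list of disomy-read observation data.frames (n >= 1).
#' @inheritParams disomyLikelihood
#' @return probability in `[0, 1]`.
#' @export
matchedLikelihood <- function(aReads, bReads, panel, composition, cap = 6L) {
  .checkReads(aReads, "aReads"); .checkReads(bReads, "bReads")
  .checkPairCounts(aReads, bReads, cap)
  .likCore(aReads, bReads, panel, composition, cap)$matched
}

#' Unmatched-haplotypes likelihood
#'
#' Likelihood under the hypothesis that the monosomy haplotype is
#' independent of both disomy homologs: the joint frequency of all
#' monosomy-read alleles multiplied by the plain disomy model of the test
#' reads.
#'
#' @inheritParams matchedLikelihood
#' @return probability in `[0, 1]`.
#' @export
unmatchedLikelihood <- function(aReads, bReads, panel, composition, cap = 6L) {
  .checkReads(aReads, "aReads"); .checkReads(bReads, "bReads")
  .checkPairCounts(aReads, bReads, cap)
  .likCore(aReads, bReads, panel, composition, cap)$unmatched
}

.checkPairCounts <- function(aReads, bReads, cap) {
  if (length(aReads) < 1L) stop("at least one monosomy read required")
  if (length(aReads) > cap) stop("more than ", cap, " monosomy reads")
  if (length(bReads) < 1L) stop("at least one disomy read required")
  if (length(bReads) > 2L * cap) stop("more than ", 2L * cap, " disomy reads")
}

#' Log-likelihood ratio of the two haplotype-matching hypotheses
#'
#' `gamma = log(P_unmatched / P_matched)` (natural log): positive values
#' support the unmatched-haplotypes hypothesis, negative values support
#' matching. A panel of `N` haplotypes cannot resolve probability ratios
#' beyond its counting resolution, so `gamma` is bounded at
#' `+/- log(2 * N)`; in particular, when exactly one hypothesis has
#' probability zero (its allele combination is absent from the panel) the
#' ratio saturates at the bound instead of diverging. When both
#' hypotheses are zero the subsample carries no usable signal and is
#' flagged `uninformative`.
#'
#' @inheritParams matchedLikelihood
#' @return list with `gamma`, `pMatched`, `pUnmatched`, `uninformative`.
#' @examples
#' pan <- syntheticPanel(nHaplotypes = 100, nSites = 40, chromLength = 4e4,
#'                       seed = 2)
#' comp <- AncestryComposition(c(POP1 = 1))
#' a <- list(data.frame(pos = panelPositions(pan)[10], allele = 0L))
#' b <- list(data.frame(pos = panelPositions(pan)[11], allele = 0L))
#' windowLlr(a, b, pan, comp)
#' @export
windowLlr <- function(aReads, bReads, panel, composition, cap = 6L) {
  .checkReads(aReads, "aReads"); .checkReads(bReads, "bReads")
  .checkPairCounts(aReads, bReads, cap)
  lik <- .likCore(aReads, bReads, panel, composition, cap)
  .llrFromLik(lik)
}

.llrFromLik <- function(lik) {
  pm <- lik$matched
  pu <- lik$unmatched
  if (pm == 0 && pu == 0) {
    return(list(gamma = NA_real_, pMatched = 0, pUnmatched = 0,
                uninformative = TRUE))
  }
  cap <- -log(lik$floorVal)
  gamma <- if (pm == 0) cap else if (pu == 0) -cap else
    min(cap, max(-cap, log(pu) - log(pm)))
  list(gamma = gamma, pMatched = pm, pUnmatched = pu, uninformative = FALSE)
}
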