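# Generative model for benchmark data: synthetic phased panels with LD,
# parent/offspring/unrelated haplotype trios, and low-coverage read
# sampling, so that every stage of the pipeline is testable end to end
# without external downloads.

#' Generate a synthetic phased reference panel with linkage disequilibrium
#'
#' Haplotypes are built as block-wise mosaics of a small set of founder
#' haplotypes: each panel haplotype copies one founder per block, with
#' exponentially distributed block lengths. Sites within a block are
#' therefore correlated and the pairwise correlation decays with physical
#' distance, emulating LD decay; the founder count bounds haplotype
#' diversity the way a finite population does. This is a fast structural
#' stand-in for a population-genetic simulator, not a coalescent model.
#'
#' @param nHaplotypes number of haplotype rows (even, >= 4).
#' @param nSites number of biallelic SNPs; default one per 100 bp,
#'   approximating the full biallelic SNP density of a large sequencing
#'   panel.
#' @param chromLength chromosome length in bp.
#' @param nFounders founder haplotypes per population (default 32, so two
#'   unrelated haplotypes share a local founder in only a few percent of
#'   windows).
#' @param blockMean mean mosaic block length in bp (controls LD decay;
#'   default 100 kbp, the scale over which human pairwise LD decays to a
#'   quarter of its maximum).
#' @param mafShape1,mafShape2 Beta shape parameters for the alt-allele
#'   frequency spectrum among founders; the default U-shaped
#'   `Beta(0.5, 0.5)` puts most variants near the frequency extremes, as
#'   in real site frequency spectra.
#' @param mafFloor minimum distance of founder allele frequencies from 0
#'   and 1 (keeps all sites polymorphic).
#' @param mutationRate per-site probability that a copied founder allele is
#'   flipped, emulating private variation accumulated since the founder
#'   (default 0: the mosaic structure alone carries the LD the method
#'   uses, and flips blur the block boundaries that define it).
#' @param densityProfile optional data.frame (`start`, `end`, `weight`)
#'   of relative SNP-density multipliers for sub-intervals of the
#'   chromosome (weight 1 elsewhere); emulates regional heterogeneity such
#'   as variant-poor pericentromeric sequence.
#' @param populations named integer vector of haplotype counts per
#'   population, e.g. `c(POP1 = 250, POP2 = 250)`; default one population
#'   `POP1` with all haplotypes. Each population has its own founder set.
#' @param chrom chromosome name.
#' @param seed optional integer seed for reproducibility.
#' @return a [ReferencePanel-class].
#' @examples
#' pan <- syntheticPanel(nHaplotypes = 200, nSites = 500,
#'                       chromLength = 1e6, seed = 1)
#' pan
#' @export
syntheticPanel <- function(nHaplotypes = 500L, nSites = NULL,
                           chromLength = 1e7, nFounders = 32L,
                           blockMean = 1e5, mafShape1 = 0.5, mafShape2 = 0.5,
                           mafFloor = 0.02, mutationRate = 0,
                           densityProfile = NULL, populations = NULL,
                           chrom = "chrS", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nHaplotypes < 4L || nHaplotypes %% 2L != 0L) {
    stop("nHaplotypes must be even and >= 4")
  }
  if (is.null(nSites)) nSites <- max(2L, round(chromLength / 100))
  if (nSites > chromLength) stop("more sites than base pairs")
  if (is.null(populations)) populations <- c(POP1 = nHaplotypes)
  if (sum(populations) != nHaplotypes) {
    stop("population sizes must sum to nHaplotypes")
  }

  pos <- .samplePositions(chromLength, nSites, densityProfile)
  palt <- mafFloor + (1 - 2 * mafFloor) * stats::rbeta(nSites, mafShape1, mafShape2)

  hap <- matrix(0L, nrow = nHaplotypes, ncol = nSites)
  popLabels <- rep(names(populations), populations)
  row0 <- 0L
  for (p in names(populations)) {
    founders <- matrix(rbinom(nFounders * nSites, 1L, rep(palt, each = nFounders)),
                       nrow = nFounders)
    for (i in seq_len(populations[[p]])) {
      row <- .mosaicRow(founders, pos, chromLength, blockMean)
      if (mutationRate > 0) {
        flip <- runif(nSites) < mutationRate
        row[flip] <- 1L - row[flip]
      }
      hap[row0 + i, ] <- row
    }
    row0 <- row0 + populations[[p]]
  }
  # bases are arbitrary; only the 0/1 coding matters downstream
  bases <- c("A", "C", "G", "T")
  others <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                  c("A", "C", "T"), c("A", "C", "G"))
  refIdx <- sample.int(4L, nSites, replace = TRUE)
  alt <- others[cbind(refIdx, sample.int(3L, nSites, replace = TRUE))]
  ReferencePanel(chrom, pos, bases[refIdx], alt, hap, popLabels)
}

# site positions under a piecewise-constant relative density
.samplePositions <- function(chromLength, nSites, densityProfile) {
  if (is.null(densityProfile)) {
    return(sort(sample.int(chromLength, nSites)))
  }
  bounds <- sort(unique(c(0, chromLength, densityProfile$start,
                          densityProfile$end)))
  bounds <- bounds[bounds >= 0 & bounds <= chromLength]
  segStart <- bounds[-length(bounds)]
  segEnd <- bounds[-1]
  w <- rep(1, length(segStart))
  for (i in seq_len(nrow(densityProfile))) {
    hit <- segStart >= densityProfile$start[i] & segEnd <= densityProfile$end[i]
    w[hit] <- densityProfile$weight[i]
  }
  mass <- w * (segEnd - segStart)
  cnt <- as.vector(stats::rmultinom(1, nSites, mass / sum(mass)))
  cnt <- pmin(cnt, segEnd - segStart)
  pos <- unlist(lapply(seq_along(cnt), function(i) {
    if (cnt[i] == 0L) return(integer())
    segStart[i] + sample.int(segEnd[i] - segStart[i], cnt[i])
  }))
  sort(as.integer(pos))
}

.mosaicRow <- function(founders, pos, chromLength, blockMean) {
  nBlocks <- max(2L, ceiling(2 * chromLength / blockMean))
  breaks <- cumsum(c(0, rexp(nBlocks, rate = 1 / blockMean)))
  while (breaks[length(breaks)] < chromLength) {
    breaks <- c(breaks, breaks[length(breaks)] +
                  cumsum(rexp(nBlocks, rate = 1 / blockMean)))
  }
  block <- findInterval(pos, breaks)
  src <- sample.int(nrow(founders), length(breaks), replace = TRUE)
  founders[cbind(src[block], seq_along(pos))]
}

#' Draw a parent / offspring / unrelated haplotype trio from a panel
#'
#' Selects three distinct haplotype rows: the offspring carries rows 1 and
#' 2, the parental chromosome is row 1 (so the offspring matches it by
#' construction) and row 3 is an unrelated chromosome. In non-admixed mode
#' all three rows come from one population; in recent-admixed mode the two
#' offspring rows come from different populations and the unrelated row
#' from one of those two.
#'
#' @param panel a [ReferencePanel-class].
#' @param ancestry `"non-admixed"` or `"recent-admixed"`.
#' @param population population to draw from (non-admixed); default the
#'   panel's first.
#' @param populations two populations for recent admixture; default the
#'   panel's first two.
#' @return list with integer row indices `parent`, `offspring` (length 2)
#'   and `unrelated`, plus `populations` (label per offspring row).
#' @export
drawTrio <- function(panel, ancestry = c("non-admixed", "recent-admixed"),
                     population = NULL, populations = NULL) {
  ancestry <- match.arg(ancestry)
  labs <- panel@populations
  if (ancestry == "non-admixed") {
    if (is.null(population)) population <- labs[1]
    rows <- which(labs == population)
    if (length(rows) < 3L) stop("need >= 3 haplotypes in population ", population)
    pick <- sample(rows, 3L)
    return(list(parent = pick[1], offspring = pick[1:2], unrelated = pick[3],
                populations = c(population, population)))
  }
  if (is.null(populations)) populations <- head(unique(labs), 2L)
  if (length(unique(populations)) != 2L) stop("recent admixture needs two populations")
  r1 <- which(labs == populations[1])
  r2 <- which(labs == populations[2])
  if (length(r1) < 2L || length(r2) < 2L) stop("not enough haplotypes per population")
  h1 <- sample(r1, 2L)
  h2 <- sample(r2, 1L)
  list(parent = h1[1], offspring = c(h1[1], h2), unrelated = h1[2],
       populations = populations)
}

#' Simulate low-coverage reads from a set of source haplotypes
#'
#' Reads have uniformly distributed midpoints and fixed length; each read
#' copies the panel alleles of one source haplotype over its span. The
#' source is drawn from `probs` (one probability per haplotype slot,
#' summing to 1). The total read count is
#' `round(ploidy * coverage * chromLength / readLen)`, where `coverage` is
#' the depth per homolog. Optional `breakpoints` swap which panel row
#' plays slot 1 for read midpoints beyond each breakpoint (alternating
#' between `hapRows[1]` and `altRow`), which is how known crossovers are
#' planted in simulated samples.
#'
#' @param panel a [ReferencePanel-class].
#' @param hapRows integer vector of panel row indices, one per haplotype
#'   slot.
#' @param probs probability per slot; must sum to 1.
#' @param coverage depth of coverage per homolog (x).
#' @param chromLength chromosome length in bp.
#' @param readLen read length in bp (default 75, single-end).
#' @param ploidy 1 or 2.
#' @param sampleId sample identifier for the returned object.
#' @param breakpoints sorted bp positions at which slot 1 switches row.
#' @param altRow panel row that alternates with `hapRows[1]` at the
#'   breakpoints.
#' @return a [SampleReads-class].
#' @export
simulateReads <- function(panel, hapRows, probs, coverage, chromLength,
                          readLen = 75L, ploidy = 1L, sampleId = "sim",
                          breakpoints = NULL, altRow = NULL) {
  if (abs(sum(probs) - 1) > 1e-9) stop("haplotype probabilities must sum to 1")
  if (length(probs) != length(hapRows)) stop("one probability per haplotype slot")
  if (!is.null(breakpoints)) {
    if (is.unsorted(breakpoints)) stop("breakpoints must be sorted")
    if (is.null(altRow)) stop("altRow required with breakpoints")
  }
  nReads <- round(ploidy * coverage * chromLength / readLen)
  mids <- runif(nReads, 0, chromLength)
  slot <- sample.int(length(hapRows), nReads, replace = TRUE, prob = probs)
  src <- hapRows[slot]
  if (!is.null(breakpoints) && length(breakpoints)) {
    seg <- findInterval(mids, breakpoints)  # 0 before first breakpoint
    swap <- slot == 1L & (seg %% 2L == 1L)
    src[swap] <- altRow
  }
  start <- pmax(0, floor(mids - readLen / 2))
  end <- pmin(chromLength, start + readLen)
  ids <- sprintf("%s_r%06d", sampleId, seq_len(nReads))

  pos <- as.numeric(panel@positions)
  lo <- findInterval(start, pos) + 1L       # first site with pos > start
  hi <- findInterval(end, pos)              # last site with pos <= end
  cnt <- pmax(hi - lo + 1L, 0L)
  readRow <- rep.int(seq_len(nReads), cnt)
  siteIdx <- unlist(lapply(which(cnt > 0L), function(i) lo[i]:hi[i]),
                    use.names = FALSE)
  observations <- data.frame(
    read_id = ids[readRow],
    pos = panel@positions[siteIdx],
    allele = panel@haplotypes[cbind(src[readRow], siteIdx)])
  if (!nrow(observations)) {
    observations <- data.frame(read_id = character(), pos = integer(),
                               allele = integer())
  }
  reads <- data.frame(read_id = ids, start = as.integer(start),
                      end = as.integer(end), score = NA_integer_)
  SampleReads(sampleId, panel@chrom, ploidy, reads, observations)
}

#' Simulate a monosomy/disomy sibling pair
#'
#' Draws a haplotype trio and simulates reads for a monosomic reference
#' sample and a disomic test sample. In the `"matched"` scenario the
#' monosomy is the parental chromosome shared with the offspring; in
#' `"unmatched"` it is the unrelated chromosome. Optional `breakpoints`
#' plant crossovers by switching the offspring's shared homolog between
#' the parental row and an extra unrelated row, so the truth label
#' alternates along the chromosome starting from the scenario label.
#'
#' @param panel a [ReferencePanel-class].
#' @param scenario `"matched"` or `"unmatched"`.
#' @param ancestry `"non-admixed"` or `"recent-admixed"`.
#' @param coverage depth per homolog (x).
#' @param chromLength chromosome length (bp); defaults to the panel span.
#' @param readLen read length (bp).
#' @param breakpoints sorted bp positions where the shared haplotype
#'   switches (only meaningful for the `"matched"` start).
#' @param seed optional integer seed.
#' @return list with `mono` and `di` ([SampleReads-class]), `truth`
#'   (data.frame `start`, `end`, `label` of matched/unmatched segments),
#'   `trio` (the drawn rows) and `composition` (an
#'   [AncestryComposition-class] or list of two, ready for the scan).
#' @examples
#' pan <- syntheticPanel(nHaplotypes = 100, chromLength = 1e6,
#'                       nSites = 2000, seed = 3)
#' pair <- simulatePair(pan, "matched", coverage = 0.05, seed = 4)
#' pair$mono
#' @export
simulatePair <- function(panel, scenario = c("matched", "unmatched"),
                         ancestry = c("non-admixed", "recent-admixed"),
                         coverage = 0.05, chromLength = NULL, readLen = 75L,
                         breakpoints = NULL, seed = NULL) {
  scenario <- match.arg(scenario)
  ancestry <- match.arg(ancestry)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(chromLength)) chromLength <- max(panel@positions)
  trio <- drawTrio(panel, ancestry)

  if (!is.null(breakpoints) && length(breakpoints)) {
    if (scenario != "matched") stop("breakpoints are planted from the matched state")
    used <- c(trio$parent, trio$offspring, trio$unrelated)
    altPool <- setdiff(which(panel@populations == panel@populations[trio$parent]),
                       used)
    if (!length(altPool)) stop("no spare haplotype for breakpoint planting")
    altRow <- sample(altPool, 1L)
  } else {
    altRow <- NULL
  }

  monoRow <- if (scenario == "matched") trio$parent else trio$unrelated
  mono <- simulateReads(panel, monoRow, 1, coverage, chromLength,
                        readLen = readLen, ploidy = 1L, sampleId = "mono")
  di <- simulateReads(panel, trio$offspring, c(0.5, 0.5), coverage,
                      chromLength, readLen = readLen, ploidy = 2L,
                      sampleId = "di", breakpoints = breakpoints,
                      altRow = altRow)

  bounds <- c(0, breakpoints, chromLength)
  labels <- rep(c(scenario, setdiff(c("matched", "unmatched"), scenario)),
                length.out = length(bounds) - 1L)
  truth <- data.frame(start = bounds[-length(bounds)], end = bounds[-1L],
                      label = labels)

  composition <- if (ancestry == "non-admixed") {
    AncestryComposition(setNames(1, trio$populations[1]))
  } else {
    list(AncestryComposition(setNames(1, trio$populations[1])),
         AncestryComposition(setNames(1, trio$populations[2])))
  }
  trio$altRow <- altRow
  list(mono = mono, di = di, truth = truth, trio = trio,
       composition = composition)
}

#' Simulate a sibling case: one shared monosomic reference, several disomies
#'
#' All test embryos carry the parental haplotype, so each pairwise scan
#' against the shared monosomy is matched throughout except where a
#' crossover intervenes. Crossovers planted on the monosomy
#' (`monoBreakpoints`) flip every sibling's track at the same position and
#' should be attributed to the reference; per-sibling `siblingBreakpoints`
#' flip only that embryo's track.
#'
#' @param panel a [ReferencePanel-class].
#' @param nSiblings number of disomic test embryos (>= 2).
#' @param coverage depth per homolog (x).
#' @param chromLength chromosome length (bp); defaults to the panel span.
#' @param readLen read length (bp).
#' @param monoBreakpoints sorted bp positions of reference crossovers.
#' @param siblingBreakpoints optional list (length `nSiblings`) of sorted
#'   bp positions of private crossovers per embryo.
#' @param seed optional integer seed.
#' @return list with `mono`, `siblings` (list of [SampleReads-class]),
#'   `composition`, and the planted breakpoint positions.
#' @export
simulateSiblingCase <- function(panel, nSiblings = 3L, coverage = 0.05,
                                chromLength = NULL, readLen = 75L,
                                monoBreakpoints = NULL,
                                siblingBreakpoints = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nSiblings < 2L) stop("need at least 2 test embryos")
  if (is.null(chromLength)) chromLength <- max(panel@positions)
  pop <- panel@populations[1]
  rows <- which(panel@populations == pop)
  need <- 2L + 2L * nSiblings
  if (length(rows) < need) stop("population too small for this sibling case")
  pick <- sample(rows, need)
  parent <- pick[1]
  monoAlt <- pick[2]
  sibSecond <- pick[3:(2 + nSiblings)]
  sibAlt <- pick[(3 + nSiblings):(2 + 2 * nSiblings)]

  mono <- simulateReads(panel, parent, 1, coverage, chromLength,
                        readLen = readLen, ploidy = 1L, sampleId = "mono",
                        breakpoints = monoBreakpoints, altRow = monoAlt)
  siblings <- vector("list", nSiblings)
  for (i in seq_len(nSiblings)) {
    bp <- if (!is.null(siblingBreakpoints)) siblingBreakpoints[[i]] else NULL
    siblings[[i]] <- simulateReads(
      panel, c(parent, sibSecond[i]), c(0.5, 0.5), coverage, chromLength,
      readLen = readLen, ploidy = 2L, sampleId = sprintf("sib%02d", i),
      breakpoints = bp, altRow = sibAlt[i])
  }
  list(mono = mono, siblings = siblings,
       composition = AncestryComposition(setNames(1, pop)),
       monoBreakpoints = monoBreakpoints %||% numeric(),
       siblingBreakpoints = siblingBreakpoints)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
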