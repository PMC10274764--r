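---
title: "Mapping meiotic crossovers from low-coverage sibling-embryo sequencing"
author: "meioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping meiotic crossovers from low-coverage sibling-embryo sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioscan)
```

## The problem

Preimplantation genetic testing for aneuploidy (PGT-A) produces
whole-genome sequencing of IVF embryo biopsies at extremely low coverage —
well under 0.05x per homolog. At such coverage direct genotyping is
impossible: reads from two samples almost never overlap, and only a tiny
minority of variant positions are observed at all. Yet PGT-A data carry a
unique relatedness structure: each IVF cycle yields several sibling
embryos, and chromosome losses are common. A monosomic chromosome (or a
haploid / genome-wide isodisomic embryo) is *phased by default* — every
read from it comes from one homolog — so it can serve as a reference
haplotype against which the disomic siblings are compared. Intervals where
a disomic sibling shares the reference haplotype (identical by descent)
alternate with intervals where it does not, and the transition points are
meiotic crossovers in the gamete that formed one of the two embryos.

`meioscan` implements this comparison. The missing genotype information is
replaced by linkage disequilibrium (LD) from an external phased reference
panel: observing alleles on one read changes the probability of alleles on
a nearby read *if* both reads came from the same underlying haplotype,
and does not if they came from different haplotypes.

## The statistical model

All frequencies are exact counting estimates over the phased haplotype
rows of the reference panel (`ReferencePanel`). For a read `A`, `f(A)`
denotes the joint frequency of all panel-site alleles observed on the
read, i.e. the frequency of the (partial) haplotype the read defines;
`f(A, B)` is the joint frequency over two reads. For a sample with
ancestry proportions `alpha_i` over panel populations, every `f` is
replaced by the effective mixture `sum_i alpha_i f_i`
(`effectiveFrequency`).

For one monosomy read `A` and one disomy read `B`, the two hypotheses are

* matched: the monosomy haplotype equals one of the two disomy homologs,
  so the reads land on the same haplotype with prior odds 1:1,

      P_matched = 1/2 f(A, B) + 1/2 f(A) f(B),

* unmatched: the monosomy haplotype is independent of both homologs,

      P_unmatched = f(A) f(B),

and the evidence is the log-likelihood ratio
`gamma = log(P_unmatched / P_matched)` (natural log). Positive `gamma`
supports non-matching, negative `gamma` supports matching.

For `m` monosomy reads and `n` disomy reads the disomy model marginalises
exactly over all `2^n` assignments of the disomy reads to the two
homologs; the matched model substitutes, for the first homolog, the
conditional frequency function `g(X) = f(A_1..A_m, X)` so that every
assignment term carries the monosomy reads on that homolog; the unmatched
model multiplies the plain disomy model by `f(A_1..A_m)`
(`matchedLikelihood`, `unmatchedLikelihood`, `disomyLikelihood`). For
recently admixed samples the two homologs carry separate population
distributions (a list of two `AncestryComposition` objects); for more
distant admixture a single mixed composition replaces every frequency.

### Numerical choices

Counting frequencies are used *raw* inside the assignment sums: an allele
combination absent from the panel contributes probability zero and its
terms simply drop out. Smoothing the zero frequencies inside the sums is
tempting but harmful — with `2^n` terms per hypothesis, floored
impossible terms accumulate and can dominate both sums, systematically
biasing the ratio toward the matched hypothesis. Instead, regularisation
happens once, at the hypothesis level: a panel of `N` haplotypes cannot
resolve probability ratios beyond its counting resolution `1/(2N)`, so
`gamma` is bounded at `+/- log(2N)` (about 6.9 for 500 haplotypes). When
both hypotheses are zero the subsample carries no signal and is redrawn.

## Prioritizing reads

A read's priority score counts the *common haplotypes* of the panel
region it spans: all `2^k` haplotypes over the `k` panel SNPs inside the
read span are enumerated and those with effective frequency strictly
between `f0` and `1 - f0` are counted (`priorityScore`; default
`f0 = 0.05`, enumeration capped at 16 SNPs per read). The score never
looks at the alleles the read actually carries. A single-SNP read scores
2 when the minor allele frequency exceeds `f0`, else 0. Reads scoring
below a threshold (default 1) are ignored downstream.

## Adaptive genomic windows

Pairwise LD in human genomes decays over roughly 100 kbp, so reads can
only inform on each other within windows of that scale. Windows are sized
adaptively by the local density of informative reads in *both* samples
(`buildWindows`): a window closes as soon as it holds at least `b`
monosomy and `2 b` disomy informative reads (the disomy has two homologs,
so twice the minimum yields the same expected number per homolog), and a
forming window is dismissed when consecutive reads of either sample are
more than 100 kbp apart or when it reaches 350 kbp short of its minima.

Default `b = 20`. Two constraints pin this choice. The bootstrap resamples
at most 6 monosomy and 12 disomy reads per window (below), so `b` must
comfortably exceed those caps or every "resample" is the full read set and
the bootstrap variance degenerates to zero, which in turn collapses the
crossover-calling thresholds. And windows must stay at the 10--100 kbp
haplotype scale: at 0.05x per homolog, `b = 20` gives ~80 kbp windows,
about one LD correlation length, which maximises the joint information of
the resampled reads; much larger windows spread the resampled reads
across uncorrelated LD blocks and the conditioning signal dissolves.

The window-coverage fraction `C` (total window length over chromosome
length, `coverageFraction`) measures depth and library complexity at
once; reference samples need `C >= 0.5` and the best-covered candidate
monosomy is chosen (`selectReference`).

## Bootstrap, bins and classification

Within each window, an m-out-of-n bootstrap (`bootstrapWindow`, default
`m = 100` iterations) repeatedly draws, without replacement and with equal
probabilities, up to 6 monosomy and up to 12 disomy informative reads,
computes the subsample LLR, and reports the sample mean and the
Bessel-corrected sample variance. Resampling without replacement respects
the models' assumption about the odds of drawing two reads from one
haplotype.

Windows are aggregated into fixed bins (default 2 Mbp): the bin LLR is
the sum of window means, its variance the sum of window variances
(independent windows), and both are normalized by the window count
(`aggregateBin`). A bin whose confidence interval
`gamma_bin +/- z sqrt(var_bin)` lies entirely above zero is classified
unmatched, entirely below zero matched, otherwise ambiguous
(`classifyBin`, default `z = 1.96`). A bin containing no genomic window is
unclassifiable and counts as ambiguous.

## Crossover detection

Crossovers are read off the cumulative track `y_n` of window mean LLRs
with accumulated variance `v_n` (`cumulativeTrack`): matched segments
drive `y` down, unmatched segments drive it up, so transitions are local
extrema. A window `j` is called (`detectCrossovers`) when it is the
extremum of a region `(i, k)` whose flanks each move by at least
`z sqrt(delta v)` with at least `delta` windows per flank (defaults
`z = 1.96`, `delta = 15`); the confidence `kappa` is the smaller flank
z-score. When two consecutive accepted extrema share a type, the skipped
opposite extremum between them is recovered as the interior window
optimising the difference of its two flank z-scores (`recoverSkipped`);
recovered calls may carry `kappa < z` and are flagged. Resolution is on
the order of the window size (tens to ~150 kbp), set by read sparsity,
heterozygosity and panel LD range.

## Attributing crossovers to samples

A crossover on the shared monosomic reference flips every sibling's track
at the same position and in the same direction. Calls from `n` test
embryos are merged and scanned greedily for direction-consistent clusters
within a region of size `l` (default 5 Mbp), first of size `n`, then
`n - 1`, down to the smallest size exceeding `n / 2`
(`clusterCrossovers`). Cluster means become reference crossovers with
support `lambda = k / n` and confidence `min(kappa)`; when one embryo
contributes several calls to a cluster only the one closest to the
cluster mean is kept. Remaining calls are each embryo's own crossovers
(`attributeCrossovers`).

## The synthetic benchmark generator

`syntheticPanel` builds phased panels as block-wise mosaics of founder
haplotypes: each haplotype copies one of `nFounders` founders per block,
with exponential block lengths (mean 100 kbp, the scale over which human
LD decays to a quarter of its maximum). This induces LD without a
population-genetic simulation and is documented as a structural stand-in,
not a coalescent model. Parameters were fixed from realism arguments
before the benchmarks were run:

* `nFounders = 32`: with few founders, "unrelated" haplotypes share a
  local founder too often (16% of windows at 12 founders), creating long
  spurious IBD between unrelated samples; 32 founders bring the local
  collision rate to a few percent, as expected between unrelated human
  haplotypes, while keeping LD strong.
* site density 1 SNP / 100 bp with a U-shaped `Beta(0.5, 0.5)` allele
  frequency spectrum (floor 0.02): approximates the full biallelic call
  set of a large panel, where abundant low-frequency alleles pin
  haplotypes sharply; restricting to common SNPs alone underpowers the
  likelihoods relative to a real panel.
* `mutationRate` (private allele flips on copied blocks) defaults to 0;
  flips blur the block boundaries that carry the LD signal and do not add
  a mechanism the benchmarks need.

`drawTrio` draws parent / offspring / unrelated haplotype rows (from one
population, or two for recent admixture); `simulateReads` drops
fixed-length reads (default 75 bp single-end) at uniform midpoints,
copying the alleles of a haplotype drawn per read (`p = 1` for the
monosomy, `1/2, 1/2` for the disomy); `simulatePair` and
`simulateSiblingCase` assemble benchmark samples, planting known
crossovers by switching the source row of the shared homolog at given
breakpoints.

What the generator does *not* emulate: sequencing error, GC bias and
amplification artifacts; real LD profiles (block-mosaic LD is sharper than
coalescent LD); ancestry mismatch between sample and panel; and panels
where the sample's haplotypes are absent. Passing benchmarks on synthetic
data therefore demonstrate the statistical machinery under a
well-specified model, not field performance on clinical data.

## Benchmark design and problem sizes

The packaged benchmarks (test suite and `scripts/acceptance.R`) use
500-haplotype panels at 0.05x per homolog:

* *Trinomial classification / balanced ROC*: 14 Mbp chromosome with a
  variant-poor region (relative density 0.17) spanning three of the seven
  2 Mbp bins, emulating pericentromeric SNP deserts; 12 pairs per
  coverage (0.05x / 0.025x / 0.013x), bootstrap `m = 50`. Balanced rates
  average the two one-sided true (false) rates; ambiguous calls count
  toward neither, and the AUC is integrated by trapezoid with (0,0) and
  (1,1) anchors appended, since the balanced curve need not reach them.
  At 0.05x the desert still tiles with near-cap windows; at 0.025x and
  below windows can no longer form inside it, its central bin becomes
  unclassifiable, and the mean AUC degrades with coverage — the same
  mechanism by which performance is lost in variant-poor regions of real
  genomes.
* *Crossover localization*: 100 replicates on 6 Mbp chromosomes, one
  breakpoint planted uniformly in the central 2 Mbp so both flanks hold
  at least ~2x `delta` windows.
* *Attribution*: 50 replicates of four siblings on 4 Mbp chromosomes with
  one crossover planted on the shared reference, `m = 30`.

The reduced bootstrap counts (`m = 50` / `m = 30` instead of the default
100) only widen the Monte-Carlo component of the per-window mean, which
is small against the between-window spread at these read counts.

## Known limitations

* The benchmark generator's mosaic LD is blockier than real LD; absolute
  per-window LLR magnitudes on real panels will be smaller, and windows
  must be sized against the panel's own LD range.
* Bootstrap variance is a subsample-spread estimate: it is zero when a
  window holds no more reads than the resampling caps, so window minima
  well above the caps are a structural requirement, not a tuning choice.
* Crossovers falling in regions without informative windows (SNP deserts,
  dismissed windows) are undetectable in principle; coverage fraction `C`
  bounds how much of a chromosome is scannable.
* Attribution assumes the sibling set shares exactly one reference; with
  only two test embryos the majority rule (`k > n/2`) requires both to
  call, so reference attribution is fragile below three siblings.

## A minimal worked run

```{r example, eval = FALSE}
pan <- syntheticPanel(nHaplotypes = 500, chromLength = 6e6, seed = 1)
case <- simulateSiblingCase(pan, nSiblings = 3, coverage = 0.05,
                            monoBreakpoints = 3e6, seed = 2)
res <- runCase(case$mono, setNames(case$siblings, paste0("s", 1:3)),
               pan, case$composition, chromLength = 6e6, seed = 3)
res$attribution$reference     # the planted reference crossover
```
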