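#' @import methods
#' @importFrom stats rbinom rbeta rexp runif var setNames quantile ecdf qnorm
#' @importFrom utils combn read.delim write.table head tail
NULL

#' ReferencePanel: a phased haplotype reference panel for one chromosome
#'
#' Holds the phased biallelic SNPs of a reference panel restricted to a
#' single chromosome: site positions (1-based, strictly increasing),
#' ref/alt alleles, a 0/1 haplotype matrix (one row per phased haplotype,
#' one column per site), and a population label for every haplotype row.
#' All single- and joint-haplotype frequencies used by the matching models
#' are exact counts over these rows.
#'
#' @slot chrom chromosome identifier.
#' @slot positions integer vector of 1-based site positions, strictly
#'   increasing.
#' @slot ref,alt character vectors of reference / alternative alleles
#'   (single bases).
#' @slot haplotypes integer matrix in \{0,1\}; rows are haplotypes, columns
#'   are sites (0 = ref allele, 1 = alt allele).
#' @slot populations character vector of population labels, one per
#'   haplotype row.
#'
#' @seealso [loadPanelVcf()], [syntheticPanel()], [jointFrequency()]
#' @export
setClass("ReferencePanel",
  representation(
    chrom = "character",
    positions = "integer",
    ref = "character",
    alt = "character",
    haplotypes = "matrix",
    populations = "character"
  )
)

setValidity("ReferencePanel", function(object) {
  msg <- character()
  p <- object@positions
  h <- object@haplotypes
  if (length(object@chrom) != 1L) msg <- c(msg, "chrom must be a single string")
  if (length(p) != ncol(h)) {
    msg <- c(msg, "number of positions must equal number of haplotype columns")
  }
  if (length(p) > 1L && any(diff(p) <= 0L)) {
    msg <- c(msg, "positions must be strictly increasing")
  }
  if (length(object@ref) != length(p) || length(object@alt) != length(p)) {
    msg <- c(msg, "ref and alt must have one entry per site")
  }
  if (length(object@populations) != nrow(h)) {
    msg <- c(msg, "one population label required per haplotype row")
  }
  if (nrow(h) > 0L && ncol(h) > 0L && !all(h == 0L | h == 1L)) {
    msg <- c(msg, "haplotype matrix entries must be 0 or 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReferencePanel
#'
#' @param chrom chromosome identifier.
#' @param positions integer vector of 1-based positions, strictly increasing.
#' @param ref,alt single-base allele vectors, one per site.
#' @param haplotypes 0/1 matrix, rows = haplotypes, columns = sites.
#' @param populations population label per haplotype row.
#' @return a [ReferencePanel-class] object.
#' @examples
#' pan <- ReferencePanel("chr1", c(100L, 200L), c("A", "C"), c("G", "T"),
#'                       rbind(c(0, 1), c(1, 0), c(1, 1), c(0, 0)),
#'                       rep("EUR", 4))
#' nHaplotypes(pan)
#' @export
ReferencePanel <- function(chrom, positions, ref, alt, haplotypes, populations) {
  mode(haplotypes) <- "integer"
  new("ReferencePanel",
      chrom = as.character(chrom), positions = as.integer(positions),
      ref = as.character(ref), alt = as.character(alt),
      haplotypes = haplotypes, populations = as.character(populations))
}

#' AncestryComposition: ancestry proportions of a target sample
#'
#' An ordered set of (population label, weight) pairs describing the
#' ancestry proportions alpha_i of a sample. Weights are non-negative and
#' sum to one; effective haplotype frequencies are the alpha-weighted
#' mixture of per-population frequencies.
#'
#' @slot populations character vector of population labels.
#' @slot weights numeric vector of ancestry proportions (sum to 1).
#' @export
setClass("AncestryComposition",
  representation(populations = "character", weights = "numeric")
)

setValidity("AncestryComposition", function(object) {
  msg <- character()
  if (length(object@populations) != length(object@weights)) {
    msg <- c(msg, "one weight per population required")
  }
  if (length(object@weights) == 0L) msg <- c(msg, "at least one population required")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  if (length(object@weights) && abs(sum(object@weights) - 1) > 1e-9) {
    msg <- c(msg, "weights must sum to 1 (tolerance 1e-9)")
  }
  if (anyDuplicated(object@populations)) msg <- c(msg, "duplicated population label")
  if (length(msg)) msg else TRUE
})

#' Construct an AncestryComposition
#'
#' @param weights named numeric vector of ancestry proportions, e.g.
#'   `c(EUR = 0.3, EAS = 0.7)`; must sum to 1.
#' @return an [AncestryComposition-class] object.
#' @examples
#' AncestryComposition(c(EUR = 0.3, EAS = 0.7))
#' @export
AncestryComposition <- function(weights) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("'weights' must be a named numeric vector of ancestry proportions")
  }
  new("AncestryComposition", populations = names(weights),
      weights = as.numeric(weights))
}

#' SampleReads: one sample's reads reduced to panel-site allele observations
#'
#' Reads of a single sample on a single chromosome, each reduced to its
#' observed alleles at reference-panel sites. `reads` carries one row per
#' read (id, 0-based half-open span, priority score); `observations` one
#' row per (read, site) with the observed allele coded 0 (ref) / 1 (alt).
#' `ploidy` is the per-chromosome ploidy context: 1 for a monosomic or
#' haploid reference sample, 2 for a disomic test sample.
#'
#' @slot sampleId sample identifier.
#' @slot chrom chromosome identifier.
#' @slot ploidy integer, 1 or 2.
#' @slot reads data.frame with columns `read_id`, `start`, `end`
#'   (0-based half-open), `score` (non-negative integer priority score,
#'   NA until scored).
#' @slot observations data.frame with columns `read_id`, `pos` (1-based
#'   panel position), `allele` (0/1), sorted by position within read.
#' @export
setClass("SampleReads",
  representation(
    sampleId = "character",
    chrom = "character",
    ploidy = "integer",
    reads = "data.frame",
    observations = "data.frame"
  )
)

setValidity("SampleReads", function(object) {
  msg <- character()
  if (!object@ploidy %in% c(1L, 2L)) msg <- c(msg, "ploidy must be 1 or 2")
  need <- c("read_id", "start", "end", "score")
  if (!all(need %in% names(object@reads))) {
    msg <- c(msg, sprintf("reads must have columns %s", paste(need, collapse = ", ")))
  }
  needo <- c("read_id", "pos", "allele")
  if (!all(needo %in% names(object@observations))) {
    msg <- c(msg, sprintf("observations must have columns %s", paste(needo, collapse = ", ")))
  }
  if (all(need %in% names(object@reads)) && nrow(object@reads) > 1L &&
      is.unsorted(object@reads$start)) {
    msg <- c(msg, "reads must be sorted by start")
  }
  if (all(needo %in% names(object@observations)) && nrow(object@observations)) {
    if (!all(object@observations$allele %in% c(0L, 1L))) {
      msg <- c(msg, "observed alleles must be 0 or 1")
    }
    if (!all(object@observations$read_id %in% object@reads$read_id)) {
      msg <- c(msg, "observation read_id not present in reads")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SampleReads object
#'
#' @param sampleId sample identifier.
#' @param chrom chromosome identifier.
#' @param ploidy 1 (monosomic/haploid reference) or 2 (disomic test sample).
#' @param reads data.frame with columns `read_id`, `start`, `end` (0-based
#'   half-open) and optionally `score`.
#' @param observations data.frame with columns `read_id`, `pos`, `allele`.
#' @return a [SampleReads-class] object.
#' @export
SampleReads <- function(sampleId, chrom, ploidy, reads, observations) {
  if (is.null(reads$score)) reads$score <- NA_integer_
  reads <- reads[order(reads$start), , drop = FALSE]
  rownames(reads) <- NULL
  observations <- observations[order(match(observations$read_id, reads$read_id),
                                     observations$pos), , drop = FALSE]
  rownames(observations) <- NULL
  observations$allele <- as.integer(observations$allele)
  observations$pos <- as.integer(observations$pos)
  new("SampleReads", sampleId = as.character(sampleId),
      chrom = as.character(chrom), ploidy = as.integer(ploidy),
      reads = reads, observations = observations)
}

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel on", object@chrom, "\n")
  cat("  sites:", length(object@positions), "  haplotypes:",
      nrow(object@haplotypes), "\n")
  tab <- table(object@populations)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  if (length(object@positions)) {
    cat("  span:", min(object@positions), "-", max(object@positions), "bp\n")
  }
  invisible(NULL)
})

setMethod("show", "AncestryComposition", function(object) {
  cat("AncestryComposition:",
      paste(sprintf("%s=%.3g", object@populations, object@weights),
            collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "SampleReads", function(object) {
  cat("SampleReads for sample", object@sampleId, "on", object@chrom,
      "(ploidy", paste0(object@ploidy, ")"), "\n")
  cat("  reads:", nrow(object@reads), "  observations:",
      nrow(object@observations), "\n")
  sc <- object@reads$score
  if (length(sc) && !all(is.na(sc))) {
    cat("  scored:", sum(!is.na(sc)), " (max score ",
        max(sc, na.rm = TRUE), ")\n", sep = "")
  }
  invisible(NULL)
})
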