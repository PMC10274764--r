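# Reference panel loading and exact haplotype-frequency queries.

#' Load a phased reference panel from a VCF
#'
#' Reads phased genotypes from a VCF and returns the biallelic SNPs of one
#' chromosome (optionally restricted to an interval) as a
#' [ReferencePanel-class]. Every diploid sample contributes two haplotype
#' rows. Multi-allelic sites, indels and sites with missing genotypes are
#' excluded (counts reported via `message`); an unphased genotype is an
#' error, since panel haplotypes must be known without ambiguity.
#'
#' @param path path to a VCF (optionally bgzipped).
#' @param chrom chromosome to load.
#' @param populations named character vector mapping sample id to population
#'   label, or a path to a two-column TSV (sample_id, population). Samples
#'   without a label get population `"ALL"`.
#' @param start,end optional 1-based interval limits, both inclusive.
#' @return a [ReferencePanel-class].
#' @examples
#' vcf <- system.file("extdata", "toy_panel.vcf", package = "meioscan")
#' pan <- loadPanelVcf(vcf, chrom = "chr1")
#' pan
#' @export
loadPanelVcf <- function(path, chrom, populations = NULL,
                         start = NULL, end = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  keep <- fix[, "CHROM"] == chrom
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (!is.null(start)) keep <- keep & pos >= start
  if (!is.null(end)) keep <- keep & pos <= end
  if (!any(keep)) stop("no sites on ", chrom, " in the requested region")

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  nonbi <- sum(keep & !snp)
  keep <- keep & snp

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
  if (!nrow(gt)) stop("no biallelic SNPs on ", chrom, " in the requested region")

  unph <- grepl("/", gt, fixed = TRUE)
  dim(unph) <- dim(gt)
  if (any(unph)) {
    i <- which(unph, arr.ind = TRUE)[1, ]
    stop(sprintf("unphased genotype at %s:%d (sample %s)",
                 chrom, pos[i[1]], colnames(gt)[i[2]]))
  }
  miss <- is.na(gt) | gt %in% c(".", ".|.")
  missSite <- apply(miss, 1L, any)
  if (any(missSite)) {
    gt <- gt[!missSite, , drop = FALSE]
    pos <- pos[!missSite]; ref <- ref[!missSite]; alt <- alt[!missSite]
  }
  if (!nrow(gt)) stop("no fully genotyped biallelic SNPs on ", chrom)
  if (nonbi + sum(missSite) > 0) {
    message(sprintf("excluded %d non-biallelic/indel and %d incomplete site(s)",
                    nonbi, sum(missSite)))
  }

  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  if (!all(c(a1, a2) %in% c("0", "1"))) stop("unexpected allele code in GT")
  samples <- colnames(gt)
  nh <- 2L * length(samples)
  hap <- matrix(0L, nrow = nh, ncol = nrow(gt))
  hap[seq(1L, nh, by = 2L), ] <- t(matrix(as.integer(a1), nrow = nrow(gt)))
  hap[seq(2L, nh, by = 2L), ] <- t(matrix(as.integer(a2), nrow = nrow(gt)))

  popmap <- .resolvePopulations(populations)
  pops <- rep("ALL", nh)
  if (length(popmap)) {
    hit <- match(rep(samples, each = 2L), names(popmap))
    pops[!is.na(hit)] <- popmap[hit[!is.na(hit)]]
  }
  o <- order(pos)
  ReferencePanel(chrom, pos[o], ref[o], alt[o], hap[, o, drop = FALSE], pops)
}

.resolvePopulations <- function(populations) {
  if (is.null(populations)) return(character())
  if (is.character(populations) && is.null(names(populations)) &&
      length(populations) == 1L && file.exists(populations)) {
    tab <- read.delim(populations, header = FALSE, stringsAsFactors = FALSE)
    return(setNames(as.character(tab[[2]]), as.character(tab[[1]])))
  }
  if (is.null(names(populations))) stop("'populations' must be named or a TSV path")
  setNames(as.character(populations), names(populations))
}

#' Restrict a panel to a genomic interval
#'
#' @param panel a [ReferencePanel-class].
#' @param start,end 1-based interval, both endpoints inclusive.
#' @return a [ReferencePanel-class] restricted to sites in `[start, end]`.
#' @export
panelRegion <- function(panel, start, end) {
  keep <- panel@positions >= start & panel@positions <= end
  if (!any(keep)) stop("no panel sites in [", start, ", ", end, "]")
  ReferencePanel(panel@chrom, panel@positions[keep], panel@ref[keep],
                 panel@alt[keep], panel@haplotypes[, keep, drop = FALSE],
                 panel@populations)
}

#' Write / read the internal panel cache
#'
#' The cache is a plain-text format holding one chromosome per file: a
#' header with the chromosome and per-haplotype population labels, then one
#' line per site (`pos ref alt` and the packed haplotype column as a 0/1
#' string). Round-trip through the cache is lossless.
#'
#' @param panel a [ReferencePanel-class].
#' @param path file path for the cache.
#' @return `writePanelCache` returns `path` invisibly; `readPanelCache`
#'   returns the [ReferencePanel-class].
#' @export
writePanelCache <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#meioscan-panel\tv1",
               paste0("#chrom\t", panel@chrom),
               paste0("#populations\t", paste(panel@populations, collapse = "\t"))),
             con)
  cols <- apply(panel@haplotypes, 2L, paste, collapse = "")
  writeLines(paste(panel@positions, panel@ref, panel@alt, cols, sep = "\t"), con)
  invisible(path)
}

#' @rdname writePanelCache
#' @export
readPanelCache <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#meioscan-panel")) stop("not a meioscan panel cache")
  chrom <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][2]
  pops <- strsplit(lines[3], "\t", fixed = TRUE)[[1]][-1]
  body <- strsplit(lines[-(1:3)], "\t", fixed = TRUE)
  pos <- as.integer(vapply(body, `[`, "", 1L))
  ref <- vapply(body, `[`, "", 2L)
  alt <- vapply(body, `[`, "", 3L)
  packed <- vapply(body, `[`, "", 4L)
  hap <- vapply(packed, function(s) as.integer(strsplit(s, "")[[1]]),
                integer(length(pops)))
  ReferencePanel(chrom, pos, ref, alt, matrix(hap, nrow = length(pops)), pops)
}

# observations: data.frame/list with pos (1-based panel position) and
# allele (0/1). Returns integer site indices, erroring on unknown sites.
.obsSiteIndex <- function(panel, observations) {
  idx <- match(observations$pos, panel@positions)
  if (anyNA(idx)) {
    stop("position(s) not in panel: ",
         paste(observations$pos[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Joint haplotype frequency within one panel population
#'
#' The fraction of a population's haplotype rows that simultaneously carry
#' every listed allele — the exact counting estimate of the frequency of
#' the haplotype the observations define. An empty observation set returns
#' 1 (vacuous conjunction), so the likelihood models reduce correctly.
#'
#' @param panel a [ReferencePanel-class].
#' @param population a population label present in the panel.
#' @param observations data.frame with columns `pos` (1-based panel
#'   position) and `allele` (0 = ref, 1 = alt). May have zero rows.
#' @return frequency in `[0, 1]`.
#' @examples
#' pan <- syntheticPanel(nHaplotypes = 20, nSites = 50, chromLength = 5e4,
#'                       seed = 1)
#' jointFrequency(pan, "POP1",
#'                data.frame(pos = panelPositions(pan)[1], allele = 1L))
#' @export
jointFrequency <- function(panel, population, observations) {
  rows <- which(panel@populations == population)
  if (!length(rows)) stop("unknown population: ", population)
  if (NROW(observations) == 0L) return(1)
  idx <- .obsSiteIndex(panel, observations)
  sub <- panel@haplotypes[rows, idx, drop = FALSE]
  hit <- sub == matrix(as.integer(observations$allele), nrow = length(rows),
                       ncol = length(idx), byrow = TRUE)
  mean(rowSums(hit) == length(idx))
}

#' Effective (ancestry-weighted) joint haplotype frequency
#'
#' The mixture `sum_i alpha_i * f_i` of per-population joint frequencies,
#' where `alpha_i` are the ancestry proportions of the target sample. With
#' a one-population composition this equals [jointFrequency()] exactly.
#'
#' @param panel a [ReferencePanel-class].
#' @param composition an [AncestryComposition-class] (weights sum to 1).
#' @param observations as in [jointFrequency()].
#' @return frequency in `[0, 1]`.
#' @export
effectiveFrequency <- function(panel, composition, observations) {
  stopifnot(is(composition, "AncestryComposition"))
  validObject(composition)
  f <- vapply(composition@populations, jointFrequency, 0,
              panel = panel, observations = observations)
  sum(composition@weights * f)
}
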