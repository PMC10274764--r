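# Reducing alignments to panel-site allele observations and scoring reads
# by their haplotype information content.

#' Extract panel-site allele observations from a BAM file
#'
#' Reduces aligned reads to their observed alleles at reference-panel
#' sites. Secondary, supplementary, duplicate and unmapped alignments are
#' excluded; alignments below the mapping-quality threshold and bases
#' below the base-quality threshold are dropped; a base matching neither
#' the ref nor the alt allele at a panel site is dropped from that read's
#' observations (the read itself is kept). Paired-end mates sharing a
#' query name are merged into a single read record — all alleles observed
#' on one DNA molecule belong to one haplotype — with the span taken as
#' the union of the mate spans; sites at which mates disagree are dropped.
#'
#' @param bam path to an indexed or unindexed BAM file.
#' @param panel a [ReferencePanel-class]; its chromosome must be present in
#'   the BAM header.
#' @param sampleId sample identifier for the returned object.
#' @param ploidy chromosome ploidy context (1 = monosomic/haploid
#'   reference, 2 = disomic test sample).
#' @param minMapq,minBaseq quality thresholds (defaults 30/30).
#' @return a [SampleReads-class] (scores unset; see [scoreReads()]).
#' @export
extractObservations <- function(bam, panel, sampleId, ploidy = 2L,
                                minMapq = 30L, minBaseq = 30L) {
  chrom <- panel@chrom
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!chrom %in% names(hdr)) {
    stop("chromosome ", chrom, " not present in BAM header (",
         paste(names(hdr), collapse = ", "), ")")
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, mapqFilter = minMapq,
    what = c("qname", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(rec$pos) & as.character(rec$rname) == chrom
  qname <- rec$qname[keep]
  pos <- rec$pos[keep]
  cigar <- rec$cigar[keep]
  seqs <- as.character(rec$seq[keep])
  quals <- as.character(rec$qual[keep])

  sitePos <- panel@positions
  refA <- panel@ref
  altA <- panel@alt
  n <- length(qname)
  obs <- vector("list", n)
  starts0 <- integer(n)
  ends0 <- integer(n)
  if (n) {
    refBlocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar, pos = pos, ops = c("M", "=", "X"))
    qryBlocks <- GenomicAlignments::cigarRangesAlongQuerySpace(
      cigar, ops = c("M", "=", "X"))
    widths <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
    for (i in seq_len(n)) {
      starts0[i] <- pos[i] - 1L
      ends0[i] <- pos[i] - 1L + widths[i]
      rb <- refBlocks[[i]]
      qb <- qryBlocks[[i]]
      lo <- findInterval(pos[i] - 1L, sitePos) + 1L
      hi <- findInterval(ends0[i], sitePos)
      if (lo > hi) next
      rows <- list()
      for (s in lo:hi) {
        p <- sitePos[s]
        k <- which(p >= IRanges::start(rb) & p <= IRanges::end(rb))
        if (!length(k)) next
        qpos <- IRanges::start(qb)[k[1]] + (p - IRanges::start(rb)[k[1]])
        base <- substr(seqs[i], qpos, qpos)
        q <- utf8ToInt(substr(quals[i], qpos, qpos)) - 33L
        if (q < minBaseq) next
        allele <- if (base == refA[s]) 0L else if (base == altA[s]) 1L else NA_integer_
        if (is.na(allele)) next
        rows[[length(rows) + 1L]] <- data.frame(pos = p, allele = allele)
      }
      if (length(rows)) obs[[i]] <- do.call(rbind, rows)
    }
  }

  # merge mates: one molecule per query name
  ids <- unique(qname)
  readRows <- vector("list", length(ids))
  obsRows <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    idx <- which(qname == ids[j])
    readRows[[j]] <- data.frame(read_id = ids[j],
                                start = min(starts0[idx]),
                                end = max(ends0[idx]),
                                score = NA_integer_)
    oo <- do.call(rbind, obs[idx])
    if (!is.null(oo) && nrow(oo)) {
      agg <- split(oo$allele, oo$pos)
      consistent <- vapply(agg, function(a) length(unique(a)) == 1L, TRUE)
      oo <- data.frame(read_id = ids[j],
                       pos = as.integer(names(agg)[consistent]),
                       allele = vapply(agg[consistent], `[`, 0L, 1L))
      obsRows[[j]] <- oo
    }
  }
  reads <- do.call(rbind, readRows)
  if (is.null(reads)) {
    reads <- data.frame(read_id = character(), start = integer(),
                        end = integer(), score = integer())
  }
  observations <- do.call(rbind, obsRows)
  if (is.null(observations)) {
    observations <- data.frame(read_id = character(), pos = integer(),
                               allele = integer())
  }
  SampleReads(sampleId, chrom, ploidy, reads, observations)
}

# site indices a span overlaps: 1-based sites p with start0 < p <= end0
.spanSites <- function(panel, start0, end0) {
  lo <- findInterval(start0, panel@positions) + 1L
  hi <- findInterval(end0, panel@positions)
  if (lo > hi) integer() else lo:hi
}

#' Priority score of a read
#'
#' Counts the common haplotypes of the panel region a read spans: all
#' `2^n` haplotypes over the `n` panel SNPs inside the read span are
#' enumerated, their effective (ancestry-weighted) frequencies computed,
#' and the score is the number with frequency strictly between `f0` and
#' `1 - f0`. The score depends only on panel variation — never on the
#' alleles the read actually carries — and prioritises reads that overlap
#' intermediate-frequency SNPs, whose alleles discriminate haplotypes. A
#' read spanning a single SNP scores 2 when the minor allele frequency
#' exceeds `f0` and 0 otherwise.
#'
#' @param panel a [ReferencePanel-class].
#' @param start,end read span, 0-based half-open.
#' @param composition an [AncestryComposition-class] (a list of two is
#'   averaged, matching a 50/50 recent-admixed sample).
#' @param f0 frequency cutoff, `0 < f0 < 0.5` (default 0.05).
#' @param cap maximum SNPs per read for the enumeration (default 16);
#'   exceeding it is an error rather than a silent truncation.
#' @return non-negative integer score.
#' @export
priorityScore <- function(panel, start, end, composition, f0 = 0.05,
                          cap = 16L) {
  if (f0 <= 0 || f0 >= 0.5) stop("f0 must lie in (0, 0.5)")
  ctx <- .scoreContext(panel, composition)
  .scoreSpan(panel, start, end, ctx, f0, cap)
}

.scoreContext <- function(panel, composition) {
  pair <- .resolvePair(composition)
  w <- pair$a1 / 2
  for (p in names(pair$a2)) w[p] <- (if (p %in% names(w)) w[p] else 0) + pair$a2[p] / 2
  pops <- names(w)[w > 0]
  grp <- .grouping(panel, pops)
  list(pops = pops, weights = unname(w[pops]),
       rowsByPop = lapply(pops, function(p) which(panel@populations == p)))
}

.scoreSpan <- function(panel, start, end, ctx, f0, cap) {
  .scoreSites(panel, .spanSites(panel, start, end), ctx, f0, cap)
}

.scoreSites <- function(panel, idx, ctx, f0, cap) {
  n <- length(idx)
  if (n == 0L) return(0L)
  if (n > cap) {
    stop("read spans ", n, " panel SNPs; enumeration cap is ", cap)
  }
  freq <- numeric(2^n)
  pow <- 2^(seq_len(n) - 1L)
  for (k in seq_along(ctx$pops)) {
    rows <- ctx$rowsByPop[[k]]
    pat <- as.integer(panel@haplotypes[rows, idx, drop = FALSE] %*% pow)
    cnt <- tabulate(pat + 1L, nbins = 2^n)
    freq <- freq + ctx$weights[k] * cnt / length(rows)
  }
  sum(freq > f0 & freq < 1 - f0)
}

#' Score all reads of a sample
#'
#' Applies [priorityScore()] to every read, memoising by spanned site set
#' (reads covering the same SNPs share a score).
#'
#' @param x a [SampleReads-class].
#' @param panel a [ReferencePanel-class].
#' @param composition an [AncestryComposition-class] (or list of two).
#' @param f0 frequency cutoff (default 0.05).
#' @param cap maximum SNPs per read (default 16).
#' @return `x` with the `score` column filled in.
#' @export
scoreReads <- function(x, panel, composition, f0 = 0.05, cap = 16L) {
  if (f0 <= 0 || f0 >= 0.5) stop("f0 must lie in (0, 0.5)")
  ctx <- .scoreContext(panel, composition)
  reads <- x@reads
  if (!nrow(reads)) return(x)
  pos <- as.numeric(panel@positions)
  lo <- findInterval(reads$start, pos) + 1L
  hi <- findInterval(reads$end, pos)
  key <- paste(lo, hi)
  uk <- !duplicated(key)
  cache <- vapply(which(uk), function(i) {
    idx <- if (lo[i] > hi[i]) integer() else lo[i]:hi[i]
    .scoreSites(panel, idx, ctx, f0, cap)
  }, 0L)
  names(cache) <- key[uk]
  reads$score <- as.integer(cache[key])
  methods::initialize(x, reads = reads)
}

#' Filter a sample's reads by priority score
#'
#' @param x a scored [SampleReads-class].
#' @param threshold minimum score; reads with `score >= threshold` are
#'   kept, order preserved.
#' @return a [SampleReads-class] containing the informative reads.
#' @export
selectInformative <- function(x, threshold = 1L) {
  if (anyNA(x@reads$score)) stop("reads are unscored; run scoreReads() first")
  keep <- x@reads$score >= threshold
  reads <- x@reads[keep, , drop = FALSE]
  rownames(reads) <- NULL
  obs <- x@observations[x@observations$read_id %in% reads$read_id, , drop = FALSE]
  rownames(obs) <- NULL
  methods::initialize(x, reads = reads, observations = obs)
}
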