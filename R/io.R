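# Plain-text interchange formats: observation TSV (portable alternative to
# BAM), per-window LLR track TSV, crossover BED and cluster TSV. Writers
# and readers round-trip losslessly.

#' Write / read the portable observation TSV
#'
#' One row per (read, panel site) with columns `sample_id`, `chrom`,
#' `read_id`, `pos` (1-based), `allele` (0/1). Reads with no observations
#' appear once with `pos = -1` and `allele = "."`. On reading, read spans
#' are reconstructed as `[min(pos) - 1, max(pos))` (0-based half-open);
#' under an error-free read simulator every spanned panel site is
#' observed, so scores and windows are unaffected by the reconstruction.
#'
#' @param x a [SampleReads-class] or a list of them.
#' @param path TSV path.
#' @param ploidy for `readObservationTsv`: a single value or a named vector
#'   (by sample id) giving each sample's chromosome ploidy context.
#' @return `writeObservationTsv` returns `path` invisibly;
#'   `readObservationTsv` returns a named list of [SampleReads-class].
#' @export
writeObservationTsv <- function(x, path) {
  if (is(x, "SampleReads")) x <- list(x)
  rows <- lapply(x, function(s) {
    obs <- s@observations
    noObs <- setdiff(s@reads$read_id, unique(obs$read_id))
    df <- data.frame(sample_id = s@sampleId, chrom = s@chrom,
                     read_id = obs$read_id, pos = obs$pos,
                     allele = as.character(obs$allele))
    if (length(noObs)) {
      df <- rbind(df, data.frame(sample_id = s@sampleId, chrom = s@chrom,
                                 read_id = noObs, pos = -1L, allele = "."))
    }
    # canonical order (first observed position, then read id, then
    # position) so that write -> read -> write is byte-identical
    first <- tapply(df$pos, df$read_id, function(p) min(p[p > 0], Inf))
    key <- unname(first[df$read_id])
    df[order(key, df$read_id, df$pos), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeObservationTsv
#' @export
readObservationTsv <- function(path, ploidy = 2L) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(allele = "character"))
  need <- c("sample_id", "chrom", "read_id", "pos", "allele")
  if (!all(need %in% names(tab))) {
    stop("observation TSV must have columns ", paste(need, collapse = ", "))
  }
  bad <- which(!(tab$allele %in% c("0", "1", ".")))
  if (length(bad)) stop("malformed allele at line ", bad[1] + 1L)
  out <- list()
  for (sid in unique(tab$sample_id)) {
    sub <- tab[tab$sample_id == sid, , drop = FALSE]
    pl <- if (length(ploidy) == 1L && is.null(names(ploidy))) ploidy
          else if (sid %in% names(ploidy)) ploidy[[sid]]
          else stop("no ploidy given for sample ", sid)
    hasObs <- sub$allele != "."
    obs <- sub[hasObs, c("read_id", "pos", "allele")]
    obs$allele <- as.integer(obs$allele)
    span <- if (nrow(obs)) {
      do.call(rbind, lapply(split(obs$pos, obs$read_id), range))
    } else matrix(integer(), ncol = 2)
    ids <- unique(sub$read_id)
    reads <- data.frame(read_id = ids, start = 0L, end = 0L,
                        score = NA_integer_)
    hit <- match(reads$read_id, rownames(span))
    reads$start[!is.na(hit)] <- as.integer(span[hit[!is.na(hit)], 1] - 1L)
    reads$end[!is.na(hit)] <- as.integer(span[hit[!is.na(hit)], 2])
    out[[sid]] <- SampleReads(sid, sub$chrom[1], pl, reads, obs)
  }
  out
}

#' Write / read the per-window LLR track TSV
#'
#' Columns: `chrom`, `start`, `end` (0-based half-open), `gamma_mean`,
#' `gamma_var`, `m` (bootstrap subsample count).
#'
#' @param estimates data.frame as returned by [scanChromosome()].
#' @param path TSV path.
#' @return the path (writer, invisibly) or the data.frame (reader).
#' @export
writeLlrTrack <- function(estimates, path) {
  cols <- c("chrom", "start", "end", "gamma_mean", "gamma_var", "m")
  write.table(estimates[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeLlrTrack
#' @export
readLlrTrack <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gamma_mean", "gamma_var", "m")
  if (!all(need %in% names(tab))) {
    stop("LLR track must have columns ", paste(need, collapse = ", "))
  }
  if (anyNA(tab$gamma_mean)) {
    stop("malformed gamma_mean at line ", which(is.na(tab$gamma_mean))[1] + 1L)
  }
  tab
}

#' Write / read the window track TSV
#'
#' Columns: `chrom`, `start`, `end`, `n_mono_reads`, `n_di_reads`.
#'
#' @param windows a `GRanges` from [buildWindows()].
#' @param path TSV path.
#' @return the path (writer, invisibly) or a data.frame (reader).
#' @export
writeWindowTrack <- function(windows, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(windows)),
                   start = GenomicRanges::start(windows) - 1L,
                   end = GenomicRanges::end(windows),
                   n_mono_reads = windows$nMono,
                   n_di_reads = windows$nDi)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWindowTrack
#' @export
readWindowTrack <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "n_mono_reads", "n_di_reads")
  if (!all(need %in% names(tab))) {
    stop("window track must have columns ", paste(need, collapse = ", "))
  }
  tab
}

#' Write / read crossover calls as BED
#'
#' 0-based half-open BED with `name` = sample id, `score` = confidence
#' kappa scaled by 100 and capped at 1000, `strand` = ".", plus
#' `direction` and `kappa` columns.
#'
#' @param calls data.frame of crossover calls (from [detectCrossovers()],
#'   with a `sample_id` column added by the caller, or from [runCase()]).
#' @param path BED path.
#' @return the path (writer, invisibly) or a data.frame (reader).
#' @export
writeCrossoverBed <- function(calls, path) {
  score <- pmin(1000, round(100 * calls$kappa))
  df <- data.frame(chrom = calls$chrom, start = calls$start, end = calls$end,
                   name = calls$sample_id, score = score, strand = ".",
                   direction = calls$direction, kappa = calls$kappa)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeCrossoverBed
#' @export
readCrossoverBed <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 8L) stop("crossover BED must have 8 columns")
  names(tab) <- c("chrom", "start", "end", "sample_id", "score", "strand",
                  "direction", "kappa")
  bad <- which(is.na(tab$start) | is.na(tab$end) | tab$end < tab$start)
  if (length(bad)) stop("malformed interval at line ", bad[1])
  tab
}

#' Write / read the per-cluster attribution TSV
#'
#' Columns: `chrom`, `mean_pos`, `k`, `n`, `lambda`, `kappa_min`,
#' `direction`.
#'
#' @param clusters data.frame from [clusterCrossovers()].
#' @param path TSV path.
#' @return the path (writer, invisibly) or a data.frame (reader).
#' @export
writeClusterTsv <- function(clusters, path) {
  cols <- c("chrom", "mean_pos", "k", "n", "lambda", "kappa_min", "direction")
  write.table(clusters[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeClusterTsv
#' @export
readClusterTsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "mean_pos", "k", "n", "lambda", "kappa_min", "direction")
  if (!all(need %in% names(tab))) {
    stop("cluster TSV must have columns ", paste(need, collapse = ", "))
  }
  tab
}
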