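# Adaptive, non-overlapping genomic windows sized by the local coverage of
# both samples, plus the window-coverage metric used to select reference
# samples.

#' Window-building parameters
#'
#' `b` is the minimum number of informative monosomy reads per window; the
#' disomy must contribute at least `2 * b` (two homologs, so the same
#' minimum per homolog). A forming window is dismissed when the gap
#' between consecutive informative reads of either sample exceeds
#' `maxGap`, or when it reaches `maxLen` without meeting the read minima.
#'
#' The default `b = 20` exceeds the bootstrap resampling caps (6 reads
#' from the monosomy, 12 from the disomy), so each bootstrap draw is a
#' proper subsample and the per-window variance is informative; at the
#' coverages this method targets it also puts windows at the upper end of
#' the 10--100 kbp haplotype scale, comparable to the LD-block length,
#' which balances per-window signal against LD decay.
#'
#' @param b minimum monosomy reads per window (>= 1).
#' @param maxLen maximum window length in bp (default 350000).
#' @param maxGap maximum consecutive-read gap in bp (default 100000).
#' @param scoreThreshold minimum priority score for a read to count as
#'   informative (default 1).
#' @return a `windowSpec` list.
#' @export
windowSpec <- function(b = 20L, maxLen = 350000L, maxGap = 100000L,
                       scoreThreshold = 1L) {
  if (b < 1L) stop("b must be >= 1")
  if (maxLen <= 0) stop("maxLen must be positive")
  structure(list(b = as.integer(b), maxLen = as.numeric(maxLen),
                 maxGap = as.numeric(maxGap),
                 scoreThreshold = as.integer(scoreThreshold)),
            class = "windowSpec")
}

#' Build adaptive genomic windows from two samples' informative reads
#'
#' Scans the informative reads of the monosomic reference and the disomic
#' test sample jointly in the forward direction. A window opens at the
#' first unconsumed read and closes as soon as it holds at least `b`
#' monosomy and `2 * b` disomy reads; its end is the end coordinate of the
#' read that satisfied the last unmet minimum. A forming window is
#' dismissed — and scanning restarts at the read after the trigger — when
#' the start-to-start gap between consecutive reads of one sample exceeds
#' `maxGap`, or when adding a read would extend the window past `maxLen`
#' before the minima are met. Emitted windows are non-overlapping and
#' sorted.
#'
#' @param mono,di scored [SampleReads-class] objects on the same
#'   chromosome (ploidy 1 and 2 respectively). Reads below
#'   `spec$scoreThreshold` are ignored.
#' @param spec a [windowSpec()].
#' @return a `GRanges` (1-based starts internally; exporters write 0-based
#'   half-open) with metadata columns `nMono`, `nDi`, `monoReads`,
#'   `diReads`.
#' @export
buildWindows <- function(mono, di, spec = windowSpec()) {
  if (mono@chrom != di@chrom) stop("samples are on different chromosomes")
  if (mono@ploidy != 1L || di@ploidy != 2L) {
    stop("expected ploidy 1 (mono) and 2 (di)")
  }
  mt <- mono@reads[!is.na(mono@reads$score) &
                     mono@reads$score >= spec$scoreThreshold, , drop = FALSE]
  dt <- di@reads[!is.na(di@reads$score) &
                   di@reads$score >= spec$scoreThreshold, , drop = FALSE]
  ev <- rbind(
    if (nrow(mt)) data.frame(start = mt$start, end = mt$end, sample = 1L,
                             id = mt$read_id) else NULL,
    if (nrow(dt)) data.frame(start = dt$start, end = dt$end, sample = 2L,
                             id = dt$read_id) else NULL)
  out <- list()
  if (!is.null(ev) && nrow(ev)) {
    ev <- ev[order(ev$start, ev$sample), , drop = FALSE]
    n <- nrow(ev)
    i <- 1L
    while (i <= n) {
      winStart <- ev$start[i]
      nm <- 0L; nd <- 0L
      lastStart <- c(NA_real_, NA_real_)
      members <- integer()
      j <- i
      closed <- FALSE
      while (j <= n) {
        s <- ev$sample[j]
        if (!is.na(lastStart[s]) && ev$start[j] - lastStart[s] > spec$maxGap) {
          i <- j + 1L; break                      # gap dismissal
        }
        if (ev$end[j] - winStart > spec$maxLen) {
          i <- j + 1L; break                      # length-cap dismissal
        }
        members <- c(members, j)
        lastStart[s] <- ev$start[j]
        if (s == 1L) nm <- nm + 1L else nd <- nd + 1L
        if (nm >= spec$b && nd >= 2L * spec$b) {
          winEnd <- ev$end[j]
          out[[length(out) + 1L]] <- list(
            start = winStart, end = winEnd,
            mono = ev$id[members[ev$sample[members] == 1L]],
            di = ev$id[members[ev$sample[members] == 2L]])
          # consume reads starting inside the emitted window
          i <- j + 1L
          while (i <= n && ev$start[i] < winEnd) i <- i + 1L
          closed <- TRUE
          break
        }
        j <- j + 1L
      }
      if (j > n && !closed) break                 # ran out of reads
    }
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges(character(), IRanges::IRanges())
    gr$nMono <- integer(); gr$nDi <- integer()
    gr$monoReads <- IRanges::CharacterList()
    gr$diReads <- IRanges::CharacterList()
    return(gr)
  }
  gr <- GenomicRanges::GRanges(
    mono@chrom,
    IRanges::IRanges(start = vapply(out, `[[`, 0, "start") + 1,
                     end = vapply(out, `[[`, 0, "end")))
  gr$nMono <- vapply(out, function(w) length(w$mono), 0L)
  gr$nDi <- vapply(out, function(w) length(w$di), 0L)
  gr$monoReads <- IRanges::CharacterList(lapply(out, `[[`, "mono"))
  gr$diReads <- IRanges::CharacterList(lapply(out, `[[`, "di"))
  gr
}

#' Fraction of a chromosome covered by genomic windows
#'
#' `C = sum(window lengths) / L`: a joint measure of depth of coverage and
#' library complexity. Samples whose windows cover less than half the
#' chromosome are excluded from crossover mapping.
#'
#' @param windows a `GRanges` from [buildWindows()] (must be
#'   non-overlapping).
#' @param L chromosome length in bp.
#' @return list with `C`, `L` and the vector of window lengths.
#' @export
coverageFraction <- function(windows, L) {
  if (length(windows) > 1L) {
    o <- order(GenomicRanges::start(windows))
    s <- GenomicRanges::start(windows)[o]
    e <- GenomicRanges::end(windows)[o]
    if (any(s[-1] <= e[-length(e)])) stop("windows overlap")
  }
  lw <- GenomicRanges::width(windows)
  list(C = sum(lw) / L, L = L, lengths = lw)
}

#' Choose the reference monosomy with the best window coverage
#'
#' Among candidate reference samples, returns the id with the highest
#' window-coverage fraction `C`, requiring `C >= 0.5`; `NULL` when every
#' candidate falls below the threshold. Ties break to the
#' lexicographically smallest sample id.
#'
#' @param candidates named numeric vector (or list of [coverageFraction()]
#'   results) of `C` values keyed by sample id.
#' @param minC minimum acceptable coverage fraction (default 0.5).
#' @return a sample id, or `NULL`.
#' @export
selectReference <- function(candidates, minC = 0.5) {
  if (is.list(candidates)) {
    candidates <- vapply(candidates, function(x) x$C, 0)
  }
  ok <- candidates >= minC
  if (!any(ok)) return(NULL)
  cand <- candidates[ok]
  best <- names(cand)[cand == max(cand)]
  sort(best)[1]
}
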