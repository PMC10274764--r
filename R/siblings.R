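# Attribution of crossovers to the shared reference sample versus the
# individual test embryos, by clustering calls across siblings.
#
# A crossover on the monosomic reference chromosome flips the
# matched/unmatched state of *every* sibling's track at the same position
# and in the same direction, so calls recurring across most siblings are
# attributed to the reference; the remainder are private to each embryo.

#' Cluster crossover calls across sibling embryos
#'
#' Merges the calls of `n` test embryos sharing one reference into a
#' sorted list and scans it greedily for clusters: first groups with calls
#' from all `n` embryos inside a region of size `l`, then size `n - 1`,
#' iterating down to the smallest size exceeding `n / 2`. Candidate
#' clusters are anchored at each call and extend while the span stays
#' within `l`; overlapping candidates resolve to the larger cluster, then
#' the smaller span, then the leftmost. Calls of opposite direction never
#' co-cluster (a reference crossover flips all siblings the same way).
#' When one embryo contributes several calls to a cluster, only the call
#' closest to the cluster mean is kept as a member; the others are marked
#' discarded.
#'
#' @param callsets named list (one element per test embryo) of call
#'   data.frames from [detectCrossovers()] (columns `mid`, `direction`,
#'   `kappa`, plus `chrom`).
#' @param l cluster region size in bp (default 5 Mbp).
#' @return list with `clusters` (data.frame `chrom`, `mean_pos`, `k`, `n`,
#'   `lambda`, `kappa_min`, `direction`) and `members` (data.frame mapping
#'   each input call to a cluster id, with a `status` of `"member"` or
#'   `"discarded"`).
#' @export
clusterCrossovers <- function(callsets, l = 5e6) {
  n <- length(callsets)
  if (n < 2L) stop("clustering needs at least 2 test embryos")
  if (is.null(names(callsets))) names(callsets) <- sprintf("embryo%02d", seq_len(n))
  merged <- do.call(rbind, lapply(names(callsets), function(id) {
    cs <- callsets[[id]]
    if (!NROW(cs)) return(NULL)
    data.frame(embryo = id, chrom = cs$chrom, pos = cs$mid,
               direction = cs$direction, kappa = cs$kappa,
               call_idx = seq_len(nrow(cs)))
  }))
  clusters <- list()
  members <- list()
  if (!is.null(merged) && nrow(merged)) {
    merged <- merged[order(merged$pos), , drop = FALSE]
    merged$taken <- FALSE
    minSize <- floor(n / 2) + 1L
    for (size in seq(n, minSize)) {
      repeat {
        # candidate anchored at each untaken call
        best <- NULL
        for (a in which(!merged$taken)) {
          inWin <- which(!merged$taken &
                           merged$direction == merged$direction[a] &
                           merged$pos >= merged$pos[a] &
                           merged$pos <= merged$pos[a] + l)
          k <- length(unique(merged$embryo[inWin]))
          if (k < size) next
          span <- diff(range(merged$pos[inWin]))
          if (is.null(best) || k > best$k ||
              (k == best$k && (span < best$span ||
                               (span == best$span && merged$pos[a] < best$pos)))) {
            best <- list(idx = inWin, k = k, span = span, pos = merged$pos[a])
          }
        }
        if (is.null(best)) break
        sel <- merged[best$idx, , drop = FALSE]
        mean0 <- mean(sel$pos)
        # one member per embryo: closest to the cluster mean
        chosen <- unlist(lapply(split(seq_len(nrow(sel)), sel$embryo),
                                function(ii) ii[which.min(abs(sel$pos[ii] - mean0))]))
        memberIdx <- best$idx[chosen]
        discardIdx <- setdiff(best$idx, memberIdx)
        cid <- length(clusters) + 1L
        clusters[[cid]] <- data.frame(
          chrom = sel$chrom[1],
          mean_pos = mean(merged$pos[memberIdx]),
          k = length(memberIdx), n = n,
          lambda = length(memberIdx) / n,
          kappa_min = min(merged$kappa[memberIdx]),
          direction = sel$direction[1])
        members[[cid]] <- data.frame(
          cluster = cid,
          embryo = merged$embryo[c(memberIdx, discardIdx)],
          call_idx = merged$call_idx[c(memberIdx, discardIdx)],
          pos = merged$pos[c(memberIdx, discardIdx)],
          status = rep(c("member", "discarded"),
                       c(length(memberIdx), length(discardIdx))))
        merged$taken[best$idx] <- TRUE
      }
    }
  }
  list(clusters = if (length(clusters)) do.call(rbind, clusters) else
         data.frame(chrom = character(), mean_pos = numeric(), k = integer(),
                    n = integer(), lambda = numeric(), kappa_min = numeric(),
                    direction = character()),
       members = if (length(members)) do.call(rbind, members) else
         data.frame(cluster = integer(), embryo = character(),
                    call_idx = integer(), pos = numeric(),
                    status = character()))
}

#' Attribute clustered crossovers to the reference sample
#'
#' Cluster mean positions become the reference sample's crossovers; the
#' member (and discarded duplicate) calls are removed from each embryo's
#' list, and every remaining call is a crossover private to its embryo.
#' Every input call ends up in exactly one of: a cluster membership, a
#' discarded duplicate, or an embryo's residual list.
#'
#' @param callsets as in [clusterCrossovers()].
#' @param clustering result of [clusterCrossovers()]; computed when `NULL`.
#' @param l cluster region size in bp (used when `clustering` is `NULL`).
#' @return list with `reference` (data.frame of reference crossovers:
#'   `chrom`, `mean_pos`, `k`, `n`, `lambda`, `kappa_min`, `direction`)
#'   and `residual` (named list of per-embryo call data.frames).
#' @export
attributeCrossovers <- function(callsets, clustering = NULL, l = 5e6) {
  if (is.null(names(callsets))) {
    names(callsets) <- sprintf("embryo%02d", seq_along(callsets))
  }
  if (is.null(clustering)) clustering <- clusterCrossovers(callsets, l)
  mem <- clustering$members
  residual <- lapply(names(callsets), function(id) {
    cs <- callsets[[id]]
    if (!NROW(cs)) return(cs)
    used <- mem$call_idx[mem$embryo == id]
    cs[!(seq_len(nrow(cs)) %in% used), , drop = FALSE]
  })
  names(residual) <- names(callsets)
  list(reference = clustering$clusters, residual = residual)
}
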