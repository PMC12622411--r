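# Apex-frame and subprototype selection.
#
# Two-step procedure: frames are first ranked by their mean cosine
# similarity to all other frames of the same stimulus condition (keeping
# the top-`shortlist_k` "typical" frames); the shortlist member least
# similar to the neutral baseline frames is then the apex. The two
# criteria -- maximal within-stimulus similarity, minimal baseline
# similarity -- are thereby satisfied lexicographically.

apex_ranking <- function(stim_hogs, baseline_hogs, shortlist_k) {
  ns <- nrow(stim_hogs)
  if (ns < 1 || nrow(baseline_hogs) < 1) {
    stop("need at least one stimulus and one baseline frame")
  }
  if (shortlist_k > ns) {
    warning("shortlist_k clamped from ", shortlist_k, " to ", ns)
    shortlist_k <- ns
  }
  S <- cosine_matrix(stim_hogs)
  within <- if (ns == 1) 1 else (rowSums(S) - diag(S)) / (ns - 1)
  shortlist <- order(-within, seq_len(ns))[seq_len(shortlist_k)]
  base_sim <- rowMeans(cosine_matrix(stim_hogs[shortlist, , drop = FALSE],
                                     baseline_hogs))
  ord <- shortlist[order(base_sim, shortlist)]  # ascending; ties -> earliest
  list(shortlist = sort(shortlist), ranked = ord,
       base_sim = base_sim[order(base_sim, shortlist)])
}

#' Select the apex frame of a stimulus condition
#'
#' @param stim_hogs numeric matrix of stimulus-frame HOG vectors (rows).
#' @param baseline_hogs numeric matrix of neutral baseline HOG vectors.
#' @param shortlist_k shortlist size for the within-stimulus step.
#' @return list with `index` (apex frame row index into `stim_hogs`) and
#'   `shortlist` (the retained frame indices); ties break toward the
#'   earliest frame index.
#' @export
select_apex_frame <- function(stim_hogs, baseline_hogs, shortlist_k = 10) {
  r <- apex_ranking(stim_hogs, baseline_hogs, shortlist_k)
  list(index = r$ranked[1], shortlist = r$shortlist)
}

#' Select the k subprototype frames of a stimulus condition
#'
#' Reuses the two-step apex procedure and returns the `k` shortlist frames
#' least similar to the neutral baseline (ranked by the second-step
#' criterion).
#'
#' @inheritParams select_apex_frame
#' @param k number of subprototype frames.
#' @return integer frame indices (length `min(k, shortlist size)`).
#' @export
select_subprototypes <- function(stim_hogs, neutral_hogs, k = 10,
                                 shortlist_k = max(10, k)) {
  r <- apex_ranking(stim_hogs, neutral_hogs, shortlist_k)
  if (k > length(r$ranked)) {
    warning("k clamped from ", k, " to the shortlist size ",
            length(r$ranked))
    k <- length(r$ranked)
  }
  degenerate <- (length(r$base_sim) > 1 &&
                   diff(range(r$base_sim)) < 1e-12) ||
    (nrow(stim_hogs) == nrow(neutral_hogs) &&
       isTRUE(all.equal(stim_hogs, neutral_hogs, tolerance = 1e-12)))
  if (degenerate) {
    warning("stimulus frames are indistinguishable from the baseline; ",
            "subprototype ranking is degenerate")
  }
  r$ranked[seq_len(k)]
}
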