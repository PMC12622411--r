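#' Pre/post-stimulus facial similarity trace
#'
#' Scores every frame by cosine similarity to the mean pre-stimulus HOG
#' vector; the trough is the minimum over the post-onset window. The
#' normalized variant divides the trace (and trough) by the mean similarity
#' within the reference window itself.
#'
#' @param trial_hogs numeric matrix, frames x features, covering one trial.
#' @param onset_frame first post-stimulus frame index.
#' @param reference_frames indices of the pre-stimulus reference window
#'   (must precede `onset_frame`).
#' @param post_frames indices over which the trough is taken (default: all
#'   frames from onset onward).
#' @return list with `trace`, `trough`, `trough_frame`, `pre_mean` (mean
#'   reference-window similarity) and `normalized_trough`.
#' @export
pre_post_similarity <- function(trial_hogs, onset_frame,
                                reference_frames = seq_len(onset_frame - 1),
                                post_frames = onset_frame:nrow(trial_hogs)) {
  if (length(reference_frames) == 0 || length(post_frames) == 0) {
    stop("reference and post windows must be non-empty")
  }
  if (max(reference_frames) >= onset_frame) {
    stop("reference window must precede the onset")
  }
  ref <- colMeans(trial_hogs[reference_frames, , drop = FALSE])
  trace <- as.numeric(cosine_matrix(trial_hogs, matrix(ref, 1)))
  trough_frame <- post_frames[which.min(trace[post_frames])]
  trough <- trace[trough_frame]
  pre_mean <- mean(trace[reference_frames])
  list(trace = trace, trough = trough, trough_frame = trough_frame,
       pre_mean = pre_mean,
       normalized_trough = trough / pre_mean)
}
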