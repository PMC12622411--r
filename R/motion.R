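#' Motion energy of a frame sequence
#'
#' Per-step motion energy is the mean absolute pixel difference between
#' consecutive frames within a region of interest (normalized by the number
#' of ROI pixels); the per-pixel heatmap is the mean absolute difference of
#' every pixel over the window. Invariant to adding a constant intensity to
#' every frame.
#'
#' @param frames list of grayscale matrices (>= 2).
#' @param roi optional logical matrix selecting the ROI (default: all
#'   pixels).
#' @return object of class `motion_energy`: list with `series` (length
#'   `n_frames - 1`) and `heatmap` (per-pixel mean absolute change).
#' @export
motion_energy <- function(frames, roi = NULL) {
  if (length(frames) < 2) stop("need at least two frames")
  dmn <- dim(frames[[1]])
  if (is.null(roi)) roi <- matrix(TRUE, dmn[1], dmn[2])
  if (!any(roi)) stop("empty ROI")
  n <- length(frames)
  series <- numeric(n - 1)
  heat <- matrix(0, dmn[1], dmn[2])
  for (i in seq_len(n - 1)) {
    d <- abs(frames[[i + 1]] - frames[[i]])
    series[i] <- mean(d[roi])
    heat <- heat + d
  }
  structure(list(series = series, heatmap = heat / (n - 1)),
            class = "motion_energy")
}
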