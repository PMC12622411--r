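# Keypoint tracks, QC, and the ten-feature facial geometry battery.

#' Keypoint track container
#'
#' Per-frame table of 37 named keypoints with x/y pixel coordinates and a
#' tracking confidence in [0, 1].
#'
#' @param coords numeric array `(frames, keypoints, 2)` of x/y coordinates.
#' @param names character vector of keypoint names.
#' @param regions character vector of region assignments.
#' @param fps frame rate (Hz).
#' @param confidence optional `(frames, keypoints)` matrix; defaults to 1.
#' @return object of class `keypoint_track`.
#' @export
keypoint_track <- function(coords, names, regions, fps = 30,
                           confidence = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 2,
            dim(coords)[2] == length(names))
  if (is.null(confidence)) {
    confidence <- matrix(1, dim(coords)[1], dim(coords)[2])
  }
  stopifnot(all(confidence >= 0 & confidence <= 1, na.rm = TRUE))
  structure(list(coords = coords, names = names, regions = regions,
                 fps = fps, confidence = confidence),
            class = "keypoint_track")
}

#' @export
print.keypoint_track <- function(x, ...) {
  cat(sprintf("<keypoint_track> %d frames x %d keypoints @ %g fps\n",
              dim(x$coords)[1], dim(x$coords)[2], x$fps))
  invisible(x)
}

track_point <- function(track, name) {
  j <- match(name, track$names)
  if (is.na(j)) stop("keypoint not found: ", name)
  matrix(track$coords[, j, ], ncol = 2)
}

#' Write / read a pose-estimation keypoint CSV
#'
#' The on-disk dialect uses the three header rows of common pose-estimation
#' exports (scorer / bodyparts / coords with x, y, likelihood triplets).
#'
#' @param track a [keypoint_track()].
#' @param path file path.
#' @param scorer scorer tag written in the first header row.
#' @return `write_dlc_csv()`: `path` invisibly; `read_dlc_csv()`: a
#'   `keypoint_track`.
#' @export
write_dlc_csv <- function(track, path, scorer = "facevalence") {
  n <- dim(track$coords)[1]
  k <- dim(track$coords)[2]
  wide <- matrix(NA_real_, n, 3 * k)
  for (j in seq_len(k)) {
    wide[, 3 * j - 2] <- track$coords[, j, 1]
    wide[, 3 * j - 1] <- track$coords[, j, 2]
    wide[, 3 * j] <- track$confidence[, j]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("scorer", rep(scorer, 3 * k)), collapse = ","), con)
  writeLines(paste(c("bodyparts", rep(track$names, each = 3)),
                   collapse = ","), con)
  writeLines(paste(c("coords", rep(c("x", "y", "likelihood"), k)),
                   collapse = ","), con)
  utils::write.table(cbind(seq_len(n) - 1L, round(wide, 6)), con, sep = ",",
                     col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dlc_csv
#' @param fps frame rate to attach on read (Hz).
#' @export
read_dlc_csv <- function(path, fps = 30) {
  hdr <- readLines(path, n = 3)
  parts <- strsplit(hdr[2], ",")[[1]][-1]
  nms <- parts[seq(1, length(parts), by = 3)]
  dat <- utils::read.csv(path, skip = 3, header = FALSE)
  n <- nrow(dat)
  k <- length(nms)
  coords <- array(NA_real_, c(n, k, 2))
  conf <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    coords[, j, 1] <- dat[[3 * j - 1]]
    coords[, j, 2] <- dat[[3 * j]]
    conf[, j] <- dat[[3 * j + 1]]
  }
  ref <- face_keypoints(face_phenotype())
  regions <- ref$region[match(nms, ref$name)]
  keypoint_track(coords, nms, regions, fps = fps, confidence = conf)
}

#' Quality-control a keypoint track
#'
#' Coordinates with tracking confidence below `conf_threshold` are replaced
#' by linear interpolation between the nearest flanking high-confidence
#' frames (edge gaps are held at the nearest valid value); every coordinate
#' series is then smoothed with a rolling median.
#'
#' @param track a [keypoint_track()].
#' @param conf_threshold confidence below which a frame is discarded.
#' @param median_window odd rolling-median window length (frames).
#' @return cleaned `keypoint_track` (confidences set to 1 where
#'   interpolated); keypoints with no high-confidence frames are dropped to
#'   `NA` with a warning.
#' @export
qc_track <- function(track, conf_threshold = 0.9, median_window = 5) {
  stopifnot(median_window %% 2 == 1)
  n <- dim(track$coords)[1]
  out <- track
  for (j in seq_len(dim(track$coords)[2])) {
    good <- track$confidence[, j] >= conf_threshold
    if (!any(good)) {
      warning("keypoint ", track$names[j],
              " has no high-confidence frames; dropped")
      out$coords[, j, ] <- NA_real_
      out$confidence[, j] <- 0
      next
    }
    for (d in 1:2) {
      x <- track$coords[, j, d]
      if (!all(good)) {
        x <- approx(which(good), x[good], xout = seq_len(n), rule = 2)$y
      }
      if (n >= median_window) {
        x <- as.numeric(runmed(x, median_window, endrule = "median"))
      }
      out$coords[, j, d] <- x
    }
    out$confidence[, j] <- 1
  }
  out
}

#' Compute the ten-feature facial geometry battery
#'
#' Distances are Euclidean; three-point angles are the interior angle at
#' the middle vertex; directional angles are measured against the stated
#' axis in the y-up frame and folded into [0, 180] degrees. The nostril
#' reference for mouth inclination is the centroid of the three nostril
#' keypoints; the whisker angle uses the first whisker's base-to-tip
#' vector; the ear angle uses the ear root as the vector origin.
#'
#' @param track a cleaned [keypoint_track()].
#' @param signed_angles if `TRUE`, directional angles keep their sign
#'   instead of being folded into [0, 180].
#' @return data.frame (one row per frame) with columns `pupil_size`,
#'   `eye_opening`, `mouth_inclination`, `snout_mouth_length`,
#'   `nose_position`, `whisker_angle`, `ear_length`, `ear_angle`,
#'   `ear_width`, `ear_fold`.
#' @export
compute_geometry <- function(track, signed_angles = FALSE) {
  P <- function(nm) track_point(track, nm)
  n <- dim(track$coords)[1]
  d2 <- function(a, b) sqrt(rowSums((a - b)^2))
  ang3 <- function(a, b, c) {
    vapply(seq_len(n), function(i) interior_angle(a[i, ], b[i, ], c[i, ]),
           numeric(1))
  }
  dir_angle <- function(v, axis) {
    vapply(seq_len(n), function(i) {
      if (all(v[i, ] == 0) || anyNA(v[i, ])) return(NA_real_)
      vector_angle(v[i, ], axis = axis, signed = signed_angles)
    }, numeric(1))
  }
  nost <- (P("nostril_1") + P("nostril_2") + P("nostril_3")) / 3
  data.frame(
    pupil_size = d2(P("pupil_u"), P("pupil_d")),
    eye_opening = d2(P("eyelid_up"), P("eyelid_down")),
    mouth_inclination = ang3(nost, P("eyelid_inner"), P("lower_lip")),
    snout_mouth_length = d2(P("nose_tip"), P("lower_lip")),
    nose_position = d2(P("nose_tip"), P("nose_bridge")),
    whisker_angle = dir_angle(P("whisker1_p4") - P("whisker1_p1"), "-x"),
    ear_length = d2(P("pinna_posterior"), P("ear_base")),
    ear_angle = dir_angle(P("pinna_posterior") - P("ear_base"), "+x"),
    ear_width = d2(P("ear_mid_outer"), P("ear_mid_inner")),
    ear_fold = ang3(P("ear_base"), P("pinna_posterior"), P("ear_mid_outer")))
}

#' Map geometry feature names to generator phenotype fields
#'
#' The measured geometry battery names two distance features after what
#' they measure (`pupil_size`, `nose_position`); this helper maps them back
#' to the corresponding generator phenotype fields for recovery checks.
#'
#' @return named character vector, geometry name -> phenotype field.
#' @export
geometry_field_map <- function() {
  c(pupil_size = "pupil_diameter", eye_opening = "eye_opening",
    mouth_inclination = "mouth_inclination",
    snout_mouth_length = "snout_mouth_length",
    nose_position = "nose_extension", whisker_angle = "whisker_angle",
    ear_length = "ear_length", ear_angle = "ear_angle",
    ear_width = "ear_width", ear_fold = "ear_fold")
}

#' Baseline-relative proportional change of a feature series
#'
#' The baseline is the mean over the 4 s window before stimulus onset; the
#' per-frame change is `(value - baseline) / baseline`. In `"peak"` mode
#' the signed extremum (largest absolute change) within the stimulus window
#' is returned as the trial's summary.
#'
#' @param series numeric per-frame feature values.
#' @param onset stimulus onset (s from series start).
#' @param fps frame rate (Hz).
#' @param mode `"peak"` or `"timecourse"`.
#' @param baseline_s baseline window length (s).
#' @param window_s stimulus window for peak extraction, in seconds relative
#'   to onset.
#' @return list with `baseline`, `change` (per-frame proportional change),
#'   `peak` (signed extremum, `"peak"` mode), and `flag` (`"zero_baseline"`
#'   when undefined).
#' @export
change_from_baseline <- function(series, onset, fps,
                                 mode = c("peak", "timecourse"),
                                 baseline_s = 4, window_s = c(0, 2)) {
  mode <- match.arg(mode)
  n <- length(series)
  i_on <- round(onset * fps) + 1
  i_b0 <- max(1, i_on - round(baseline_s * fps))
  if (i_on - i_b0 < 2) stop("need pre-stimulus data for the baseline")
  baseline <- mean(series[i_b0:(i_on - 1)], na.rm = TRUE)
  if (!is.finite(baseline) || baseline == 0) {
    return(list(baseline = baseline, change = rep(NA_real_, n),
                peak = NA_real_, flag = "zero_baseline"))
  }
  change <- (series - baseline) / baseline
  peak <- NA_real_
  if (mode == "peak") {
    iw <- seq(max(1, i_on + round(window_s[1] * fps)),
              min(n, i_on + round(window_s[2] * fps)))
    w <- change[iw]
    peak <- w[which.max(abs(w))]
  }
  list(baseline = baseline, change = change, peak = peak, flag = NA_character_)
}

#' Subtract the temporally nearest water-control change
#'
#' @param change numeric vector (or single value) of per-trial change
#'   scores for a stimulus.
#' @param change_time onset times (s) of those trials.
#' @param water numeric vector of water-trial change scores.
#' @param water_time onset times (s) of the water trials.
#' @return corrected change scores (same length as `change`); equidistant
#'   ties break toward the earlier water trial.
#' @export
water_correct <- function(change, change_time, water, water_time) {
  if (length(water) == 0) stop("no water trials available")
  stopifnot(length(water) == length(water_time),
            length(change) == length(change_time))
  vapply(seq_along(change), function(i) {
    d <- abs(water_time - change_time[i])
    j <- which(d == min(d))
    j <- j[which.min(water_time[j])]  # tie -> earlier trial
    change[i] - water[j]
  }, numeric(1))
}

#' PCA of per-trial keypoint data
#'
#' Columns are z-scored (optional) before principal component analysis;
#' zero-variance columns are dropped with a warning.
#'
#' @param x numeric matrix, trials (or frames) x features.
#' @param z_score z-score columns first.
#' @return list with `scores`, `loadings`, `explained` (variance ratios)
#'   and `kept` (column names retained).
#' @export
keypoint_pca <- function(x, z_score = TRUE) {
  stopifnot(nrow(x) >= 2)
  v <- apply(x, 2, var)
  if (any(v == 0)) {
    warning("dropping zero-variance columns: ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = z_score)
  list(scores = pc$x, loadings = pc$rotation,
       explained = pc$sdev^2 / sum(pc$sdev^2), kept = colnames(x))
}

#' First sustained threshold crossing after stimulus onset
#'
#' Latency is the first post-onset time at which the absolute deviation
#' from the baseline mean exceeds `threshold_sd` baseline standard
#' deviations for at least `sustain` consecutive frames.
#'
#' @param series numeric per-frame feature values.
#' @param onset stimulus onset (s from series start).
#' @param fps frame rate (Hz).
#' @param threshold_sd threshold in baseline standard deviations.
#' @param sustain minimum run length (frames).
#' @param baseline_s baseline window length (s).
#' @param fallback_abs absolute threshold used when the baseline standard
#'   deviation is zero (flagged).
#' @return list with `latency_s` (`NA` if never crossed) and `flag`.
#' @export
response_latency <- function(series, onset, fps, threshold_sd = 2,
                             sustain = 3, baseline_s = 4,
                             fallback_abs = 1e-8) {
  n <- length(series)
  i_on <- round(onset * fps) + 1
  i_b0 <- max(1, i_on - round(baseline_s * fps))
  base <- series[i_b0:(i_on - 1)]
  mu <- mean(base, na.rm = TRUE)
  s <- sd(base)
  flag <- NA_character_
  thr <- threshold_sd * s
  if (!is.finite(s) || s == 0) {
    thr <- fallback_abs
    flag <- "zero_baseline_sd"
  }
  dev <- abs(series - mu) > thr
  dev[seq_len(i_on - 1)] <- FALSE
  r <- rle(dev)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= sustain)
  if (length(hit) == 0) {
    return(list(latency_s = NA_real_, flag = flag))
  }
  i_first <- ends[hit[1]] - r$lengths[hit[1]] + 1
  list(latency_s = (i_first - i_on) / fps, flag = flag)
}
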