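# Trial-level dynamics of the synthetic generator.
#
# Each facial feature follows baseline -> latency-delayed saturating rise
# toward (baseline + stimulus offset) during the stimulus -> exponential
# return, plus per-frame white feature noise. Frames are rendered lazily
# from the per-frame feature matrix; the ground-truth keypoint track is
# computed analytically.

# activation in [0, 1] at time t (s, relative to onset)
response_curve <- function(t, latency, rise, decay, stim_dur) {
  a <- numeric(length(t))
  on <- t >= latency
  a[on] <- 1 - exp(-(t[on] - latency) / rise)
  t_peak <- max(stim_dur, latency + 2 * rise)
  post <- t > t_peak
  a[post] <- a[post] * 0 + (1 - exp(-(t_peak - latency) / rise)) *
    exp(-(t[post] - t_peak) / decay)
  a
}

#' Simulate one stimulus trial of a synthetic session
#'
#' @param base baseline [face_phenotype()] of the mouse.
#' @param effects a [valence_effects()] specification.
#' @param stimulus one of [stimulus_labels()].
#' @param spec a [cohort_spec()].
#' @param seed integer seed for the per-frame feature noise.
#' @param track if `FALSE`, skip the analytic keypoint track (cheaper when
#'   only rendered frames or feature trajectories are needed).
#' @return object of class `trial_fixture`: list with `time` (s), `onset_s`,
#'   `stimulus`, `valence`, `features` (frames x 10 matrix of ground-truth
#'   feature trajectories), `track` (a [keypoint_track()]), `phenotypes`
#'   (per-frame perturbed phenotypes kept implicitly via `features`),
#'   `base`, and `spec`.
#' @export
simulate_trial <- function(base, effects, stimulus, spec, seed = 0,
                           track = TRUE) {
  if (!stimulus %in% stimulus_labels()) {
    stop("unknown stimulus label: ", stimulus)
  }
  fps <- spec$fps
  n <- round((spec$pre_s + spec$stimulus_duration + spec$post_s) * fps)
  time <- (seq_len(n) - 1) / fps
  onset <- spec$pre_s
  off <- effects$offsets[[stimulus]]
  fields <- phenotype_fields()

  feat <- matrix(NA_real_, n, length(fields),
                 dimnames = list(NULL, fields))
  noise <- with_seed(seed, matrix(rnorm(n * length(fields),
                                        sd = effects$noise_sd),
                                  n, length(fields)))
  for (j in seq_along(fields)) {
    f <- fields[j]
    a <- response_curve(time - onset, effects$latency[[f]], effects$rise,
                        effects$decay, spec$stimulus_duration)
    o <- if (f %in% names(off)) off[[f]] else 0
    feat[, j] <- base[[f]] + o * a + noise[, j]
  }

  # analytic ground-truth keypoints per frame
  trk <- NULL
  if (isTRUE(track)) {
    coords <- array(NA_real_, c(n, 37, 2))
    kp0 <- NULL
    for (i in seq_len(n)) {
      ph <- perturb_phenotype(base, feat[i, ] - unlist(base[fields]))
      kp <- face_keypoints(ph, spec$frame_size)
      if (is.null(kp0)) kp0 <- kp
      coords[i, , 1] <- kp$x
      coords[i, , 2] <- kp$y
    }
    trk <- keypoint_track(coords, names = kp0$name, regions = kp0$region,
                          fps = fps)
  }

  structure(list(time = time, onset_s = onset, stimulus = stimulus,
                 valence = stimulus_valence()[[stimulus]],
                 features = feat, track = trk, base = base, spec = spec),
            class = "trial_fixture")
}

#' Render selected frames of a simulated trial
#'
#' @param trial a `trial_fixture` from [simulate_trial()].
#' @param frames integer frame indices (default all).
#' @param canvas canvas side (px); defaults to the trial's `frame_size`.
#' @return list of grayscale matrices.
#' @export
render_trial <- function(trial, frames = seq_along(trial$time),
                         canvas = trial$spec$frame_size) {
  fields <- phenotype_fields()
  base_v <- unlist(trial$base[fields])
  lapply(frames, function(i) {
    ph <- perturb_phenotype(trial$base, trial$features[i, ] - base_v)
    render_face(ph, canvas)$image
  })
}

#' Frame indices of a trial window
#'
#' @param trial a `trial_fixture`.
#' @param window numeric length-2 window in seconds relative to stimulus
#'   onset.
#' @return integer frame indices.
#' @export
trial_window_frames <- function(trial, window = c(0, 2)) {
  which(trial$time - trial$onset_s >= window[1] &
          trial$time - trial$onset_s < window[2])
}
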