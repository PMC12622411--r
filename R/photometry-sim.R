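# Synthetic dual-channel fiber photometry.
#
# The 470 nm channel is a slow photobleaching trend plus a motion artifact
# shared with the 410 nm isosbestic channel plus per-event calcium
# transients (instant rise, exponential decay) whose amplitudes follow the
# neuron-type tuning reported for the ventral tegmental area: dopaminergic
# populations respond to positive valence, GABAergic to negative valence,
# glutamatergic to arousal, pan-neuronal equally to everything. The 410 nm
# channel carries the bleaching trend and the artifact but no transients.

#' Per-stimulus transient amplitude tables by neuron type
#'
#' Units are arbitrary fluorescence; only the orderings are meaningful:
#' DA sucrose > NaCl > water > bitterness/shock; GABA shock/bitterness >
#' water > sucrose/NaCl; Glu sucrose, shock > NaCl, bitterness; pan equal.
#'
#' @return named list of named amplitude vectors.
#' @export
neuron_amplitudes <- function() {
  list(DA   = c(sucrose = 10, nacl = 7, water = 3, bitter = 1, shock = 1),
       GABA = c(sucrose = 1.5, nacl = 1, water = 3, bitter = 8, shock = 10),
       Glu  = c(sucrose = 9, nacl = 4, water = 3, bitter = 4, shock = 9),
       pan  = c(sucrose = 5, nacl = 5, water = 5, bitter = 5, shock = 5))
}

#' Simulate a dual-channel photometry recording
#'
#' @param neuron_type one of `"DA"`, `"GABA"`, `"Glu"`, `"pan"`.
#' @param events data.frame with columns `onset_s` and `stimulus`.
#' @param duration_s total recording length (s); defaults to the last onset
#'   plus 20 s.
#' @param fs per-channel sampling rate (Hz).
#' @param f0 initial 470 nm fluorescence (a.u.).
#' @param bleach_tau photobleaching time constant (s); `Inf` disables.
#' @param bleach_floor asymptotic fraction of `f0` that survives bleaching.
#' @param artifact_sd standard deviation of the shared motion artifact.
#' @param artifact_tau autocorrelation time of the artifact (s).
#' @param noise_sd white measurement noise per channel.
#' @param transient_tau calcium transient decay constant (s).
#' @param iso_gain multiplicative gain of the 410 nm bleaching trend.
#' @param seed integer seed.
#' @return object of class `photometry_recording`: `time`, `f470`, `f410`,
#'   `fs`, `events`, and `ground_truth` (noiseless transient component and
#'   per-event amplitudes).
#' @export
simulate_photometry <- function(neuron_type, events, duration_s = NULL,
                                fs = 15, f0 = 100, bleach_tau = 600,
                                bleach_floor = 0.7, artifact_sd = 1,
                                artifact_tau = 0.5, noise_sd = 0.3,
                                transient_tau = 1, iso_gain = 0.8,
                                seed = 0) {
  amps <- neuron_amplitudes()
  if (!neuron_type %in% names(amps)) {
    stop("unknown neuron_type: ", neuron_type)
  }
  if (is.null(events) || nrow(events) == 0) stop("events must be non-empty")
  if (!all(events$stimulus %in% stimulus_labels())) {
    stop("unknown stimulus label in events")
  }
  duration_s <- duration_s %||% (max(events$onset_s) + 20)
  n <- round(duration_s * fs)
  time <- (seq_len(n) - 1) / fs

  bleach <- if (is.finite(bleach_tau)) {
    f0 * (bleach_floor + (1 - bleach_floor) * exp(-time / bleach_tau))
  } else rep(f0, n)

  amp_tab <- amps[[neuron_type]]
  ev_amp <- amp_tab[events$stimulus]
  transient <- numeric(n)
  for (i in seq_len(nrow(events))) {
    on <- events$onset_s[i]
    idx <- which(time >= on)
    transient[idx] <- transient[idx] +
      ev_amp[i] * exp(-(time[idx] - on) / transient_tau)
  }

  sig <- with_seed(seed, {
    w <- rnorm(n)
    rho <- exp(-1 / (fs * artifact_tau))
    art <- as.numeric(stats::filter(w, rho, method = "recursive"))
    s <- sd(art)
    art <- if (s > 0) art / s * artifact_sd else art * 0
    list(art = art, n470 = rnorm(n, sd = noise_sd),
         n410 = rnorm(n, sd = noise_sd))
  })

  f470 <- bleach + sig$art + transient + sig$n470
  f410 <- iso_gain * bleach + sig$art + sig$n410

  structure(list(time = time, f470 = f470, f410 = f410, fs = fs,
                 events = events,
                 ground_truth = list(transient = transient,
                                     amplitudes = unname(ev_amp),
                                     artifact = sig$art, bleach = bleach)),
            class = "photometry_recording")
}

#' Simulate a photometry recording coupled to a facial similarity trace
#'
#' Builds a session in which a shared latent drive (the noiseless calcium
#' transient component) appears both in the 470 nm channel and, scaled and
#' noise-corrupted, in a facial valence-similarity timecourse sampled at
#' video rate. Used to validate the neural-facial correlation analysis.
#'
#' @inheritParams simulate_photometry
#' @param coupling gain from latent drive to facial similarity (0 = fully
#'   independent).
#' @param facial_noise_sd white noise on the facial similarity trace.
#' @param video_fps facial sampling rate (Hz).
#' @return list with `recording` (a `photometry_recording`), `facial`
#'   (numeric similarity trace), `facial_time` (s) and `events`.
#' @export
simulate_coupled_session <- function(neuron_type = "DA", events,
                                     coupling = 0.08, facial_noise_sd = 0.15,
                                     video_fps = 30, seed = 0, ...) {
  rec <- simulate_photometry(neuron_type, events, seed = seed, ...)
  nf <- round(max(rec$time) * video_fps) + 1
  ft <- (seq_len(nf) - 1) / video_fps
  latent <- approx(rec$time, rec$ground_truth$transient, xout = ft,
                   rule = 2)$y
  facial <- with_seed(derive_seed(seed, "facial"),
                      coupling * latent + rnorm(nf, sd = facial_noise_sd))
  list(recording = rec, facial = facial, facial_time = ft,
       events = rec$events)
}
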