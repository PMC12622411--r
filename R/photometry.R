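# Dual-channel fiber photometry processing: adaptive iteratively
# reweighted penalized-least-squares (airPLS) baseline drift removal,
# isosbestic motion correction by least-squares regression, dF/F,
# peristimulus averages, water-normalized peak ratios, and the
# permutation-tested correlation between neural signal and facial valence
# similarity.

# Whittaker smoother solve: (W + lambda D'D) z = W y  (sparse Cholesky)
whittaker_solve <- function(y, w, lambda) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  Wm <- Matrix::Diagonal(n, w)
  A <- Wm + lambda * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, w * y))
}

#' Asymmetric penalized-least-squares baseline estimate
#'
#' Adaptive iteratively reweighted penalized least squares: a Whittaker
#' smoother whose weights shrink exponentially where the trace exceeds the
#' current baseline, so positive transients are ignored while the slow
#' drift is followed.
#'
#' @param trace numeric signal (length >= 10).
#' @param lambda smoothness penalty (larger = stiffer baseline).
#' @param max_iter maximum reweighting iterations.
#' @return list with `baseline`, `converged`, `iterations`.
#' @export
airpls_baseline <- function(trace, lambda = 1e8, max_iter = 50) {
  n <- length(trace)
  if (n < 10) stop("trace too short for baseline estimation")
  w <- rep(1, n)
  z <- trace
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    z <- whittaker_solve(trace, w, lambda)
    d <- trace - z
    neg <- d < 0
    ssn <- sum(abs(d[neg]))
    if (ssn == 0 || ssn < 1e-3 * sum(abs(trace))) {
      converged <- TRUE
      break
    }
    w_new <- numeric(n)
    w_new[neg] <- exp(it * abs(d[neg]) / ssn)
    w_new[1] <- w_new[n] <- max(w_new)
    if (all(abs(w_new - w) < 1e-12)) {
      converged <- TRUE
      break
    }
    w <- w_new
  }
  list(baseline = z, converged = converged, iterations = it)
}

#' Isosbestic motion correction and dF/F
#'
#' Ordinary least-squares fit of the 410 nm control onto the 470 nm
#' signal; the fitted control is subtracted and dF/F is the corrected
#' signal divided by the fitted control. Channels are typically detrended
#' (baseline-subtracted with the trend's offset retained) beforehand.
#'
#' @param f470,f410 numeric channel vectors of equal length.
#' @return object of class `corrected_trace`: list with `fitted_control`,
#'   `corrected`, `dff`, regression coefficients `a`, `b`, and `flag`
#'   (`"degenerate_control"` when the 410 nm channel is constant and a
#'   mean-only fit was used).
#' @export
motion_correct <- function(f470, f410) {
  stopifnot(length(f470) == length(f410))
  flag <- NA_character_
  if (sd(f410) < 1e-12) {
    a <- 0
    b <- mean(f470)
    flag <- "degenerate_control"
  } else {
    fit <- lm(f470 ~ f410)
    a <- coef(fit)[[2]]
    b <- coef(fit)[[1]]
  }
  fitted_control <- a * f410 + b
  corrected <- f470 - fitted_control
  dff <- rep(NA_real_, length(f470))
  ok <- fitted_control != 0
  dff[ok] <- corrected[ok] / fitted_control[ok]
  structure(list(fitted_control = fitted_control, corrected = corrected,
                 dff = dff, a = a, b = b, flag = flag),
            class = "corrected_trace")
}

#' Full processing of a dual-channel recording to dF/F
#'
#' Removes the slow drift of both channels with [airpls_baseline()]
#' (subtracting the trend but retaining its median level so the traces stay
#' on their physical scale), then applies [motion_correct()].
#'
#' @param rec a `photometry_recording` (or list with `f470`, `f410`).
#' @param lambda airPLS smoothness.
#' @return a `corrected_trace` with added elements `time` and `fs`.
#' @export
process_photometry <- function(rec, lambda = 1e8) {
  b470 <- airpls_baseline(rec$f470, lambda)$baseline
  b410 <- airpls_baseline(rec$f410, lambda)$baseline
  d470 <- rec$f470 - b470 + median(b470)
  d410 <- rec$f410 - b410 + median(b410)
  ct <- motion_correct(d470, d410)
  ct$time <- rec$time
  ct$fs <- rec$fs
  ct
}

#' Peristimulus time histogram of a dF/F trace
#'
#' Each trial is baseline-subtracted (mean of the `pre_s` window before
#' onset) and the per-trial peak is the maximum within the post window.
#'
#' @param dff numeric dF/F trace.
#' @param time_s timestamps (s) of `dff`.
#' @param events data.frame with `onset_s` (and optionally `stimulus`).
#' @param pre_s baseline window (s).
#' @param post_s post-onset window (s).
#' @return object of class `psth_result`: `trials` (trials x time matrix),
#'   `t_rel` (s), `mean_trace`, `peaks`, `peak_times`, `stimulus`.
#' @export
compute_psth <- function(dff, time_s, events, pre_s = 4, post_s = 10) {
  fs <- 1 / median(diff(time_s))
  npre <- round(pre_s * fs)
  npost <- round(post_s * fs)
  if (any(events$onset_s - pre_s < time_s[1])) {
    stop("every event needs a full pre-stimulus window")
  }
  if (nrow(events) > 1 &&
      any(diff(sort(events$onset_s)) < pre_s + post_s)) {
    warning("peristimulus windows overlap between trials")
  }
  t_rel <- (seq_len(npre + npost + 1) - npre - 1) / fs
  rows <- lapply(seq_len(nrow(events)), function(i) {
    i0 <- which.min(abs(time_s - events$onset_s[i]))
    idx <- (i0 - npre):(i0 + npost)
    if (max(idx) > length(dff)) {
      return(NULL)
    }
    tr <- dff[idx]
    tr - mean(tr[seq_len(npre)])
  })
  keep <- !vapply(rows, is.null, logical(1))
  trials <- do.call(rbind, rows[keep])
  post_idx <- which(t_rel >= 0)
  peaks <- apply(trials[, post_idx, drop = FALSE], 1, max)
  peak_t <- t_rel[post_idx][apply(trials[, post_idx, drop = FALSE], 1,
                                  which.max)]
  structure(list(trials = trials, t_rel = t_rel,
                 mean_trace = colMeans(trials), peaks = peaks,
                 peak_times = peak_t,
                 stimulus = events$stimulus[keep] %||% NULL),
            class = "psth_result")
}

#' Stimulus peak response normalized to the water response
#'
#' @param stim_peaks numeric per-trial peaks for a stimulus.
#' @param water_peaks numeric per-trial peaks for the water control.
#' @return ratio of mean stimulus peak to mean water peak.
#' @export
peak_ratio_vs_water <- function(stim_peaks, water_peaks) {
  mw <- mean(water_peaks)
  if (!is.finite(mw) || mw <= 0) {
    stop("water peak must be positive for normalization")
  }
  mean(stim_peaks) / mw
}

#' Permutation-tested correlation between neural and facial signals
#'
#' Pools all timepoints within the post-onset windows of the given events,
#' computes the Spearman rank correlation between the z-scored dF/F and
#' the facial valence-similarity trace (both on the photometry clock), and
#' builds a one-sided permutation null by shuffling the pooled facial
#' samples (or circularly shifting them). The p-value uses the add-one
#' estimator `p = (1 + #{shuffled >= observed}) / (1 + n_shuffles)`.
#'
#' @param z_dff numeric z-scored dF/F samples on the photometry clock.
#' @param facial numeric facial similarity samples, same clock and length
#'   (use [resample_to_rate()] for 30 fps video traces).
#' @param time_s shared timestamps (s).
#' @param events data.frame with `onset_s`.
#' @param window_s post-onset window pooled per event (s).
#' @param n_shuffles permutation count.
#' @param mode `"permute"` (shuffle pooled facial samples) or `"shift"`
#'   (circular shift of the facial series).
#' @param seed integer seed.
#' @return object of class `shuffle_corr`: `rho`, `p`, `null` (permutation
#'   distribution), `n_points`, `n_shuffles`, `seed`.
#' @export
neural_facial_correlation <- function(z_dff, facial, time_s, events,
                                      window_s = 2, n_shuffles = 1000,
                                      mode = c("permute", "shift"),
                                      seed = 0) {
  mode <- match.arg(mode)
  stopifnot(length(z_dff) == length(facial),
            length(z_dff) == length(time_s))
  sel <- rep(FALSE, length(time_s))
  for (on in events$onset_s) {
    sel <- sel | (time_s >= on & time_s < on + window_s)
  }
  x <- z_dff[sel]
  y <- facial[sel]
  if (length(x) < 10) stop("fewer than 10 pooled timepoints")
  rho <- cor(x, y, method = "spearman")
  rx <- rank(x)
  null <- with_seed(seed, vapply(seq_len(n_shuffles), function(s) {
    ys <- if (mode == "permute") {
      sample(y)
    } else {
      k <- sample.int(length(y) - 1, 1)
      y[c((k + 1):length(y), 1:k)]
    }
    cor(rx, rank(ys))
  }, numeric(1)))
  p <- (1 + sum(null >= rho)) / (1 + n_shuffles)
  structure(list(rho = rho, p = p, null = null, n_points = length(x),
                 n_shuffles = n_shuffles, seed = seed),
            class = "shuffle_corr")
}

#' Resample a video-rate trace onto the photometry clock
#'
#' Maps a 30 fps facial series to the 15 Hz neural clock by averaging
#' consecutive frame pairs (or, generally, by block-averaging the integer
#' rate ratio).
#'
#' @param x numeric series at `from_rate`.
#' @param from_rate source rate (Hz).
#' @param to_rate target rate (Hz); `from_rate / to_rate` must be a whole
#'   number.
#' @return numeric series at `to_rate`.
#' @export
resample_to_rate <- function(x, from_rate = 30, to_rate = 15) {
  r <- from_rate / to_rate
  if (abs(r - round(r)) > 1e-9) stop("rate ratio must be an integer")
  r <- round(r)
  n <- floor(length(x) / r)
  colMeans(matrix(x[seq_len(n * r)], r, n))
}

#' Read and write photometry trace CSV files
#'
#' Column layout `time_s, f470, f410`.
#'
#' @param path CSV path.
#' @param fs sampling rate attached on read (Hz); default inferred.
#' @param events optional event table attached on read.
#' @return a `photometry_recording`.
#' @export
read_photometry_csv <- function(path, fs = NULL, events = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "f470", "f410") %in% names(d)))
  structure(list(time = d$time_s, f470 = d$f470, f410 = d$f410,
                 fs = fs %||% (1 / median(diff(d$time_s))),
                 events = events, ground_truth = NULL),
            class = "photometry_recording")
}
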