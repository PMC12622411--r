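# Keypoint QC and the ten-feature geometry battery.

toy_track <- function(x_series, conf = NULL, fps = 30) {
  n <- length(x_series)
  coords <- array(0, c(n, 2, 2))
  coords[, 1, 1] <- x_series
  coords[, 1, 2] <- 5
  coords[, 2, 1] <- 1
  coords[, 2, 2] <- 1
  keypoint_track(coords, c("kp_a", "kp_b"), c("ear", "ear"), fps = fps,
                 confidence = conf)
}

test_that("track QC interpolates, smooths and is idempotent", {
  # all confident + constant -> no-op
  tk <- toy_track(rep(10, 8))
  expect_equal(qc_track(tk)$coords, tk$coords)

  # a low-confidence frame is linearly interpolated (midpoint)
  x <- c(10, 10, 10, 10, 999, 14, 14, 14, 14)
  conf <- matrix(1, 9, 2)
  conf[5, 1] <- 0.2
  out <- qc_track(toy_track(x, conf), median_window = 1)
  expect_equal(out$coords[5, 1, 1], 12)

  # a single-frame impulse is removed by the 5-frame median
  x2 <- rep(20, 11)
  x2[6] <- 70
  out2 <- qc_track(toy_track(x2))
  expect_equal(out2$coords[, 1, 1], rep(20, 11))
  # direct filter oracle
  expect_equal(out2$coords[, 1, 1],
               as.numeric(stats::runmed(x2, 5, endrule = "median")))

  # idempotent on its own output: exactly for the interpolation stage,
  # and for filtered series whose roots the median filter has reached
  co <- tracked_cohort()
  tr <- cohort_trials(co)[[1]]
  conf <- tr$track$confidence
  conf[seq(5, nrow(conf), by = 9), ] <- 0.5
  noisy <- tr$track
  noisy$confidence <- conf
  once_i <- qc_track(noisy, median_window = 1)
  twice_i <- qc_track(once_i, median_window = 1)
  expect_equal(twice_i$coords, once_i$coords, tolerance = 1e-12)
  once <- qc_track(toy_track(c(rep(20, 6), 77, rep(20, 6))))
  twice <- qc_track(once)
  expect_equal(twice$coords, once$coords, tolerance = 1e-12)

  # keypoint with no confident frames is dropped with a warning
  conf0 <- matrix(1, 8, 2)
  conf0[, 1] <- 0.1
  expect_warning(d <- qc_track(toy_track(rep(3, 8), conf0)),
                 "no high-confidence")
  expect_true(all(is.na(d$coords[, 1, ])))
})

test_that("geometry features match closed-form constructions", {
  # pupil distance
  coords <- array(0, c(1, 37, 2))
  kp <- face_keypoints(face_phenotype(), 256)
  coords[1, , 1] <- kp$x
  coords[1, , 2] <- kp$y
  tk <- keypoint_track(coords, kp$name, kp$region)
  i_u <- match("pupil_u", kp$name); i_d <- match("pupil_d", kp$name)
  tk$coords[1, i_u, ] <- c(0, 10)
  tk$coords[1, i_d, ] <- c(0, 2)
  g <- compute_geometry(tk)
  expect_equal(g$pupil_size, 8)

  # collinear mouth points -> straight angle
  tk2 <- keypoint_track(coords, kp$name, kp$region)
  for (nm in c("nostril_1", "nostril_2", "nostril_3")) {
    tk2$coords[1, match(nm, kp$name), ] <- c(10, 50)
  }
  tk2$coords[1, match("eyelid_inner", kp$name), ] <- c(20, 50)
  tk2$coords[1, match("lower_lip", kp$name), ] <- c(30, 50)
  expect_equal(compute_geometry(tk2)$mouth_inclination, 180)

  # ear angle via the atan2 oracle, y-up convention
  tk3 <- keypoint_track(coords, kp$name, kp$region)
  tk3$coords[1, match("ear_base", kp$name), ] <- c(100, 100)
  tk3$coords[1, match("pinna_posterior", kp$name), ] <- c(101, 99)
  expect_equal(compute_geometry(tk3)$ear_angle,
               atan2(1, 1) * 180 / pi, tolerance = 1e-12)

  # full-phenotype recovery on a noiseless trial at the reference canvas
  spec <- cohort_spec(n_mice = 1, fps = 10, frame_size = 256, seed = 0)
  tr <- simulate_trial(face_phenotype(),
                       valence_effects(noise_sd = 0, identity_sd = 0),
                       "nacl", spec, seed = 1)
  gg <- compute_geometry(tr$track)
  fm <- geometry_field_map()
  expect_lt(max(abs(as.matrix(gg) - tr$features[, fm[colnames(gg)]])),
            1e-6)
})

test_that("lengths are rigid-motion invariant; angles shift by rotation", {
  co <- tracked_cohort()
  tk <- cohort_trials(co)[[1]]$track
  rot <- 20
  tf <- compose_transforms(similarity_matrix(1, rot, 30, -12),
                           identity_transform())
  tk_r <- apply_transform(tk, tf)
  g0 <- compute_geometry(tk)
  g1 <- compute_geometry(tk_r)
  for (f in c("pupil_size", "eye_opening", "snout_mouth_length",
              "nose_position", "ear_length", "ear_width")) {
    expect_equal(g1[[f]], g0[[f]], tolerance = 1e-9)
  }
  # interior angles are invariant too
  expect_equal(g1$mouth_inclination, g0$mouth_inclination,
               tolerance = 1e-9)
  expect_equal(g1$ear_fold, g0$ear_fold, tolerance = 1e-9)
  # directional angles shift by exactly the applied rotation (mod 180)
  shift <- (g1$ear_angle - g0$ear_angle) %% 180
  expect_true(all(abs(shift - rot) < 1e-6 | abs(shift - (180 - rot)) < 1e-6))
})

test_that("baseline-relative change scores are proportional and signed", {
  fps <- 10
  series <- c(rep(10, 45), rep(12, 20), rep(10, 20))
  r <- change_from_baseline(series, onset = 4.5, fps = fps)
  expect_equal(r$baseline, 10)
  expect_equal(r$peak, 0.2)
  expect_equal(r$change[1:45], rep(0, 45))

  flat <- rep(7, 85)
  r2 <- change_from_baseline(flat, onset = 4.5, fps = fps)
  expect_equal(r2$peak, 0)
  r3 <- change_from_baseline(rep(0, 85), onset = 4.5, fps = fps)
  expect_equal(r3$flag, "zero_baseline")

  # decreases are kept signed (extremum by absolute value)
  dn <- c(rep(10, 45), rep(7, 20), rep(10, 20))
  expect_equal(change_from_baseline(dn, 4.5, fps)$peak, -0.3)
})

test_that("a generated ear-angle offset is recovered within 3 points", {
  # +15% of the baseline ear angle, recovered from rendered-geometry peaks
  base <- face_phenotype()
  target <- 0.15
  off <- valence_effects()$offsets
  off$sucrose[] <- 0
  off$sucrose["ear_angle"] <- target * base$ear_angle
  off$sucrose["pupil_diameter"] <- 1e-6
  eff <- valence_effects(offsets = off, identity_sd = 0, noise_sd = 0.4,
                         validate = FALSE)
  spec <- cohort_spec(n_mice = 1, fps = 30, frame_size = 256, seed = 0)
  peaks <- vapply(1:20, function(i) {
    tr <- simulate_trial(base, eff, "sucrose", spec, seed = i)
    g <- compute_geometry(qc_track(tr$track))
    change_from_baseline(g$ear_angle, tr$onset_s, spec$fps,
                         window_s = c(0, spec$stimulus_duration))$peak
  }, numeric(1))
  expect_lt(abs(mean(peaks) - target), 0.03)
  expect_true(all(peaks > 0))
})

test_that("water correction subtracts the temporally nearest control", {
  expect_equal(water_correct(0.30, 180, water = c(0.10), water_time = 100),
               0.20)
  expect_equal(water_correct(0.10, 100, water = c(0.10), water_time = 100),
               0)
  # nearest-neighbor rule: stimulus at 180 s picks the 100 s water trial
  expect_equal(water_correct(0.5, 180, water = c(0.1, 0.4),
                             water_time = c(100, 500)), 0.4)
  # equidistant tie breaks toward the earlier trial
  expect_equal(water_correct(0.5, 300, water = c(0.1, 0.4),
                             water_time = c(100, 500)), 0.4)
  expect_error(water_correct(0.5, 300, numeric(0), numeric(0)), "water")
})

test_that("water-corrected ear-angle signs follow the valence pattern", {
  kin <- cohort_kinematics(tracked_cohort())
  ear <- kin$peaks[kin$peaks$feature == "ear_angle" &
                     kin$peaks$stimulus != "water", ]
  expected <- c(sucrose = 1, nacl = 1, bitter = -1, shock = -1)
  ok <- sign(ear$corrected) == expected[ear$stimulus]
  expect_gte(mean(ok), 0.9)
  s <- kin$sign_by_stimulus$ear_angle
  expect_equal(s[["sucrose"]], s[["nacl"]])
  expect_equal(s[["bitter"]], s[["shock"]])
  expect_equal(s[["sucrose"]], -s[["shock"]])
})

test_that("keypoint PCA z-scores, drops degenerate columns, finds modes", {
  # rank-1 data -> first component explains everything
  set.seed(10)
  u <- rnorm(30)
  X <- cbind(a = u, b = 2 * u, c = -u)
  p <- keypoint_pca(X, z_score = TRUE)
  expect_equal(p$explained[1], 1, tolerance = 1e-12)
  Z <- scale(X)
  expect_true(all(abs(colMeans(Z)) < 1e-12))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-12))

  X2 <- cbind(X, flat = rep(1, 30))
  expect_warning(keypoint_pca(X2), "zero-variance")

  # an independent ear variance mode dominates a top-2 component
  n <- 60
  shared <- rnorm(n)
  earmode <- rnorm(n)
  M <- cbind(ear_x = shared + 3 * earmode, ear_y = shared - 3 * earmode,
             nose_x = shared + 0.1 * rnorm(n),
             nose_y = shared + 0.1 * rnorm(n),
             whisker_x = shared + 0.1 * rnorm(n),
             whisker_y = shared + 0.1 * rnorm(n))
  pm <- keypoint_pca(M)
  mass <- function(v) sum(v[1:2]^2) / sum(v^2)
  expect_gt(max(mass(pm$loadings[, 1]), mass(pm$loadings[, 2])), 0.5)
})

test_that("response latency finds sustained crossings and orderings", {
  fps <- 30
  never <- rep(5, 300) + 0
  r0 <- response_latency(never, onset = 5, fps = fps)
  expect_true(is.na(r0$latency_s))
  expect_equal(r0$flag, "zero_baseline_sd")

  set.seed(11)
  stepped <- c(rnorm(150, 5, 0.1), rep(5, 15), rep(9, 135) + rnorm(135, 0, 0.1))
  r1 <- response_latency(stepped, onset = 5, fps = fps)
  expect_equal(r1$latency_s, 0.5, tolerance = 0.05)

  # generator latencies: whisker (0.1 s) precedes pupil (1.0 s)
  eff <- valence_effects(noise_sd = 0.2, identity_sd = 0)
  spec <- cohort_spec(n_mice = 1, fps = 30, frame_size = 256, seed = 0)
  hits <- vapply(1:20, function(i) {
    tr <- simulate_trial(face_phenotype(), eff, "sucrose", spec, seed = 100 + i)
    lw <- response_latency(tr$features[, "whisker_angle"], tr$onset_s,
                           spec$fps)$latency_s
    lp <- response_latency(tr$features[, "pupil_diameter"], tr$onset_s,
                           spec$fps)$latency_s
    !is.na(lw) && !is.na(lp) && lw < lp
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
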