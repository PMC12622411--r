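# Synthetic generator: schematic faces, trial dynamics, photometry.

test_that("keypoint schema has the six-region layout and exact recovery", {
  p <- face_phenotype()
  kp <- face_keypoints(p, 256)
  expect_equal(nrow(kp), 37L)
  counts <- table(kp$region)
  expect_equal(counts[["pupil"]], 8L)
  expect_equal(counts[["eye"]], 4L)
  expect_equal(counts[["ear"]], 5L)
  expect_equal(counts[["nose"]], 5L)
  expect_equal(counts[["mouth"]], 3L)
  expect_equal(counts[["whisker"]], 12L)

  g <- function(nm) unlist(kp[kp$name == nm, c("x", "y")], use.names = FALSE)
  # every generating field is recovered exactly from the construction points
  expect_equal(vector_angle(g("pinna_posterior") - g("ear_base")),
               p$ear_angle, tolerance = 1e-9)
  expect_equal(sqrt(sum((g("pinna_posterior") - g("ear_base"))^2)),
               p$ear_length, tolerance = 1e-9)
  expect_equal(sqrt(sum((g("ear_mid_outer") - g("ear_mid_inner"))^2)),
               p$ear_width, tolerance = 1e-9)
  expect_equal(interior_angle(g("ear_base"), g("pinna_posterior"),
                              g("ear_mid_outer")),
               p$ear_fold, tolerance = 1e-9)
  nost <- colMeans(kp[grepl("^nostril", kp$name), c("x", "y")])
  expect_equal(interior_angle(nost, g("eyelid_inner"), g("lower_lip")),
               p$mouth_inclination, tolerance = 1e-9)
  expect_equal(sqrt(sum((g("lower_lip") - g("nose_tip"))^2)),
               p$snout_mouth_length, tolerance = 1e-9)
  expect_equal(vector_angle(g("whisker1_p4") - g("whisker1_p1"), "-x"),
               p$whisker_angle, tolerance = 1e-9)
  expect_equal(sqrt(sum((g("pupil_u") - g("pupil_d"))^2)),
               p$pupil_diameter, tolerance = 1e-9)
})

test_that("a 90-degree ear renders a vertical pinna vector", {
  p <- face_phenotype(ear_angle = 90)
  kp <- face_keypoints(p, 256)
  v <- unlist(kp[kp$name == "pinna_posterior", c("x", "y")]) -
    unlist(kp[kp$name == "ear_base", c("x", "y")])
  expect_equal(v[["x"]], 0, tolerance = 1e-9)
  expect_lt(v[["y"]], 0)  # up in image coordinates
  expect_equal(vector_angle(v), 90, tolerance = 1e-9)
})

test_that("rendering is deterministic and off-canvas phenotypes error", {
  p <- face_phenotype()
  r1 <- render_face(p, 128)
  r2 <- render_face(p, 128)
  expect_identical(r1$image, r2$image)
  expect_true(all(r1$image >= 0 & r1$image <= 1))
  expect_error(face_keypoints(face_phenotype(ear_length = 150), 128),
               "off-canvas")
})

test_that("null-effect noiseless trials are static at the baseline render", {
  eff0 <- valence_effects(noise_sd = 0, identity_sd = 0, effect_scale = 0,
                          validate = FALSE)
  spec <- cohort_spec(n_mice = 1, fps = 10, pre_s = 1, post_s = 1,
                      frame_size = 128, seed = 0)
  tr <- simulate_trial(face_phenotype(), eff0, "sucrose", spec, seed = 1)
  base <- unlist(face_phenotype()[colnames(tr$features)])
  expect_equal(max(abs(sweep(tr$features, 2, base))), 0)
  frames <- render_trial(tr, c(1, 20, 40))
  expect_identical(frames[[1]], frames[[2]])
  expect_identical(frames[[2]], frames[[3]])
})

test_that("sucrose and shock move the ear angle in opposite directions", {
  eff <- valence_effects(noise_sd = 0, identity_sd = 0)
  spec <- cohort_spec(n_mice = 1, fps = 10, frame_size = 256, seed = 0)
  base <- face_phenotype()
  su <- simulate_trial(base, eff, "sucrose", spec, seed = 1)
  sh <- simulate_trial(base, eff, "shock", spec, seed = 1)
  i <- round((spec$pre_s + 1.5) * spec$fps)
  expect_gt(su$features[i, "ear_angle"] - base$ear_angle, 0)
  expect_lt(sh$features[i, "ear_angle"] - base$ear_angle, 0)
})

test_that("seeded trials regenerate identically", {
  eff <- valence_effects(noise_sd = 0.5)
  spec <- cohort_spec(n_mice = 1, fps = 10, frame_size = 128, seed = 0)
  t1 <- simulate_trial(face_phenotype(), eff, "bitter", spec, seed = 42)
  t2 <- simulate_trial(face_phenotype(), eff, "bitter", spec, seed = 42)
  expect_identical(t1$features, t2$features)
  expect_identical(t1$track$coords, t2$track$coords)
  expect_error(simulate_trial(face_phenotype(), eff, "coffee", spec),
               "unknown stimulus")
})

test_that("effect specification enforces the valence sign structure", {
  expect_error(valence_effects(identity_sd = 1.5)$offsets, NA)
  bad <- valence_effects()$offsets
  bad$sucrose["ear_angle"] <- -bad$sucrose["ear_angle"]
  expect_error(valence_effects(offsets = bad), "share signs|opposite")
  bad2 <- valence_effects()$offsets
  bad2$shock["pupil_diameter"] <- 0
  expect_error(valence_effects(offsets = bad2), "pupil")
})

test_that("photometry nulls, pan tuning and determinism behave", {
  ev <- data.frame(onset_s = 10, stimulus = "sucrose")
  rec <- simulate_photometry("DA", ev, duration_s = 30,
                             bleach_tau = Inf, artifact_sd = 0,
                             noise_sd = 0, seed = 1)
  on <- which(rec$time >= 10)
  # single exponential-decay transient on a constant offset
  expect_equal(sd(rec$f470[rec$time < 10]), 0)
  amp <- neuron_amplitudes()$DA[["sucrose"]]
  expect_equal(rec$f470[on] - rec$f470[1],
               amp * exp(-(rec$time[on] - 10) / 1), tolerance = 1e-9)
  expect_equal(sd(rec$f410), 0)

  ev5 <- data.frame(onset_s = seq(10, 90, by = 20),
                    stimulus = stimulus_labels())
  pan <- simulate_photometry("pan", ev5, artifact_sd = 0, noise_sd = 0,
                             bleach_tau = Inf, seed = 1)
  peaks <- vapply(ev5$onset_s, function(on) {
    max(pan$f470[pan$time >= on & pan$time < on + 2]) - 100
  }, numeric(1))
  expect_lt(diff(range(peaks)), 0.6)  # equal amplitudes (residual decay tails)

  r1 <- simulate_photometry("GABA", ev5, seed = 9)
  r2 <- simulate_photometry("GABA", ev5, seed = 9)
  expect_identical(r1$f470, r2$f470)
  expect_error(simulate_photometry("astro", ev5), "unknown neuron_type")
})

test_that("DA amplitude ordering appears in event-aligned raw 470 peaks", {
  ev <- data.frame(onset_s = seq(10, 250, by = 25),
                   stimulus = rep(stimulus_labels(), 2))
  rec <- simulate_photometry("DA", ev, artifact_sd = 0, noise_sd = 0,
                             bleach_tau = Inf, seed = 1)
  peaks <- vapply(seq_len(nrow(ev)), function(i) {
    sel <- rec$time >= ev$onset_s[i] & rec$time < ev$onset_s[i] + 2
    max(rec$f470[sel]) - 100
  }, numeric(1))
  m <- tapply(peaks, ev$stimulus, mean)
  expect_gt(m[["sucrose"]], m[["nacl"]])
  expect_gt(m[["nacl"]], m[["water"]])
  expect_gt(m[["water"]], max(m[["bitter"]], m[["shock"]]))
})

test_that("cohorts have the right size, identity structure and determinism", {
  spec <- cohort_spec(n_mice = 3, trials_per_stimulus = 2, fps = 10,
                      pre_s = 1, post_s = 1, frame_size = 128, seed = 5)
  co <- build_cohort(spec, valence_effects(), track = FALSE)
  expect_equal(nrow(co$events), 3 * 2 * 5)
  expect_equal(length(cohort_trials(co)), 30)

  co0 <- build_cohort(spec, valence_effects(identity_sd = 0),
                      track = FALSE)
  bases <- lapply(co0$mice, function(m) unlist(m$base))
  expect_equal(bases[[1]], bases[[2]])
  expect_equal(bases[[2]], bases[[3]])

  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  spec_s <- cohort_spec(n_mice = 2, trials_per_stimulus = 1, fps = 10,
                        pre_s = 1, post_s = 1, frame_size = 128, seed = 5)
  build_cohort(spec_s, valence_effects(), out_dir = d1)
  build_cohort(spec_s, valence_effects(), out_dir = d2)
  m1 <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  m2 <- yaml::read_yaml(file.path(d2, "manifest.yaml"))
  expect_identical(m1$checksums, m2$checksums)
  expect_gt(length(m1$checksums), 0)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("keypoint CSV round-trips through the pose-export dialect", {
  co <- tracked_cohort()
  tr <- cohort_trials(co)[[1]]
  f <- tempfile(fileext = ".csv")
  write_dlc_csv(tr$track, f)
  back <- read_dlc_csv(f, fps = co$spec$fps)
  expect_equal(back$names, tr$track$names)
  expect_equal(back$coords, tr$track$coords, tolerance = 1e-5)
  unlink(f)
})
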