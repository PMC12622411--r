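# Valence prototypes and similarity scoring.

test_that("subprototype selection reuses the two-step apex procedure", {
  set.seed(6)
  stim <- matrix(abs(rnorm(20 * 10)) + 0.01, 20, 10)
  neutral <- matrix(abs(rnorm(5 * 10)) + 0.01, 5, 10)
  # k = 1 agrees with the apex frame
  expect_equal(select_subprototypes(stim, neutral, k = 1, shortlist_k = 10),
               select_apex_frame(stim, neutral, shortlist_k = 10)$index)
  # full ranking matches the exhaustive oracle
  got <- select_subprototypes(stim, neutral, k = 5, shortlist_k = 10)
  want <- apex_oracle(stim, neutral, 10)$ranked[1:5]
  expect_equal(got, want)
  # degenerate: stimulus equals neutral -> warning, deterministic result
  expect_warning(
    s1 <- select_subprototypes(neutral, neutral, k = 2, shortlist_k = 5),
    "degenerate|indistinguishable")
  expect_warning(
    s2 <- select_subprototypes(neutral, neutral, k = 2, shortlist_k = 5))
  expect_identical(s1, s2)
  expect_warning(select_subprototypes(stim[1:3, ], neutral, k = 5,
                                      shortlist_k = 3), "clamped")
})

test_that("prototype construction is an order-invariant elementwise mean", {
  v <- c(0.4, 0.6, 0.2)
  p1 <- build_prototype(list(sucrose = rbind(v, v), nacl = rbind(v),
                             bitter = rbind(2 * v), shock = rbind(2 * v)))
  expect_equal(unname(p1$positive), v)
  p2 <- build_prototype(list(sucrose = rbind(c(0, 2)), nacl = rbind(c(2, 0)),
                             bitter = rbind(c(1, 1)), shock = rbind(c(1, 1))))
  expect_equal(unname(p2$positive), c(1, 1))
  # order invariance over subprototype rows
  set.seed(7)
  M <- matrix(abs(rnorm(40)), 8, 5)
  pa <- build_prototype(list(sucrose = M[1:4, ], nacl = M[5:6, ],
                             bitter = M[7:8, ], shock = M[7:8, ]))
  pb <- build_prototype(list(sucrose = M[4:1, ], nacl = M[6:5, ],
                             bitter = M[8:7, ], shock = M[8:7, ]))
  expect_equal(pa$positive, pb$positive, tolerance = 1e-12)
  expect_error(build_prototype(list(sucrose = M[1:2, ])), "negative")
})

test_that("stream scoring is exact, antisymmetric, and valence-consistent", {
  set.seed(8)
  pos <- abs(rnorm(12)) + 0.1
  neg <- abs(rnorm(12)) + 0.1
  neg <- neg / sqrt(sum(neg^2)) * sqrt(sum(pos^2))  # equal norms
  proto <- build_prototype(list(sucrose = rbind(pos), nacl = rbind(pos),
                                bitter = rbind(neg), shock = rbind(neg)))
  tc <- score_stream(rbind(pos, (pos + neg) / 2), proto)
  expect_equal(tc$sim_pos[1], 1, tolerance = 1e-12)
  expect_gt(tc$diff[1], 0)
  expect_equal(tc$diff[2], 0, tolerance = 1e-12)  # midpoint, equal norms

  swapped <- proto
  swapped$positive <- proto$negative
  swapped$negative <- proto$positive
  F <- matrix(abs(rnorm(5 * 12)) + 0.05, 5, 12)
  expect_equal(score_stream(F, proto)$diff,
               -score_stream(F, swapped)$diff, tolerance = 1e-12)
  expect_error(score_stream(F[, 1:5], proto), "length")
})

test_that("cohort prototypes separate held-out valences", {
  co <- fixture("proto_cohort", function() {
    build_cohort(cohort_spec(n_mice = 3, trials_per_stimulus = 2,
                             frame_size = 128, seed = 21),
                 valence_effects(noise_sd = 0.25, identity_sd = 1),
                 track = FALSE)
  })
  proto <- cohort_prototype(co, k = 5, canvas = 64)
  cfg <- hog_config(64)
  hog64 <- function(tr, idx) {
    hog_matrix(lapply(render_trial(tr, idx, 128), resize_image, side = 64),
               cfg)
  }
  # held-out mice (prototype mouse m01 excluded)
  eval_trials <- Filter(function(tr) tr$mouse_id != co$prototype_mouse,
                        cohort_trials(co))
  diffs <- vapply(eval_trials, function(tr) {
    idx <- trial_window_frames(tr, c(0.5, 2))
    H <- hog64(tr, idx[seq(1, length(idx), 5)])
    mean(score_stream(H, proto)$diff)
  }, numeric(1))
  val <- vapply(eval_trials, function(tr) tr$valence, character(1))
  # positive prototype similarity dominates for positive trials and the
  # reverse for negative trials, on average and for most trials
  expect_gt(mean(diffs[val == "positive"]), 0)
  expect_lt(mean(diffs[val == "negative"]), 0)
  expect_gte(mean(sign(diffs[val != "neutral"]) ==
                    ifelse(val[val != "neutral"] == "positive", 1, -1)),
             0.9)
  # a held-out sucrose apex is closer to the positive prototype than a
  # held-out shock apex is
  su <- Filter(function(tr) tr$mouse_id == "m02" &&
                 tr$stimulus == "sucrose", cohort_trials(co))[[1]]
  sh <- Filter(function(tr) tr$mouse_id == "m02" &&
                 tr$stimulus == "shock", cohort_trials(co))[[1]]
  apex_hog <- function(tr) {
    idx <- trial_window_frames(tr, c(0.5, 2))
    H <- hog64(tr, idx[seq(1, length(idx), 5)])
    neutral <- hog64(tr, 1:3)
    H[select_apex_frame(H, neutral, 5)$index, ]
  }
  expect_gt(cosine_similarity(apex_hog(su), proto$positive),
            cosine_similarity(apex_hog(sh), proto$positive))
})

test_that("cumulative similarity sums windows exactly", {
  tc <- data.frame(time_s = 0:9, sim_pos = rep(0.5, 10),
                   sim_neg = rep(0.25, 10), diff = rep(0.25, 10))
  class(tc) <- c("similarity_timecourse", "data.frame")
  expect_equal(cumulative_similarity(tc, c(0, 10)),
               c(cum_pos = 5, cum_neg = 2.5))
  expect_equal(cumulative_similarity(tc, c(3, 3)),
               c(cum_pos = 0, cum_neg = 0))
})

test_that("the drug valence index normalizes, counts and recovers shifts", {
  n <- 3000
  t_s <- seq(0, 1800, length.out = n)
  set.seed(9)
  # constant diff -> normalized difference 0 in every epoch
  tc0 <- data.frame(time_s = t_s, sim_pos = 0.6, sim_neg = 0.3, diff = 0.3)
  class(tc0) <- c("similarity_timecourse", "data.frame")
  s0 <- drug_valence_index(tc0, c(0, 300), list(early = c(300, 900),
                                                late = c(900, 1800)))
  expect_equal(s0$normalized_diff, c(0, 0))
  expect_equal(attr(s0, "flag"), "zero_baseline_sd")

  # counting: 62 positive of 100 classified
  tc1 <- data.frame(time_s = seq(-20, 99),
                    sim_pos = 0, sim_neg = 0,
                    diff = c(rnorm(20, sd = 1e-3), rep(1, 62), rep(-1, 38)))
  class(tc1) <- c("similarity_timecourse", "data.frame")
  s1 <- drug_valence_index(tc1, c(-20, 0), list(all = c(0, 100)))
  expect_equal(s1$n_classified, 100)
  expect_equal(s1$proportion_positive, 0.62)
  expect_equal(s1$pos_neg_ratio, 62 / 38)

  # ethanol-like session: diff mean shifts +delta after injection
  delta <- 0.08
  diff <- rnorm(n, sd = 0.05) + ifelse(t_s > 300, delta, 0)
  tc2 <- data.frame(time_s = t_s, sim_pos = 0, sim_neg = 0, diff = diff)
  class(tc2) <- c("similarity_timecourse", "data.frame")
  s2 <- drug_valence_index(tc2, c(0, 300), list(early = c(300, 1050),
                                                late = c(1050, 1800)))
  expect_true(all(s2$normalized_diff > 0))
  expect_true(all(s2$proportion_positive > s2$proportion_negative))
  # and the sign flips for a LiCl-like negative shift
  tc3 <- tc2
  tc3$diff <- rnorm(n, sd = 0.05) - ifelse(t_s > 300, delta, 0)
  s3 <- drug_valence_index(tc3, c(0, 300), list(early = c(300, 1050),
                                                late = c(1050, 1800)))
  expect_true(all(s3$normalized_diff < 0))
})
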