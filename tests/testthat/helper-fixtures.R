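# Shared fixtures, built once per test run and memoised. Everything is
# generated in code from fixed seeds; no data files are read.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# 3-mouse cohort at the 256-px reference canvas, with keypoint tracks;
# used by kinematics and structural tests (geometry is unscaled at 256).
tracked_cohort <- function() {
  fixture("tracked_cohort", function() {
    build_cohort(cohort_spec(n_mice = 3, trials_per_stimulus = 2,
                             frame_size = 256, seed = 11),
                 valence_effects(noise_sd = 0.3, identity_sd = 1))
  })
}

# 6-mouse cohort (no tracks) and its 32-px frame dataset; used by the
# classifier and Siamese tests. Frames from the saturated part of the
# stimulus window.
decoder_dataset <- function() {
  fixture("decoder_dataset", function() {
    co <- build_cohort(cohort_spec(n_mice = 6, trials_per_stimulus = 2,
                                   frame_size = 128, seed = 3),
                       valence_effects(noise_sd = 0.3, identity_sd = 1.5),
                       track = FALSE)
    cohort_frame_dataset(co, side = 32, frames_per_trial = 8,
                         window = c(0.5, 2))
  })
}

# effects whose class signal lives only in the ear parameters; the
# non-physiological structure (no pupil response) is deliberate
ear_only_effects <- function(noise_sd = 0.3) {
  zero <- stats::setNames(numeric(10), names(valence_effects()$offsets$water))
  off <- list(
    sucrose = replace(zero, c("ear_angle", "ear_length", "ear_fold"),
                      c(22, 8, 9)),
    nacl = replace(zero, c("ear_angle", "ear_length", "ear_fold"),
                   c(10, 4, 4)),
    bitter = replace(zero, c("ear_angle", "ear_length", "ear_fold"),
                     c(-12, -4, -5)),
    shock = replace(zero, c("ear_angle", "ear_length", "ear_fold"),
                    c(-24, -8, -9)),
    water = zero)
  valence_effects(offsets = off, identity_sd = 0.8, noise_sd = noise_sd,
                  validate = FALSE)
}

# cohort whose classes differ only inside the ear polygon, and its 32-px
# dataset; used by the Grad-CAM and occlusion tests
ear_only_dataset <- function() {
  fixture("ear_only_dataset", function() {
    co <- build_cohort(cohort_spec(n_mice = 5, trials_per_stimulus = 2,
                                   frame_size = 128, seed = 7),
                       ear_only_effects(), track = FALSE)
    list(cohort = co,
         dataset = cohort_frame_dataset(co, side = 32,
                                        frames_per_trial = 10,
                                        window = c(0.5, 2)))
  })
}

# logical 32-px masks for the ear region and for pure background; the ear
# mask is the union over the ear-angle/length excursions the effect specs
# can produce, so the moving pinna stays covered
ear_mask_32 <- function(pad = 10) {
  m <- matrix(FALSE, 32, 32)
  for (da in c(-26, 0, 26)) for (dl in c(-9, 9)) {
    p <- perturb_phenotype(face_phenotype(),
                           c(ear_angle = da, ear_length = dl))
    kp <- face_keypoints(p, 256)
    ear_names <- kp$name[kp$region == "ear"]
    m <- m | mask_from_keypoints(kp, ear_names, side = 32, canvas = 256,
                                 pad = pad)
  }
  m
}

background_mask_32 <- function() {
  m <- matrix(FALSE, 32, 32)
  m[26:32, 1:5] <- TRUE  # lower-left corner, away from the face
  m
}

# trained Siamese fit on the ear-only cohort (shared by unit + acceptance)
siamese_fixture <- function() {
  fixture("siamese_fixture", function() {
    ds <- decoder_dataset()
    train_mice <- c("m01", "m02", "m03", "m04")
    test_mice <- c("m05", "m06")
    pairs <- make_pairs(ds, n_pairs = 200, seed = 0, mice = train_mice)
    eval_pairs <- make_pairs(ds, n_pairs = 120, seed = 1, mice = test_mice)
    fit <- train_siamese(pairs, contrastive_config(epochs = 8, seed = 0),
                         eval_pairs = eval_pairs)
    list(fit = fit, pairs = pairs, eval_pairs = eval_pairs,
         dataset = ds)
  })
}

# independent scalar-loop oracles
cosine_oracle <- function(a, b) {
  s <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    s <- s + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  s / (sqrt(na) * sqrt(nb))
}

contrastive_oracle <- function(d, y, m) {
  tot <- 0
  for (i in seq_along(d)) {
    tot <- tot + y[i] * d[i]^2 +
      (1 - y[i]) * max(m - d[i], 0)^2
  }
  tot / (2 * length(d))
}

# exhaustive two-step apex search
apex_oracle <- function(stim, base, k) {
  ns <- nrow(stim)
  within <- numeric(ns)
  for (i in seq_len(ns)) {
    v <- c()
    for (j in seq_len(ns)) {
      if (i != j) v <- c(v, cosine_oracle(stim[i, ], stim[j, ]))
    }
    within[i] <- if (ns > 1) mean(v) else 1
  }
  short <- order(-within, seq_len(ns))[seq_len(min(k, ns))]
  bsim <- vapply(short, function(i) {
    mean(vapply(seq_len(nrow(base)),
                function(j) cosine_oracle(stim[i, ], base[j, ]),
                numeric(1)))
  }, numeric(1))
  list(index = short[order(bsim, short)][1], shortlist = sort(short),
       ranked = short[order(bsim, short)])
}

# closed-form similarity Procrustes (rotation + scale + translation)
procrustes_oracle <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  X <- sweep(src, 2, cs); Y <- sweep(dst, 2, cd)
  S <- t(X) %*% Y
  sv <- svd(S)
  R <- sv$v %*% t(sv$u)
  if (det(R) < 0) {
    sv$v[, 2] <- -sv$v[, 2]
    R <- sv$v %*% t(sv$u)
  }
  s <- sum(diag(t(Y) %*% X %*% t(R))) / sum(X^2)
  list(scale = s, rotation_deg = atan2(R[2, 1], R[1, 1]) * 180 / pi,
       translation = cd - s * as.numeric(R %*% cs))
}
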