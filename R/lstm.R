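# Region-wise LSTM decoding of keypoint trajectories.
#
# For one facial region the four keypoints with the highest variance
# across trials are tracked over a 2.5 s peristimulus window (0.5 s before
# to 2 s after onset), z-scored, and downsampled by keeping every third
# frame: 25 timepoints x (4 keypoints x 2 axes) = a 200-dimensional input
# sequence per trial, classified into the five stimulus conditions by a
# multilayer LSTM under stratified trial-level cross-validation.

#' Build the trajectory tensor for a region
#'
#' @param cohort a `synthetic_cohort` built with keypoint tracks.
#' @param region one of `"ear"`, `"whisker"`, `"nose"` (snout), `"pupil"`,
#'   `"eye"`, `"mouth"`, or `"mixed"` (4 keypoints sampled across
#'   regions).
#' @param window seconds relative to onset.
#' @param downsample keep every `downsample`-th frame.
#' @param n_keypoints keypoints per region.
#' @param seed seed for the mixed-region keypoint sample.
#' @return object of class `trajectory_tensor`: `tensor`
#'   (timepoints x channels x trials), `labels` (1..5), `classes`,
#'   `trial_id`, `mouse_id`, `keypoints`, `region`.
#' @export
build_trajectory_tensor <- function(cohort, region, window = c(-0.5, 2),
                                    downsample = 3, n_keypoints = 4,
                                    seed = 0) {
  trials <- cohort_trials(cohort)
  if (is.null(trials[[1]]$track)) {
    stop("cohort was built without keypoint tracks")
  }
  trk0 <- trials[[1]]$track
  cand <- if (region == "mixed") {
    seq_along(trk0$names)
  } else {
    which(trk0$regions == region)
  }
  if (length(cand) < n_keypoints) {
    stop("fewer than ", n_keypoints, " keypoints in region ", region)
  }
  # per-keypoint variance across trials (x + y, pooled over frames)
  allc <- lapply(trials, function(tr) tr$track$coords)
  pooled_var <- vapply(cand, function(j) {
    xs <- unlist(lapply(allc, function(a) a[, j, 1]))
    ys <- unlist(lapply(allc, function(a) a[, j, 2]))
    var(xs) + var(ys)
  }, numeric(1))
  sel <- if (region == "mixed") {
    with_seed(seed, sample(cand, n_keypoints))
  } else {
    cand[order(-pooled_var)[seq_len(n_keypoints)]]
  }

  classes <- frame_classes()
  mats <- list(); labs <- integer(0); tid <- character(0); mid <- character(0)
  for (tr in trials) {
    idx <- which(tr$time - tr$onset_s >= window[1] &
                   tr$time - tr$onset_s < window[2])
    idx <- idx[seq(1, length(idx), by = downsample)]
    m <- matrix(NA_real_, length(idx), 2 * length(sel))
    for (q in seq_along(sel)) {
      m[, 2 * q - 1] <- tr$track$coords[idx, sel[q], 1]
      m[, 2 * q] <- tr$track$coords[idx, sel[q], 2]
    }
    mats[[tr$trial_id]] <- m
    lab <- if (tr$stimulus == "water") "neutral" else tr$stimulus
    labs <- c(labs, match(lab, classes))
    tid <- c(tid, tr$trial_id)
    mid <- c(mid, tr$mouse_id)
  }
  Tn <- nrow(mats[[1]])
  D <- ncol(mats[[1]])
  tens <- array(NA_real_, c(Tn, D, length(mats)))
  for (i in seq_along(mats)) tens[, , i] <- mats[[i]]
  # z-score each channel over all trials and timepoints
  for (d in seq_len(D)) {
    v <- tens[, d, ]
    mu <- mean(v); s <- sd(v)
    tens[, d, ] <- if (s > 0) (v - mu) / s else v - mu
  }
  structure(list(tensor = tens, labels = labs, classes = classes,
                 trial_id = tid, mouse_id = mid,
                 keypoints = trk0$names[sel], region = region),
            class = "trajectory_tensor")
}

#' @export
print.trajectory_tensor <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<trajectory_tensor> %s: %d trials x (%d timepoints x %d channels = %dD)\n",
              x$region, d[3], d[1], d[2], d[1] * d[2]))
  invisible(x)
}

#' LSTM decoder configuration
#'
#' The reference architecture uses three hidden layers of 256 units with
#' dropout 0.3; the desk default halves the width. Training uses
#' cross-entropy with adaptive-moment estimation and early stopping on the
#' training loss.
#'
#' @param hidden hidden units per layer.
#' @param layers stacked LSTM layers.
#' @param dropout inter-layer dropout rate.
#' @param epochs maximum epochs.
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience (epochs without improvement).
#' @param seed integer seed.
#' @return object of class `lstm_config`.
#' @export
lstm_config <- function(hidden = 128, layers = 3, dropout = 0.3,
                        epochs = 100, lr = 0.01, batch_size = 32,
                        patience = 10, seed = 0) {
  structure(list(hidden = as.integer(hidden), layers = as.integer(layers),
                 dropout = dropout, epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "lstm_config")
}

sigm <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(D, H, L, K, seed) {
  with_seed(seed, {
    Ws <- lapply(seq_len(L), function(l) {
      Din <- if (l == 1) D else H
      W <- matrix(rnorm((Din + H) * 4 * H, sd = 1 / sqrt(Din + H)),
                  Din + H, 4 * H)
      b <- numeric(4 * H)
      b[(H + 1):(2 * H)] <- 1    # forget-gate bias
      list(W = W, b = b)
    })
    list(Ws = Ws, Wy = matrix(rnorm(H * K, sd = 1 / sqrt(H)), H, K),
         by = numeric(K), D = D, H = H, L = L, K = K)
  })
}

lstm_forward <- function(par, X, dropout = 0, train = FALSE) {
  Tn <- dim(X)[1]; N <- dim(X)[3]
  H <- par$H; L <- par$L
  caches <- vector("list", L)
  inp <- lapply(seq_len(Tn), function(t) matrix(X[t, , ], dim(X)[2], N))
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    W <- par$Ws[[l]]$W; b <- par$Ws[[l]]$b
    h <- matrix(0, H, N); cc <- matrix(0, H, N)
    cache_t <- vector("list", Tn)
    out <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      z <- rbind(inp[[t]], h)
      a <- crossprod(W, z) + b
      i <- sigm(a[1:H, , drop = FALSE])
      f <- sigm(a[(H + 1):(2 * H), , drop = FALSE])
      g <- tanh(a[(2 * H + 1):(3 * H), , drop = FALSE])
      o <- sigm(a[(3 * H + 1):(4 * H), , drop = FALSE])
      c_new <- f * cc + i * g
      h_new <- o * tanh(c_new)
      cache_t[[t]] <- list(z = z, i = i, f = f, g = g, o = o,
                           c_prev = cc, c_new = c_new)
      cc <- c_new; h <- h_new
      out[[t]] <- h_new
    }
    caches[[l]] <- cache_t
    if (l < L && dropout > 0 && train) {
      masks[[l]] <- lapply(seq_len(Tn), function(t) {
        (matrix(runif(H * N), H, N) >= dropout) / (1 - dropout)
      })
      out <- lapply(seq_len(Tn), function(t) out[[t]] * masks[[l]][[t]])
    }
    inp <- out
  }
  h_last <- inp[[Tn]]
  logits <- crossprod(par$Wy, h_last) + par$by
  list(logits = logits, caches = caches, masks = masks, h_last = h_last,
       Tn = Tn, N = N)
}

lstm_backward <- function(par, X, fw, dLogits) {
  Tn <- fw$Tn; N <- fw$N
  H <- par$H; L <- par$L
  gW <- lapply(par$Ws, function(w) list(W = 0 * w$W, b = 0 * w$b))
  gWy <- fw$h_last %*% t(dLogits)
  gby <- rowSums(dLogits)
  # gradient arriving at the output h of each layer, per timestep
  d_in_above <- vector("list", Tn)
  for (t in seq_len(Tn)) d_in_above[[t]] <- matrix(0, H, N)
  d_in_above[[Tn]] <- par$Wy %*% dLogits
  dX <- NULL
  for (l in rev(seq_len(L))) {
    if (l < L && length(fw$masks) >= l && !is.null(fw$masks[[l]])) {
      for (t in seq_len(Tn)) {
        d_in_above[[t]] <- d_in_above[[t]] * fw$masks[[l]][[t]]
      }
    }
    W <- par$Ws[[l]]$W
    Din <- if (l == 1) par$D else H
    dh_next <- matrix(0, H, N)
    dc_next <- matrix(0, H, N)
    d_below <- vector("list", Tn)
    for (t in rev(seq_len(Tn))) {
      ch <- fw$caches[[l]][[t]]
      dh <- d_in_above[[t]] + dh_next
      tc <- tanh(ch$c_new)
      do_ <- dh * tc
      dc <- dh * ch$o * (1 - tc^2) + dc_next
      di <- dc * ch$g
      dg <- dc * ch$i
      df <- dc * ch$c_prev
      dc_next <- dc * ch$f
      da <- rbind(di * ch$i * (1 - ch$i),
                  df * ch$f * (1 - ch$f),
                  dg * (1 - ch$g^2),
                  do_ * ch$o * (1 - ch$o))
      gW[[l]]$W <- gW[[l]]$W + ch$z %*% t(da)
      gW[[l]]$b <- gW[[l]]$b + rowSums(da)
      dz <- W %*% da
      d_below[[t]] <- dz[seq_len(Din), , drop = FALSE]
      dh_next <- dz[(Din + 1):(Din + H), , drop = FALSE]
    }
    d_in_above <- d_below
  }
  list(gWs = gW, gWy = gWy, gby = gby)
}

adam_update <- function(p, g, st, key, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  m <- (st[[paste0(key, "_m")]] %||% 0) * b1 + (1 - b1) * g
  v <- (st[[paste0(key, "_v")]] %||% 0) * b2 + (1 - b2) * g^2
  st[[paste0(key, "_m")]] <- m
  st[[paste0(key, "_v")]] <- v
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), st = st)
}

train_lstm <- function(X, labels, K, cfg) {
  D <- dim(X)[2]
  par <- lstm_init(D, cfg$hidden, cfg$layers, K,
                   derive_seed(cfg$seed, "lstm_init"))
  st <- list()
  step <- 0
  best <- Inf; stall <- 0
  n <- dim(X)[3]
  with_seed(derive_seed(cfg$seed, "lstm_train"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
        Xb <- X[, , bi, drop = FALSE]
        fw <- lstm_forward(par, Xb, cfg$dropout, train = TRUE)
        sx <- softmax_xent(fw$logits, labels[bi])
        losses <- c(losses, sx$loss)
        bw <- lstm_backward(par, Xb, fw, sx$dZ)
        step <- step + 1
        for (l in seq_len(cfg$layers)) {
          u <- adam_update(par$Ws[[l]]$W, bw$gWs[[l]]$W / length(bi), st,
                           paste0("W", l), cfg$lr, step)
          par$Ws[[l]]$W <- u$p; st <- u$st
          u <- adam_update(par$Ws[[l]]$b, bw$gWs[[l]]$b / length(bi), st,
                           paste0("b", l), cfg$lr, step)
          par$Ws[[l]]$b <- u$p; st <- u$st
        }
        u <- adam_update(par$Wy, bw$gWy / length(bi), st, "Wy", cfg$lr, step)
        par$Wy <- u$p; st <- u$st
        u <- adam_update(par$by, bw$gby / length(bi), st, "by", cfg$lr, step)
        par$by <- u$p; st <- u$st
      }
      ml <- mean(losses)
      if (ml < best - 1e-4) {
        best <- ml; stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= cfg$patience) break
      }
    }
  })
  par
}

lstm_predict <- function(par, X) {
  fw <- lstm_forward(par, X, dropout = 0, train = FALSE)
  max.col(t(fw$logits))
}

#' Cross-validated LSTM decoding accuracy for a facial region
#'
#' @param cohort a `synthetic_cohort` with keypoint tracks (or a
#'   prebuilt `trajectory_tensor` via `tensor`).
#' @param region region name (see [build_trajectory_tensor()]).
#' @param k folds of the stratified trial-level cross-validation.
#' @param cfg an [lstm_config()].
#' @param shuffle_labels permute training labels (chance-level control).
#' @param tensor optional prebuilt `trajectory_tensor` (skips rebuild).
#' @return object of class `lstm_cv_result`: `accuracy` (mean), `folds`
#'   (per-fold accuracy), `region`, `keypoints`.
#' @export
lstm_region_decoder <- function(cohort, region, k = 10,
                                cfg = lstm_config(),
                                shuffle_labels = FALSE, tensor = NULL) {
  tt <- tensor %||% build_trajectory_tensor(cohort, region,
                                            seed = cfg$seed)
  splits <- split_by_trial(list(trial_id = tt$trial_id,
                                labels = tt$labels),
                           "kfold", k = k, seed = cfg$seed)
  accs <- numeric(length(splits))
  for (fi in seq_along(splits)) {
    tr <- which(tt$trial_id %in% splits[[fi]]$train)
    te <- which(tt$trial_id %in% splits[[fi]]$test)
    labs <- tt$labels
    if (shuffle_labels) {
      labs[tr] <- with_seed(derive_seed(cfg$seed, paste0("shuf", fi)),
                            sample(labs[tr]))
    }
    par <- train_lstm(tt$tensor[, , tr, drop = FALSE], labs[tr],
                      length(tt$classes), cfg)
    pred <- lstm_predict(par, tt$tensor[, , te, drop = FALSE])
    accs[fi] <- mean(pred == tt$labels[te])
  }
  structure(list(accuracy = mean(accs), folds = accs, region = region,
                 keypoints = tt$keypoints),
            class = "lstm_cv_result")
}
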