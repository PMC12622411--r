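# Siamese contrastive embedding with the cross-mouse pair strategy.
#
# Pairs are labeled 1 ("same valence") only when the two frames come from
# DIFFERENT mice sharing a valence, and 0 ("different valence") only when
# they come from the SAME mouse with opposite valences, which forces the
# twin encoder to embed valence rather than identity. Neutral frames are
# excluded.

#' Contrastive (pairwise margin) loss
#'
#' `L = 1/(2N) * sum_i [ y_i d_i^2 + (1 - y_i) max(m - d_i, 0)^2 ]`, with
#' `y_i = 1` for similar pairs and `d_i` the Euclidean embedding distance.
#'
#' @param distances non-negative numeric vector of embedding distances.
#' @param labels 0/1 vector (1 = same valence).
#' @param m margin (> 0).
#' @return scalar loss.
#' @export
contrastive_loss <- function(distances, labels, m) {
  if (m <= 0) stop("margin must be positive")
  stopifnot(all(distances >= 0), all(labels %in% c(0, 1)),
            length(distances) == length(labels))
  n <- length(distances)
  sum(labels * distances^2 +
        (1 - labels) * pmax(m - distances, 0)^2) / (2 * n)
}

#' Empirical margin from training-pair distances
#'
#' The margin is the mean pairwise embedding distance over the training
#' pairs; the squared variant uses the mean squared distance instead.
#'
#' @param distances numeric embedding distances of training pairs.
#' @param squared use the mean of squared distances.
#' @return margin `m` (falls back to 1, with a warning, when all distances
#'   are zero).
#' @export
auto_margin <- function(distances, squared = FALSE) {
  if (length(distances) < 2) stop("need at least two pairs")
  m <- if (squared) mean(distances^2) else mean(distances)
  if (m == 0) {
    warning("all pair distances are zero; margin falls back to 1")
    m <- 1
  }
  m
}

#' Contrastive training configuration
#'
#' @param margin margin `m`; `NULL` selects it empirically from the
#'   initial embedding distances via [auto_margin()].
#' @param squared_margin use the squared-distance variant of the
#'   empirical margin.
#' @param embed_dim embedding dimensionality.
#' @param epochs,batch_size,lr,momentum,weight_decay optimizer settings.
#' @param input_side,channels backbone geometry.
#' @param seed integer seed.
#' @return object of class `contrastive_config`.
#' @export
contrastive_config <- function(margin = NULL, squared_margin = FALSE,
                               embed_dim = 8, epochs = 10, batch_size = 32,
                               lr = 0.005, momentum = 0.9,
                               weight_decay = 1e-4, input_side = 32,
                               channels = 8, seed = 0) {
  if (!is.null(margin) && margin <= 0) stop("margin must be positive")
  structure(list(margin = margin, squared_margin = squared_margin,
                 embed_dim = embed_dim, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 input_side = as.integer(input_side),
                 channels = as.integer(channels), seed = as.integer(seed)),
            class = "contrastive_config")
}

dataset_valences <- function(dataset) {
  cls <- dataset$classes[dataset$labels]
  v <- stimulus_valence()[ifelse(cls == "neutral", "water", cls)]
  unname(v)
}

#' Build a contrastive pair dataset under the cross-mouse strategy
#'
#' @param dataset a `frame_dataset` (neutral frames are excluded).
#' @param n_pairs total pairs (balanced 50/50 between the two categories).
#' @param seed integer seed.
#' @param mice optional subset of mouse ids to draw from.
#' @param max_per_mouse cap on pairs any one mouse participates in, to
#'   avoid identity dominance.
#' @return object of class `pair_dataset`: `i`, `j` (frame column
#'   indices), `label` (1 same valence / 0 different valence), `dataset`.
#' @export
make_pairs <- function(dataset, n_pairs = 200, seed = 0, mice = NULL,
                       max_per_mouse = Inf) {
  val <- dataset_valences(dataset)
  keep <- val %in% c("positive", "negative")
  if (!is.null(mice)) keep <- keep & dataset$mouse_id %in% mice
  idx <- which(keep)
  mouse <- dataset$mouse_id[idx]
  v <- val[idx]
  um <- unique(mouse)
  if (length(um) < 2) stop("need at least two mice")
  both <- vapply(um, function(m) {
    length(unique(v[mouse == m])) == 2
  }, logical(1))
  if (any(!both)) {
    warning("mice lacking one valence excluded from different-valence ",
            "sampling: ", paste(um[!both], collapse = ", "))
  }
  n_half <- floor(n_pairs / 2)
  with_seed(seed, {
    used <- stats::setNames(numeric(length(um)), um)
    pick <- function(pool) pool[sample.int(length(pool), 1)]
    ii <- integer(0); jj <- integer(0); yy <- integer(0)
    # same valence, different mice
    tries <- 0
    while (sum(yy == 1L) < n_half && tries < 50 * n_half) {
      tries <- tries + 1
      vv <- sample(c("positive", "negative"), 1)
      ms <- um[used[um] < max_per_mouse]
      ms <- ms[vapply(ms, function(m) any(mouse == m & v == vv), logical(1))]
      if (length(ms) < 2) next
      m2 <- sample(ms, 2)
      a <- pick(which(mouse == m2[1] & v == vv))
      b <- pick(which(mouse == m2[2] & v == vv))
      ii <- c(ii, idx[a]); jj <- c(jj, idx[b]); yy <- c(yy, 1L)
      used[m2] <- used[m2] + 1
    }
    # different valence, same mouse
    tries <- 0
    while (sum(yy == 0L) < n_pairs - n_half && tries < 50 * n_pairs) {
      tries <- tries + 1
      ms <- um[both & used[um] < max_per_mouse]
      if (length(ms) < 1) break
      m1 <- sample(ms, 1)
      a <- pick(which(mouse == m1 & v == "positive"))
      b <- pick(which(mouse == m1 & v == "negative"))
      ii <- c(ii, idx[a]); jj <- c(jj, idx[b]); yy <- c(yy, 0L)
      used[m1] <- used[m1] + 1
    }
    structure(list(i = ii, j = jj, label = yy, dataset = dataset),
              class = "pair_dataset")
  })
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("<pair_dataset> %d pairs (%d same / %d different valence)\n",
              length(x$label), sum(x$label == 1), sum(x$label == 0)))
  invisible(x)
}

embed_images <- function(model, images) {
  X <- (images - model$norm$mean) / model$norm$sd
  out <- matrix(NA_real_, model$n_out, ncol(X))
  for (b0 in seq(1, ncol(X), by = 256)) {
    bi <- b0:min(b0 + 255, ncol(X))
    out[, bi] <- nn_forward(model, X[, bi, drop = FALSE])$out
  }
  out
}

#' Embedding distances of a pair dataset
#'
#' @param model a trained Siamese encoder (`resnet_model`).
#' @param pairs a `pair_dataset`.
#' @return numeric vector of Euclidean embedding distances.
#' @export
siamese_distances <- function(model, pairs) {
  d <- pairs$dataset
  cols <- sort(unique(c(pairs$i, pairs$j)))
  E <- embed_images(model, d$images[, cols, drop = FALSE])
  colnames(E) <- as.character(cols)
  e1 <- E[, as.character(pairs$i), drop = FALSE]
  e2 <- E[, as.character(pairs$j), drop = FALSE]
  sqrt(colSums((e1 - e2)^2))
}

#' Train the Siamese contrastive embedding
#'
#' Twin copies of the reduced residual backbone with shared weights embed
#' each pair member; minibatch gradients of the contrastive loss flow
#' through both branches and are summed on the shared parameters.
#'
#' @param pairs a `pair_dataset` (training pairs).
#' @param cfg a [contrastive_config()].
#' @param eval_pairs optional `pair_dataset` (e.g. from held-out mice);
#'   their distances are returned for evaluation.
#' @return object of class `siamese_fit`: `model`, `margin`,
#'   `train_distances`, `eval_distances` (with labels), `history`.
#' @export
train_siamese <- function(pairs, cfg = contrastive_config(),
                          eval_pairs = NULL) {
  d <- pairs$dataset
  stopifnot(d$side == cfg$input_side)
  cols <- sort(unique(c(pairs$i, pairs$j)))
  mu <- rowMeans(d$images[, cols, drop = FALSE])
  sg <- sd(d$images[, cols, drop = FALSE] - mu)
  if (!is.finite(sg) || sg == 0) sg <- 1
  model <- build_resnet(d$side, cfg$channels, cfg$embed_dim,
                        seed = cfg$seed)
  model$norm <- list(mean = mu, sd = sg)

  margin <- cfg$margin
  if (is.null(margin)) {
    d0 <- siamese_distances(model, pairs)
    margin <- auto_margin(d0, squared = cfg$squared_margin)
  }

  n <- length(pairs$label)
  state <- list()
  history <- numeric(cfg$epochs)
  with_seed(derive_seed(cfg$seed, "siamese"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
        nb <- length(bi)
        X1 <- (d$images[, pairs$i[bi], drop = FALSE] - mu) / sg
        X2 <- (d$images[, pairs$j[bi], drop = FALSE] - mu) / sg
        y <- pairs$label[bi]
        f1 <- nn_forward(model, X1)
        f2 <- nn_forward(model, X2)
        diff <- f1$out - f2$out
        dist <- sqrt(colSums(diff^2))
        losses <- c(losses, contrastive_loss(dist, y, margin))
        # dL/dd per pair, then chain to each embedding
        dLdd <- (y * dist - (1 - y) * pmax(margin - dist, 0)) / nb
        safe <- pmax(dist, 1e-8)
        dE <- sweep(diff, 2, dLdd / safe, "*")
        b1 <- nn_backward(model, f1, dE)
        b2 <- nn_backward(model, f2, -dE)
        g <- mapply(function(ga, gb) {
          if (is.null(ga)) return(NULL)
          mapply(`+`, ga, gb, SIMPLIFY = FALSE)
        }, b1$grads, b2$grads, SIMPLIFY = FALSE)
        st <- sgd_step(model, g, state, cfg$lr, cfg$momentum,
                       cfg$weight_decay)
        model <- st$model
        state <- st$state
      }
      history[ep] <- mean(losses)
    }
  })

  ev <- NULL
  if (!is.null(eval_pairs)) {
    ev <- list(distances = siamese_distances(model, eval_pairs),
               labels = eval_pairs$label)
  }
  structure(list(model = model, margin = margin,
                 train_distances = siamese_distances(model, pairs),
                 train_labels = pairs$label,
                 eval_distances = ev, history = history),
            class = "siamese_fit")
}

#' Similarity Grad-CAM for a Siamese pair
#'
#' Backpropagates the negative embedding distance for same-valence pairs
#' (features supporting similarity) or the positive distance for
#' different-valence pairs (features driving dissimilarity) through each
#' branch's last convolutional layer; maps are rectified and normalized
#' to [0, 1].
#'
#' @param model a trained Siamese encoder.
#' @param img1,img2 images (matrices or pixel vectors) on the model input
#'   side.
#' @param pair_label 1 (same valence) or 0 (different valence).
#' @return list with `map1`, `map2` ([0, 1] matrices), `distance`, and
#'   `flag` (`"zero_distance"` with all-zero maps for identical inputs).
#' @export
similarity_gradcam <- function(model, img1, img2, pair_label) {
  x1 <- matrix(as.numeric(img1), ncol = 1)
  x2 <- matrix(as.numeric(img2), ncol = 1)
  x1 <- (x1 - model$norm$mean) / model$norm$sd
  x2 <- (x2 - model$norm$mean) / model$norm$sd
  f1 <- nn_forward(model, x1)
  f2 <- nn_forward(model, x2)
  diff <- f1$out - f2$out
  dist <- sqrt(sum(diff^2))
  S <- model$input_side
  if (dist < 1e-12) {
    z <- matrix(0, S, S)
    return(list(map1 = z, map2 = z, distance = dist,
                flag = "zero_distance"))
  }
  sgn <- if (pair_label == 1) -1 else 1
  dE <- sgn * diff / dist
  branch_map <- function(fw, dOut) {
    bw <- nn_backward(model, fw, dOut, stop_at = model$last_conv)
    A <- fw$acts[[model$last_conv]]
    alpha <- colMeans(matrix(bw$dX, dim(A)[1], dim(A)[2]))
    raw <- pmax(matrix(matrix(A, dim(A)[1], dim(A)[2]) %*% alpha,
                       model$conv_side, model$conv_side), 0)
    up <- pmax(resize_image(raw, S), 0)
    if (max(up) > 0) up <- up / max(up)
    up
  }
  list(map1 = branch_map(f1, dE), map2 = branch_map(f2, -dE),
       distance = dist, flag = NA_character_)
}
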