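# Minimal convolutional network engine.
#
# Activations flow through the conv stack as (H*W, channels, batch)
# arrays; 3x3 same-padding convolutions are evaluated as a single BLAS
# matrix product per batch via im2col gather indices, and their backward
# pass scatters gradients back with rowsum(). The engine supports exactly
# what the decoders need: conv / relu / 2x2 average pooling / residual
# blocks / global average pooling / dense heads, SGD with momentum and L2
# weight decay, and targeted backpropagation to the last convolutional
# layer for gradient-weighted class-activation maps.

# gather indices for 3x3 same-padding im2col; pad slot = H*W + 1
conv_idx3 <- function(H, W) {
  HW <- H * W
  y <- rep(seq_len(H), W)
  x <- rep(seq_len(W), each = H)
  idx <- matrix(0L, HW, 9)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    yy <- y + dy; xx <- x + dx
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- rep.int(HW + 1L, HW)
    v[ok] <- yy[ok] + (xx[ok] - 1L) * H
    idx[, k] <- v
  }
  idx
}

he_init <- function(fan_in, n) rnorm(n, sd = sqrt(2 / fan_in))

layer_conv <- function(H, W, Cin, Cout) {
  list(type = "conv", H = H, W = W, Cin = Cin, Cout = Cout,
       Wt = matrix(he_init(9 * Cin, 9 * Cin * Cout), 9 * Cin, Cout),
       b = numeric(Cout), idx = conv_idx3(H, W))
}

layer_res <- function(H, W, C) {
  list(type = "res", H = H, W = W, C = C,
       conv1 = layer_conv(H, W, C, C), conv2 = layer_conv(H, W, C, C))
}

conv_forward <- function(ly, X) {
  # X: (HW, Cin, N)
  HW <- ly$H * ly$W
  N <- dim(X)[3]
  Xm <- matrix(X, HW, ly$Cin * N)
  Xp <- rbind(Xm, 0)
  G <- Xp[as.vector(ly$idx), , drop = FALSE]      # (HW*9, Cin*N)
  dim(G) <- c(HW, 9, ly$Cin, N)
  G <- aperm(G, c(2, 3, 1, 4))
  dim(G) <- c(9 * ly$Cin, HW * N)
  out <- crossprod(ly$Wt, G) + ly$b               # (Cout, HW*N)
  dim(out) <- c(ly$Cout, HW, N)
  list(out = aperm(out, c(2, 1, 3)), G = G)
}

conv_backward <- function(ly, cache, dOut) {
  HW <- ly$H * ly$W
  N <- dim(dOut)[3]
  dY <- aperm(dOut, c(2, 1, 3))
  dim(dY) <- c(ly$Cout, HW * N)
  db <- rowSums(dY)
  dW <- cache$G %*% t(dY)
  dG <- ly$Wt %*% dY                              # (9*Cin, HW*N)
  dim(dG) <- c(9, ly$Cin, HW, N)
  dG <- aperm(dG, c(3, 1, 2, 4))
  dim(dG) <- c(HW * 9, ly$Cin * N)
  dXp <- rowsum(dG, rep.int(as.vector(ly$idx), 1), reorder = TRUE)
  # rows of dXp correspond to sorted unique indices 1..HW(+1)
  dXm <- dXp[seq_len(HW), , drop = FALSE]
  dim(dXm) <- c(HW, ly$Cin, N)
  list(dX = dXm, dW = dW, db = db)
}

pool_forward <- function(X, H, W) {
  C <- dim(X)[2]; N <- dim(X)[3]
  dim(X) <- c(2, H / 2, 2, W / 2, C, N)
  out <- (X[1, , 1, , , , drop = FALSE] + X[2, , 1, , , , drop = FALSE] +
            X[1, , 2, , , , drop = FALSE] + X[2, , 2, , , , drop = FALSE]) / 4
  dim(out) <- c(H * W / 4, C, N)
  out
}

pool_backward <- function(dOut, H, W) {
  C <- dim(dOut)[2]; N <- dim(dOut)[3]
  dim(dOut) <- c(H / 2, W / 2, C, N)
  up <- array(0, c(2, H / 2, 2, W / 2, C, N))
  for (a in 1:2) for (b in 1:2) {
    up[a, , b, , , ] <- dOut / 4
  }
  dim(up) <- c(H * W, C, N)
  up
}

#' Build the reduced residual frame classifier / encoder backbone
#'
#' conv(1 -> C) + relu at full resolution, 2x2 average pool, a residual
#' block, pool, a second residual block (whose rectified activations are
#' the Grad-CAM target layer), global average pooling, and a dense head.
#'
#' @param input_side input image side (px, divisible by 4).
#' @param channels convolutional width.
#' @param n_out output dimension (classes, or embedding size).
#' @param seed integer seed for the He-normal initialization.
#' @return object of class `resnet_model`.
#' @export
build_resnet <- function(input_side = 32, channels = 8, n_out = 5,
                         seed = 0) {
  stopifnot(input_side %% 4 == 0)
  S <- input_side
  with_seed(seed, {
    layers <- list(
      layer_conv(S, S, 1, channels),
      list(type = "relu"),
      list(type = "pool", H = S, W = S),
      layer_res(S / 2, S / 2, channels),
      list(type = "pool", H = S / 2, W = S / 2),
      layer_res(S / 4, S / 4, channels),
      list(type = "gap", HW = (S / 4)^2),
      list(type = "dense",
           Wt = matrix(he_init(channels, channels * n_out),
                       channels, n_out),
           b = numeric(n_out)))
    structure(list(layers = layers, input_side = S, channels = channels,
                   n_out = n_out, last_conv = 6L,
                   conv_side = S / 4, norm = list(mean = 0, sd = 1)),
              class = "resnet_model")
  })
}

#' @export
print.resnet_model <- function(x, ...) {
  cat(sprintf("<resnet_model> %d px input, %d channels, %d outputs\n",
              x$input_side, x$channels, x$n_out))
  invisible(x)
}

# forward pass; X images as (npix, N) matrix, normalized by caller
nn_forward <- function(model, X) {
  N <- ncol(X)
  A <- array(X, c(model$input_side^2, 1, N))
  caches <- vector("list", length(model$layers))
  acts <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      cf <- conv_forward(ly, A)
      A <- cf$out
      caches[[i]] <- list(G = cf$G)
    } else if (ly$type == "relu") {
      mask <- A > 0
      A <- A * mask
      caches[[i]] <- list(mask = mask)
    } else if (ly$type == "pool") {
      caches[[i]] <- list(input_dim = dim(A))
      A <- pool_forward(A, ly$H, ly$W)
    } else if (ly$type == "res") {
      x_in <- A
      c1 <- conv_forward(ly$conv1, A)
      m1 <- c1$out > 0
      h1 <- c1$out * m1
      c2 <- conv_forward(ly$conv2, h1)
      pre <- c2$out + x_in
      m2 <- pre > 0
      A <- pre * m2
      caches[[i]] <- list(G1 = c1$G, m1 = m1, G2 = c2$G, m2 = m2)
    } else if (ly$type == "gap") {
      d <- dim(A)
      caches[[i]] <- list(input_dim = d)
      A <- matrix(colMeans(matrix(A, d[1], d[2] * d[3])), d[2], d[3])
    } else if (ly$type == "dense") {
      caches[[i]] <- list(X = A)
      A <- crossprod(ly$Wt, A) + ly$b
    }
    acts[[i]] <- A
  }
  list(out = A, caches = caches, acts = acts)
}

# backward pass from dOut (gradient w.r.t. final output);
# stop_at: return dX entering layer `stop_at` without accumulating further
nn_backward <- function(model, fw, dOut, stop_at = 0L) {
  grads <- vector("list", length(model$layers))
  dA <- dOut
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    ch <- fw$caches[[i]]
    if (ly$type == "dense") {
      Xin <- ch$X
      grads[[i]] <- list(dW = Xin %*% t(dA), db = rowSums(dA))
      dA <- ly$Wt %*% dA
    } else if (ly$type == "gap") {
      d <- ch$input_dim
      dA <- array(rep(dA / d[1], each = d[1]), d)
    } else if (ly$type == "pool") {
      dA <- pool_backward(dA, ly$H, ly$W)
    } else if (ly$type == "relu") {
      dA <- dA * ch$mask
    } else if (ly$type == "conv") {
      cb <- conv_backward(ly, ch, dA)
      grads[[i]] <- list(dW = cb$dW, db = cb$db)
      dA <- cb$dX
    } else if (ly$type == "res") {
      d_post <- dA * ch$m2
      cb2 <- conv_backward(ly$conv2, list(G = ch$G2), d_post)
      d_h1 <- cb2$dX * ch$m1
      cb1 <- conv_backward(ly$conv1, list(G = ch$G1), d_h1)
      grads[[i]] <- list(dW1 = cb1$dW, db1 = cb1$db,
                         dW2 = cb2$dW, db2 = cb2$db)
      dA <- cb1$dX + d_post
    }
    if (i == stop_at + 1L) {
      return(list(grads = grads, dX = dA))
    }
  }
  list(grads = grads, dX = dA)
}

# flatten/apply parameter updates (SGD with momentum + L2 weight decay)
sgd_step <- function(model, grads, state, lr, momentum = 0.9,
                     weight_decay = 1e-4, batch_n = 1) {
  upd <- function(Wname, ly, g, key) {
    v_old <- state[[key]] %||% 0
    gg <- g / batch_n + weight_decay * ly[[Wname]]
    v <- momentum * v_old - lr * gg
    state[[key]] <<- v
    ly[[Wname]] <- ly[[Wname]] + v
    ly
  }
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- model$layers[[i]]
    if (ly$type %in% c("conv", "dense")) {
      ly <- upd("Wt", ly, g$dW, paste0("W", i))
      ly <- upd("b", ly, g$db, paste0("b", i))
    } else if (ly$type == "res") {
      ly$conv1 <- upd("Wt", ly$conv1, g$dW1, paste0("W", i, "a"))
      ly$conv1 <- upd("b", ly$conv1, g$db1, paste0("b", i, "a"))
      ly$conv2 <- upd("Wt", ly$conv2, g$dW2, paste0("W", i, "b"))
      ly$conv2 <- upd("b", ly$conv2, g$db2, paste0("b", i, "b"))
    }
    model$layers[[i]] <- ly
  }
  list(model = model, state = state)
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

# cross-entropy loss and gradient w.r.t. logits; labels in 1..K
softmax_xent <- function(logits, labels) {
  P <- softmax_cols(logits)
  n <- length(labels)
  idx <- cbind(labels, seq_len(n))
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, dZ = dZ / n)
}
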