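# Unsupervised embedding of frame descriptors: PCA -> 2-D neighbor
# embedding -> k-means.
#
# No UMAP implementation ships with this package's R dependencies, so the
# nonlinear step is a compact in-package neighbor-graph embedding of the
# UMAP family: a fuzzy k-nearest-neighbor graph (local connectivity via
# per-point bandwidth calibration) optimized in 2-D by attraction along
# graph edges and repulsion against negative samples, initialized from the
# first two principal components. It is seeded and deterministic.

# per-point bandwidth so that sum_j exp(-(d_ij - rho_i)/sigma_i) = log2(k)
smooth_knn_weights <- function(d, rho, target, n_iter = 64) {
  lo <- 0; hi <- Inf; mid <- 1
  for (it in seq_len(n_iter)) {
    val <- sum(exp(-pmax(0, d - rho) / mid))
    if (abs(val - target) < 1e-5) break
    if (val > target) {
      hi <- mid; mid <- (lo + hi) / 2
    } else {
      lo <- mid
      mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2
    }
  }
  exp(-pmax(0, d - rho) / mid)
}

umap_embed <- function(X, n_neighbors = 45, n_epochs = 200, seed = 0,
                       a = 1.577, b = 0.8951, learning_rate = 1,
                       negative_samples = 3) {
  n <- nrow(X)
  k <- max(2L, min(n_neighbors, n - 1L))
  D <- as.matrix(dist(X))
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    idx <- order(d)[seq_len(k)]
    nb <- seq_len(n)[-i][idx]
    dk <- d[idx]
    rho <- min(dk[dk > 0], Inf)
    if (!is.finite(rho)) rho <- 0
    w <- smooth_knn_weights(dk, rho, log2(k))
    ii <- c(ii, rep(i, k)); jj <- c(jj, nb); ww <- c(ww, w)
  }
  # symmetrize: fuzzy union  w_ij + w_ji - w_ij w_ji
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  Wt <- Matrix::t(W)
  Wu <- W + Wt - W * Wt
  ed <- Matrix::summary(Wu)
  ed <- ed[ed$i < ed$j, , drop = FALSE]

  # PCA init, scaled to a compact layout
  init <- prcomp(X, rank. = 2)$x
  init <- sweep(init, 2, apply(init, 2, sd) + 1e-9, "/")
  Y <- init

  ei <- ed$i; ej <- ed$j; ew <- ed$x / max(ed$x)
  m <- length(ei)
  with_seed(seed, {
    for (ep in seq_len(n_epochs)) {
      alpha <- learning_rate * (1 - (ep - 1) / n_epochs)
      dy <- Y[ei, , drop = FALSE] - Y[ej, , drop = FALSE]
      d2 <- rowSums(dy^2)
      ga <- (-2 * a * b * d2^(b - 1)) / (1 + a * d2^b)
      ga[!is.finite(ga)] <- 0
      g <- alpha * ew * ga * dy
      g <- pmax(pmin(g, 4), -4)
      upd <- rowsum(rbind(g, -g), c(ei, ej))
      ridx <- as.integer(rownames(upd))
      Y[ridx, ] <- Y[ridx, ] + upd
      for (s in seq_len(negative_samples)) {
        nj <- sample.int(n, m, replace = TRUE)
        dy <- Y[ei, , drop = FALSE] - Y[nj, , drop = FALSE]
        d2 <- rowSums(dy^2)
        gr <- (2 * b) / ((0.001 + d2) * (1 + a * d2^b))
        g <- alpha * ew * gr * dy
        g <- pmax(pmin(g, 4), -4)
        upd <- rowsum(g, ei)
        ridx <- as.integer(rownames(upd))
        Y[ridx, ] <- Y[ridx, ] + upd
      }
    }
  })
  colnames(Y) <- c("x", "y")
  Y
}

#' Embed frame descriptors and cluster the embedding
#'
#' PCA reduces the HOG matrix to at most `pca_dims` dimensions, a seeded
#' 2-D neighbor embedding lays the frames out, and k-means on the 2-D
#' coordinates assigns cluster labels (matching the convention of drawing
#' cluster centers in the embedding plane).
#'
#' @param hog_matrix numeric matrix, frames x features.
#' @param pca_dims PCA target dimensionality (clamped to
#'   `min(n_frames - 1, n_features)`).
#' @param n_neighbors neighborhood size of the embedding graph.
#' @param k number of k-means clusters (>= 2; clamped to the number of
#'   distinct frames when the input is degenerate).
#' @param seed integer seed for the embedding and k-means.
#' @param n_epochs embedding optimization epochs.
#' @return object of class `embedding_result`: `coords` (frames x 2),
#'   `labels`, `centers`, `pca_dims`, `n_neighbors`.
#' @export
embed_expressions <- function(hog_matrix, pca_dims = 400, n_neighbors = 45,
                              k, seed = 0, n_epochs = 200) {
  if (k < 2) stop("k must be >= 2")
  n <- nrow(hog_matrix)
  n_distinct <- nrow(unique(hog_matrix))
  if (n_distinct == 1) {
    # fully degenerate input: a single cluster at a single location
    coords <- matrix(0, n, 2, dimnames = list(NULL, c("x", "y")))
    return(structure(list(coords = coords, labels = rep(1L, n),
                          centers = matrix(0, 1, 2), pca_dims = 0L,
                          n_neighbors = n_neighbors, k = 1L),
                     class = "embedding_result"))
  }
  pca_dims <- min(pca_dims, n - 1L, ncol(hog_matrix))
  Z <- prcomp(hog_matrix, rank. = pca_dims)$x
  Y <- umap_embed(Z, n_neighbors = n_neighbors, n_epochs = n_epochs,
                  seed = seed)
  k <- min(k, n_distinct)
  km <- with_seed(derive_seed(seed, "kmeans"),
                  kmeans(Y, centers = k, nstart = 10, iter.max = 50))
  structure(list(coords = Y, labels = km$cluster, centers = km$centers,
                 pca_dims = pca_dims, n_neighbors = n_neighbors, k = k),
            class = "embedding_result")
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b integer label vectors of equal length.
#' @return adjusted Rand index in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- si * sj / ch2(n)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
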