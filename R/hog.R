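# Histogram-of-oriented-gradients frame descriptors.
#
# Unsigned gradient orientations (0-180 deg) are histogrammed per cell by
# gradient magnitude; with 1x1 cells per block, block normalization
# degenerates to per-cell L2 normalization, guarded so that zero-gradient
# cells yield zero histograms.

#' HOG configuration
#'
#' The reference configuration is 8 orientation bins and 16 x 16 px cells
#' at a 1024-px input; the cell size scales proportionally with the input
#' side so the descriptor length is invariant across canvas scalings.
#'
#' @param input_side input image side (px).
#' @param orientations number of unsigned orientation bins.
#' @param cell_size cell side (px); defaults to `16 * input_side / 1024`.
#' @param cells_per_block cells per normalization block (only 1 supported).
#' @return object of class `hog_config`.
#' @export
hog_config <- function(input_side, orientations = 8, cell_size = NULL,
                       cells_per_block = 1) {
  cell_size <- cell_size %||% max(1L, round(16 * input_side / 1024))
  if (cells_per_block != 1) {
    stop("only 1 x 1 cells per block is supported")
  }
  if (input_side %% cell_size != 0) {
    stop("input_side must be divisible by cell_size")
  }
  structure(list(input_side = as.integer(input_side),
                 orientations = as.integer(orientations),
                 cell_size = as.integer(cell_size),
                 cells_per_block = 1L),
            class = "hog_config")
}

#' Length of the HOG descriptor under a configuration
#' @param config a [hog_config()].
#' @return integer vector length `(input_side / cell_size)^2 * orientations`.
#' @export
hog_length <- function(config) {
  (config$input_side %/% config$cell_size)^2 * config$orientations
}

#' Compute the HOG descriptor of a grayscale frame
#'
#' @param image numeric matrix (rows = y) with side `config$input_side`.
#' @param config a [hog_config()].
#' @param eps zero-norm guard for cell normalization.
#' @return numeric `hog_vector` (non-negative, attribute `config`).
#' @export
compute_hog <- function(image, config, eps = 1e-12) {
  S <- config$input_side
  if (!is.matrix(image) || nrow(image) != S || ncol(image) != S) {
    stop("image side must equal config$input_side")
  }
  # central differences, zero at the borders
  gx <- matrix(0, S, S)
  gy <- matrix(0, S, S)
  gx[, 2:(S - 1)] <- image[, 3:S] - image[, 1:(S - 2)]
  gy[2:(S - 1), ] <- image[3:S, ] - image[1:(S - 2), ]
  mag <- sqrt(gx^2 + gy^2)
  theta <- atan2(gy, gx) * 180 / pi      # (-180, 180]
  theta <- theta %% 180                  # unsigned orientation [0, 180)

  nb <- config$orientations
  bin <- pmin(nb - 1L, floor(theta / (180 / nb)))
  cs <- config$cell_size
  nc <- S %/% cs
  row_i <- (seq_len(S) - 1L) %/% cs
  cell <- matrix(row_i, S, S) + nc * matrix(row_i, S, S, byrow = TRUE)
  group <- bin + nb * cell               # 0-based combined index
  v <- rowsum(as.vector(mag), as.vector(group))
  out <- numeric(nc * nc * nb)
  out[as.integer(rownames(v)) + 1L] <- v

  # per-cell L2 normalization with zero-norm guard
  m <- matrix(out, nrow = nb)
  norms <- sqrt(colSums(m^2))
  keep <- norms > eps
  m[, keep] <- sweep(m[, keep, drop = FALSE], 2, norms[keep], "/")
  m[, !keep] <- 0
  structure(as.numeric(m), config = config, class = "hog_vector")
}

#' HOG matrix of a list of frames
#'
#' @param frames list of grayscale matrices (equal side).
#' @param config a [hog_config()]; defaults to the frame side.
#' @return numeric matrix, frames x features.
#' @export
hog_matrix <- function(frames, config = NULL) {
  config <- config %||% hog_config(nrow(frames[[1]]))
  t(vapply(frames, function(f) as.numeric(compute_hog(f, config)),
           numeric(hog_length(config))))
}

#' Cosine similarity between two descriptor vectors
#'
#' `cos(a, b) = (a . b) / (||a|| ||b||)`; symmetric and invariant to
#' positive rescaling of either argument.
#'
#' @param a,b numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return similarity in [-1, 1].
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity is undefined for a zero vector")
  }
  sum(a * b) / (na * nb)
}

# rows-normalized cosine similarity matrix between row sets
cosine_matrix <- function(A, B = A) {
  nA <- sqrt(rowSums(A^2)); nB <- sqrt(rowSums(B^2))
  if (any(nA == 0) || any(nB == 0)) {
    stop("cosine similarity is undefined for a zero vector")
  }
  (A / nA) %*% t(B / nB)
}
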