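# Landmark-based cross-animal coregistration: least-squares affine
# initialization, similarity-restricted refinement, frame warping and
# overlay QC.

#' Six-landmark set used for coregistration
#'
#' @param nose_tip,inner_eye_corner,outer_eye_corner,lower_lip_anterior,cheek,pinna_posterior_edge
#'   numeric length-2 points (x, y) in pixel coordinates.
#' @return object of class `landmark_set` (6 x 2 matrix with row names).
#' @export
landmark_set <- function(nose_tip, inner_eye_corner, outer_eye_corner,
                         lower_lip_anterior, cheek, pinna_posterior_edge) {
  m <- rbind(nose_tip = nose_tip, inner_eye_corner = inner_eye_corner,
             outer_eye_corner = outer_eye_corner,
             lower_lip_anterior = lower_lip_anterior, cheek = cheek,
             pinna_posterior_edge = pinna_posterior_edge)
  if (!all(is.finite(m))) stop("landmarks must be finite")
  if (anyDuplicated(round(m, 9))) stop("landmarks must be distinct")
  structure(m, class = c("landmark_set", "matrix"))
}

#' Planar affine transform
#'
#' @param m numeric 2 x 3 matrix `[A | t]` mapping `(x, y)` to
#'   `A %*% c(x, y) + t`.
#' @return object of class `planar_transform`.
#' @export
planar_transform <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(2, 3)))
  if (abs(det(m[, 1:2])) < 1e-12) {
    stop("transform is not invertible")
  }
  structure(m, class = c("planar_transform", "matrix"))
}

#' @export
print.planar_transform <- function(x, ...) {
  cat("<planar_transform>\n")
  print(unclass(x))
  d <- decompose_transform(x)
  cat(sprintf("  ~similarity: scale %.4f, rotation %.3f deg, translation (%.2f, %.2f)\n",
              d$scale, d$rotation_deg, d$translation[1], d$translation[2]))
  invisible(x)
}

identity_transform <- function() {
  planar_transform(cbind(diag(2), c(0, 0)))
}

#' Decompose the linear part of a transform into similarity parameters
#'
#' Uses the polar decomposition (nearest rotation in the Frobenius sense);
#' exact for similarity transforms.
#'
#' @param tf a [planar_transform()].
#' @return list with `scale`, `rotation_deg` (y-down pixel convention) and
#'   `translation`.
#' @export
decompose_transform <- function(tf) {
  A <- unclass(tf)[, 1:2]
  sv <- svd(A)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {  # keep a proper rotation
    sv$v[, 2] <- -sv$v[, 2]
    R <- sv$u %*% t(sv$v)
  }
  list(scale = mean(sv$d), rotation_deg = atan2(R[2, 1], R[1, 1]) * 180 / pi,
       translation = unclass(tf)[, 3])
}

similarity_matrix <- function(scale, rotation_deg, tx, ty) {
  th <- rotation_deg * pi / 180
  A <- scale * rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  planar_transform(cbind(A, c(tx, ty)))
}

#' Compose and invert planar transforms
#'
#' `compose_transforms(t2, t1)` maps a point through `t1` first, then `t2`.
#'
#' @param t2,t1,tf [planar_transform()] objects.
#' @return a `planar_transform`.
#' @export
compose_transforms <- function(t2, t1) {
  A2 <- unclass(t2)[, 1:2]; A1 <- unclass(t1)[, 1:2]
  planar_transform(cbind(A2 %*% A1,
                         A2 %*% unclass(t1)[, 3] + unclass(t2)[, 3]))
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(tf) {
  A <- unclass(tf)[, 1:2]
  Ai <- solve(A)
  planar_transform(cbind(Ai, -Ai %*% unclass(tf)[, 3]))
}

#' Least-squares affine fit between two landmark sets
#'
#' Minimizes the summed squared distances between mapped source landmarks
#' and destination landmarks; exact (zero residual) whenever the
#' destination is an affine image of the source.
#'
#' @param src,dst [landmark_set()] objects (or n x 2 point matrices in
#'   correspondence).
#' @return list with `transform` (a [planar_transform()]), `residuals`
#'   (per-landmark distances) and `rmse`.
#' @export
fit_affine <- function(src, dst) {
  src <- unclass(src); dst <- unclass(dst)
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 3)
  X <- cbind(src, 1)
  if (qr(X)$rank < 3) {
    stop("source landmarks are collinear; affine fit is rank-deficient")
  }
  beta <- qr.solve(X, dst)           # 3 x 2
  tf <- planar_transform(t(beta)[, c(1, 2, 3)])
  mapped <- X %*% beta
  res <- sqrt(rowSums((mapped - dst)^2))
  list(transform = tf, residuals = res, rmse = sqrt(mean(res^2)))
}

similarity_objective <- function(par, src, dst) {
  if (any(!is.finite(par)) || abs(par[1]) > 20) return(1e300)
  th <- par[2] * pi / 180
  A <- exp(par[1]) * rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  mapped <- src %*% t(A)
  mapped[, 1] <- mapped[, 1] + par[3]
  mapped[, 2] <- mapped[, 2] + par[4]
  sum((mapped - dst)^2)
}

#' Refine an alignment to a similarity transform
#'
#' Optimizes translation, rotation and isotropic scale (4 parameters) to
#' minimize the summed squared landmark distances, initialized from the
#' similarity part of `init`. The returned objective never exceeds the
#' initialization's.
#'
#' @param src,dst landmark sets in correspondence.
#' @param init a [planar_transform()] (typically from [fit_affine()]).
#' @return list with `transform`, `scale`, `rotation_deg`, `translation`,
#'   `objective` and `converged`.
#' @export
refine_similarity <- function(src, dst, init = identity_transform()) {
  src <- unclass(src); dst <- unclass(dst)
  d0 <- decompose_transform(init)
  par0 <- c(log(max(d0$scale, 1e-6)), d0$rotation_deg,
            d0$translation[1], d0$translation[2])
  opt <- optim(par0, similarity_objective, src = src, dst = dst,
               method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  if (opt$value > similarity_objective(par0, src, dst) + 1e-9) {
    # never worse than the initialization's similarity restriction
    opt$par <- par0
    opt$value <- similarity_objective(par0, src, dst)
  }
  converged <- opt$convergence == 0
  if (!converged) warning("similarity refinement did not fully converge")
  tf <- similarity_matrix(exp(opt$par[1]), opt$par[2], opt$par[3],
                          opt$par[4])
  list(transform = tf, scale = exp(opt$par[1]), rotation_deg = opt$par[2],
       translation = opt$par[3:4], objective = opt$value,
       converged = converged)
}

#' Map points through a planar transform
#'
#' @param pts n x 2 matrix (or length-2 vector) of (x, y) points.
#' @param tf a [planar_transform()].
#' @return mapped points, same shape.
#' @export
map_points <- function(pts, tf) {
  one <- is.null(dim(pts))
  if (one) pts <- matrix(pts, 1)
  out <- pts %*% t(unclass(tf)[, 1:2])
  out[, 1] <- out[, 1] + unclass(tf)[1, 3]
  out[, 2] <- out[, 2] + unclass(tf)[2, 3]
  if (one) out[1, ] else out
}

#' Apply a planar transform to an image or to keypoints
#'
#' Images are warped by inverse mapping with bilinear (or nearest)
#' interpolation; out-of-canvas samples take the frame's median intensity
#' (or `fill`). Keypoints (data frames with `x`/`y`, point matrices or
#' [keypoint_track()] objects) are mapped forward.
#'
#' @param x grayscale matrix, n x 2 point matrix, data.frame with `x`,`y`,
#'   or a `keypoint_track`.
#' @param tf a [planar_transform()].
#' @param out_canvas output side for images (default: input side).
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @param fill fill intensity for out-of-bounds samples.
#' @return warped image or mapped keypoints, matching the input type.
#' @export
apply_transform <- function(x, tf, out_canvas = NULL,
                            interpolation = c("bilinear", "nearest"),
                            fill = NULL) {
  interpolation <- match.arg(interpolation)
  if (inherits(x, "keypoint_track")) {
    n <- dim(x$coords)[1]
    for (i in seq_len(n)) {
      x$coords[i, , ] <- map_points(x$coords[i, , ], tf)
    }
    return(x)
  }
  if (is.data.frame(x)) {
    m <- map_points(as.matrix(x[, c("x", "y")]), tf)
    x$x <- m[, 1]; x$y <- m[, 2]
    return(x)
  }
  if (is.matrix(x) && ncol(x) == 2 && is.null(fill)) {
    return(map_points(x, tf))
  }
  # image path
  S_in <- dim(x)
  S <- out_canvas %||% S_in[2]
  fill <- fill %||% median(x)
  inv <- invert_transform(tf)
  gx <- matrix(seq_len(S), S, S, byrow = TRUE)   # x = column
  gy <- matrix(seq_len(S), S, S)                 # y = row
  src <- cbind(as.vector(gx), as.vector(gy)) %*% t(unclass(inv)[, 1:2])
  sx <- src[, 1] + unclass(inv)[1, 3]
  sy <- src[, 2] + unclass(inv)[2, 3]
  out <- rep(fill, S * S)
  if (interpolation == "nearest") {
    rx <- round(sx); ry <- round(sy)
    ok <- rx >= 1 & rx <= S_in[2] & ry >= 1 & ry <= S_in[1]
    out[ok] <- x[cbind(ry[ok], rx[ok])]
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    ok <- x0 >= 1 & x0 + 1 <= S_in[2] & y0 >= 1 & y0 + 1 <= S_in[1]
    i00 <- cbind(y0[ok], x0[ok]); i01 <- cbind(y0[ok], x0[ok] + 1)
    i10 <- cbind(y0[ok] + 1, x0[ok]); i11 <- cbind(y0[ok] + 1, x0[ok] + 1)
    out[ok] <- x[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
      x[i01] * fx[ok] * (1 - fy[ok]) +
      x[i10] * (1 - fx[ok]) * fy[ok] +
      x[i11] * fx[ok] * fy[ok]
  }
  matrix(out, S, S)
}

#' Red/cyan alignment-quality overlay
#'
#' The unaligned frame fills the red channel, the aligned frame the green
#' and blue channels; gray pixels mark agreement, colored fringes mark
#' residual misalignment.
#'
#' @param unaligned,aligned grayscale matrices of equal size.
#' @return numeric array `height x width x 3` (RGB in [0, 1]).
#' @export
alignment_overlay <- function(unaligned, aligned) {
  stopifnot(all(dim(unaligned) == dim(aligned)))
  out <- array(0, c(dim(unaligned), 3))
  out[, , 1] <- unaligned
  out[, , 2] <- aligned
  out[, , 3] <- aligned
  out
}

#' Mean red-green disagreement of an overlay
#'
#' A scalar colorfulness score (mean `|R - G|`) that decreases as
#' registration improves.
#'
#' @param overlay array from [alignment_overlay()].
#' @return non-negative scalar.
#' @export
overlay_colorfulness <- function(overlay) {
  mean(abs(overlay[, , 1] - overlay[, , 2]))
}
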