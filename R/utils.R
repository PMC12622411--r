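#' @keywords internal
"_PACKAGE"

#' @importFrom stats prcomp kmeans runmed lm lsfit coef optim rnorm runif
#'   sd cor median quantile approx predict var rbinom
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's random stream. All stochastic code paths in the package flow
#' through this helper.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a parent seed and a label
#'
#' Deterministically fans one global seed out to independent per-stage or
#' per-unit seeds. Kept below 2^31 - 1.
#'
#' @param seed parent integer seed.
#' @param label character tag (stage or unit name).
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  as.integer((as.numeric(seed) * 48271 + h * 65537) %% 2147483647L)
}

stopifnot_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}

#' Angle of a 2-D vector in the y-up frame
#'
#' Image coordinates are y-down; all angle oracles convert to a y-up
#' mathematical frame before computing angles. Returns degrees in [0, 180]
#' measured against a reference axis.
#'
#' @param v numeric length-2 vector `(dx, dy)` in y-down pixel coordinates.
#' @param axis reference axis, `"+x"` or `"-x"`.
#' @param signed if `TRUE` return the signed angle in (-180, 180] instead of
#'   folding into [0, 180].
#' @return angle in degrees.
#' @export
vector_angle <- function(v, axis = c("+x", "-x"), signed = FALSE) {
  axis <- match.arg(axis)
  v <- unname(v)
  dx <- v[1]
  dy <- -v[2]  # to y-up
  if (axis == "-x") dx <- -dx
  a <- atan2(dy, dx) * 180 / pi
  if (signed) return(a)
  abs(a)
}

#' Interior angle at the middle vertex of three points
#'
#' @param p1,p2,p3 numeric length-2 points (y-down pixel coordinates); the
#'   angle is measured at `p2`.
#' @return angle in degrees in [0, 180], or `NA` if points coincide.
#' @export
interior_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Rotate a 2-D vector by an angle given in the y-up frame
#' @keywords internal
rotate_ydown <- function(v, deg) {
  # positive deg = counter-clockwise in the y-up frame
  th <- deg * pi / 180
  c(cos(th) * v[1] + sin(th) * v[2],
    -sin(th) * v[1] + cos(th) * v[2])
}

#' Unit vector at a y-up angle, expressed in y-down coordinates
#' @keywords internal
unit_ydown <- function(deg) {
  th <- deg * pi / 180
  c(cos(th), -sin(th))
}

#' Resize a grayscale matrix with bilinear interpolation
#'
#' Thin wrapper over [EBImage::resize()] returning a plain matrix.
#'
#' @param img numeric matrix (rows = y, columns = x).
#' @param side target side length in pixels.
#' @return numeric `side x side` matrix.
#' @export
resize_image <- function(img, side) {
  out <- EBImage::resize(img, w = side, h = side)
  matrix(as.numeric(out), side, side)
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}
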