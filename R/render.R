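# Schematic side-view face renderer.
#
# The face is vector-drawn (head ellipse, ear quadrilateral, eye + pupil,
# nose, mouth polyline, three straight whiskers) on a square canvas; the 37
# keypoints are the exact geometric construction points, so angle/distance
# oracles applied to them recover the generating phenotype identically.
# Pixel coordinates are y-down with pixel centres at integers; all angles
# are specified in the y-up mathematical frame.

# fixed layout of the reference 256-px canvas
.layout <- list(
  head_c = c(150, 150), head_ab = c(95, 75),
  ear_base = c(185, 85),
  eye_c = c(125, 125), eye_halfwidth = 12,
  nose_tip = c(52, 150), nose_bridge_dir = 35,
  nostril_c = c(62, 156), nostril_r = 4,
  snout_poly = rbind(c(95, 128), c(95, 172)),
  whisker_base = rbind(c(100, 150), c(100, 162), c(100, 174)),
  whisker_len = 55,
  ear_mid_frac = 0.55,
  mouth_corner_off = c(14, -4), mouth_center_off = c(7, 0)
)

#' Construct the 37 ground-truth keypoints of a schematic face
#'
#' Builds the keypoint set analytically from a phenotype, without
#' rasterizing. Keypoints are returned in y-down pixel coordinates on the
#' requested canvas; the region layout is 8 pupil, 4 eye, 5 ear, 5 nose,
#' 3 mouth and 12 whisker points.
#'
#' @param phenotype a [face_phenotype()].
#' @param canvas canvas side (px), >= 128; the reference layout (defined at
#'   256 px) and all phenotype lengths scale linearly.
#' @return data.frame with columns `name`, `region`, `x`, `y` (37 rows).
#' @export
face_keypoints <- function(phenotype, canvas = 256) {
  stopifnot_scalar_num(canvas, "canvas", min = 128)
  validate_phenotype(phenotype)
  u <- canvas / 256
  p <- phenotype
  L <- .layout

  nm <- character(37); rg <- character(37)
  xy <- matrix(NA_real_, 37, 2)
  ii <- 0L
  add <- function(name, region, pt) {
    ii <<- ii + 1L
    nm[ii] <<- name; rg[ii] <<- region
    xy[ii, ] <<- pt
  }

  # pupil: 8 points (4 cardinal + 4 diagonal) on a circle of diameter
  # pupil_diameter; the vertical top-bottom distance equals the diameter
  E <- L$eye_c * u
  r <- p$pupil_diameter * u / 2
  ang <- c(r = 0, dr = 45, d = 90, dl = 135, l = 180, ul = 225, u = 270,
           ur = 315)
  for (i in seq_along(ang)) {
    a <- ang[i] * pi / 180
    add(paste0("pupil_", names(ang)[i]), "pupil",
        E + r * c(cos(a), sin(a)))
  }

  # eye: four eyelid extremes
  add("eyelid_up", "eye", E + c(0, -p$eye_opening * u / 2))
  add("eyelid_down", "eye", E + c(0, p$eye_opening * u / 2))
  add("eyelid_inner", "eye", E + c(-L$eye_halfwidth * u, 0))
  add("eyelid_outer", "eye", E + c(L$eye_halfwidth * u, 0))

  # ear: base, posterior pinna edge at ear_angle/ear_length, two mid-ear
  # points at radius ear_mid_frac * length from the tip placed so that the
  # fold angle (at the tip, toward the outer mid point) and the width
  # (outer-inner distance) are met exactly, plus an anterior edge point
  B <- L$ear_base * u
  elen <- p$ear_length * u
  P <- B + elen * unit_ydown(p$ear_angle)
  rmid <- L$ear_mid_frac * elen
  wd <- min(p$ear_width * u, 2 * rmid * 0.999)  # keep asin defined
  phi <- 2 * asin(wd / (2 * rmid)) * 180 / pi
  bdir <- (B - P) / elen
  M_out <- P + rmid * rotate_ydown(bdir, p$ear_fold)
  M_in <- P + rmid * rotate_ydown(bdir, p$ear_fold - phi)
  add("ear_base", "ear", B)
  add("pinna_posterior", "ear", P)
  add("ear_mid_outer", "ear", M_out)
  add("ear_mid_inner", "ear", M_in)
  add("ear_anterior", "ear", (B + M_in) / 2)

  # nose: tip, bridge at nose_extension, nostril triangle (centroid fixed)
  N <- L$nose_tip * u
  add("nose_tip", "nose", N)
  add("nose_bridge", "nose", N + p$nose_extension * u *
        unit_ydown(L$nose_bridge_dir))
  Q <- L$nostril_c * u
  for (i in 1:3) {
    a <- (90 + 120 * (i - 1)) * pi / 180
    add(paste0("nostril_", i), "nose", Q + L$nostril_r * u * c(cos(a), sin(a)))
  }

  # mouth: the anterior lower lip lies on the circle of radius
  # snout_mouth_length around the nose tip, at the point where the interior
  # angle at the inner eye corner (between the nostril centre and the lip)
  # equals mouth_inclination; solved by bracketed root finding on the arc
  EL <- E + c(-L$eye_halfwidth * u, 0)
  LL <- solve_lower_lip(N, Q, EL, p$snout_mouth_length * u,
                        p$mouth_inclination)
  add("lower_lip", "mouth", LL)
  add("mouth_center", "mouth", LL + L$mouth_center_off * u)
  add("mouth_corner", "mouth", LL + L$mouth_corner_off * u)

  # whiskers: three straight 4-point whiskers at whisker_angle below -x
  wdir <- unit_ydown(180 + p$whisker_angle)
  for (w in 1:3) {
    base <- L$whisker_base[w, ] * u
    for (j in 0:3) {
      add(sprintf("whisker%d_p%d", w, j + 1), "whisker",
          base + (j / 3) * L$whisker_len * u * wdir)
    }
  }

  out <- data.frame(name = nm, region = rg, x = xy[, 1], y = xy[, 2])
  if (any(out$x < 2 | out$x > canvas - 1 | out$y < 2 | out$y > canvas - 1)) {
    bad <- out$name[out$x < 2 | out$x > canvas - 1 |
                      out$y < 2 | out$y > canvas - 1]
    stop("phenotype places keypoints off-canvas: ",
         paste(bad, collapse = ", "))
  }
  out
}

# find the lower-lip point: intersection of the ray from the inner eye
# corner rotated `incl` degrees below the nostril direction with the
# circle of radius s around the nose tip (lower intersection)
solve_lower_lip <- function(N, Q, EL, s, incl) {
  alpha_q <- atan2(-(Q[2] - EL[2]), Q[1] - EL[1]) * 180 / pi
  u <- unit_ydown(alpha_q + incl)
  w <- EL - N
  b <- sum(u * w)
  disc <- b^2 - sum(w^2) + s^2
  if (disc < 0) {
    stop("mouth construction unsolvable: inclination ", incl,
         " deg unreachable at snout-mouth length ", round(s, 2), " px")
  }
  t <- -b + sqrt(disc)  # far (lower) intersection
  if (t <= 0) {
    stop("mouth construction unsolvable: lip ray does not reach the circle")
  }
  EL + t * u
}

#' Map the 37-keypoint table to the six registration landmarks
#'
#' @param kp keypoint data.frame from [face_keypoints()].
#' @return a `landmark_set` (see [landmark_set()]).
#' @export
landmarks_from_keypoints <- function(kp) {
  g <- function(nm) unlist(kp[kp$name == nm, c("x", "y")], use.names = FALSE)
  landmark_set(nose_tip = g("nose_tip"),
               inner_eye_corner = g("eyelid_inner"),
               outer_eye_corner = g("eyelid_outer"),
               lower_lip_anterior = g("lower_lip"),
               cheek = g("whisker2_p1"),
               pinna_posterior_edge = g("pinna_posterior"))
}

# --- rasterization helpers (vectorized over the bounding box) -------------

fill_ellipse <- function(img, c0, a, b, val) {
  S <- nrow(img)
  xs <- max(1, floor(c0[1] - a)):min(S, ceiling(c0[1] + a))
  ys <- max(1, floor(c0[2] - b)):min(S, ceiling(c0[2] + b))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  m <- ((X - c0[1]) / a)^2 + ((Y - c0[2]) / b)^2 <= 1
  sub <- img[ys, xs, drop = FALSE]
  sub[m] <- val
  img[ys, xs] <- sub
  img
}

fill_polygon <- function(img, pts, val) {
  S <- nrow(img)
  xs <- max(1, floor(min(pts[, 1]))):min(S, ceiling(max(pts[, 1])))
  ys <- max(1, floor(min(pts[, 2]))):min(S, ceiling(max(pts[, 2])))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  inside <- matrix(FALSE, length(ys), length(xs))
  n <- nrow(pts)
  j <- n
  for (i in seq_len(n)) {
    xi <- pts[i, 1]; yi <- pts[i, 2]
    xj <- pts[j, 1]; yj <- pts[j, 2]
    cross <- ((yi > Y) != (yj > Y)) &
      (X < (xj - xi) * (Y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  sub <- img[ys, xs, drop = FALSE]
  sub[inside] <- val
  img[ys, xs] <- sub
  img
}

draw_segment <- function(img, p1, p2, val, width = 1.4) {
  S <- nrow(img)
  h <- width / 2 + 1
  xs <- max(1, floor(min(p1[1], p2[1]) - h)):min(S, ceiling(max(p1[1], p2[1]) + h))
  ys <- max(1, floor(min(p1[2], p2[2]) - h)):min(S, ceiling(max(p1[2], p2[2]) + h))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  d <- p2 - p1
  len2 <- sum(d^2)
  if (len2 == 0) {
    dist2 <- (X - p1[1])^2 + (Y - p1[2])^2
  } else {
    t <- ((X - p1[1]) * d[1] + (Y - p1[2]) * d[2]) / len2
    t <- pmin(1, pmax(0, t))
    dist2 <- (X - (p1[1] + t * d[1]))^2 + (Y - (p1[2] + t * d[2]))^2
  }
  m <- dist2 <= (width / 2)^2
  sub <- img[ys, xs, drop = FALSE]
  sub[m] <- val
  img[ys, xs] <- sub
  img
}

#' Render a schematic mouse face
#'
#' Deterministically rasterizes the phenotype on a square grayscale canvas
#' and returns the image together with the ground-truth keypoints. Grayscale
#' values are in [0, 1]; the construction is purely geometric, so two calls
#' with the same phenotype yield pixel-identical images.
#'
#' @inheritParams face_keypoints
#' @return list with elements `image` (canvas x canvas matrix, rows = y) and
#'   `keypoints` (the [face_keypoints()] table).
#' @export
render_face <- function(phenotype, canvas = 256) {
  kp <- face_keypoints(phenotype, canvas)  # errors if off-canvas
  u <- canvas / 256
  L <- .layout
  g <- function(nm) unlist(kp[kp$name == nm, c("x", "y")], use.names = FALSE)

  img <- matrix(0.08, canvas, canvas)
  img <- fill_ellipse(img, L$head_c * u, L$head_ab[1] * u, L$head_ab[2] * u,
                      0.5)
  img <- fill_polygon(img, rbind(L$snout_poly[1, ] * u, L$snout_poly[2, ] * u,
                                 g("nose_tip")), 0.5)
  img <- fill_polygon(img, rbind(g("ear_base"), g("ear_mid_outer"),
                                 g("pinna_posterior"), g("ear_mid_inner")),
                      0.32)
  eye_c <- (g("eyelid_inner") + g("eyelid_outer")) / 2
  img <- fill_ellipse(img, eye_c, L$eye_halfwidth * u,
                      max(phenotype$eye_opening * u / 2, 1), 0.85)
  img <- fill_ellipse(img, eye_c, phenotype$pupil_diameter * u / 2,
                      phenotype$pupil_diameter * u / 2, 0.08)
  img <- draw_segment(img, g("nose_tip"), g("nose_bridge"), 0.25, 2 * u)
  for (i in 1:3) {
    nc <- g(paste0("nostril_", i))
    img <- fill_ellipse(img, nc, 1.5 * u, 1.5 * u, 0.2)
  }
  img <- draw_segment(img, g("lower_lip"), g("mouth_center"), 0.15, 2 * u)
  img <- draw_segment(img, g("mouth_center"), g("mouth_corner"), 0.15, 2 * u)
  for (w in 1:3) {
    img <- draw_segment(img, g(sprintf("whisker%d_p1", w)),
                        g(sprintf("whisker%d_p4", w)), 0.9, 1.4 * u)
  }
  list(image = img, keypoints = kp)
}

#' Region layout of the 37-keypoint schema
#'
#' @return named integer vector of per-region keypoint counts.
#' @export
keypoint_regions <- function() {
  c(pupil = 8L, eye = 4L, ear = 5L, nose = 5L, mouth = 3L, whisker = 12L)
}
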