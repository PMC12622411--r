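#' Facial phenotype of a schematic mouse face
#'
#' The ten measured facial quantities that parameterize the schematic
#' side-view face: four ear parameters, mouth inclination, snout-mouth
#' length, nose extension, whisker angle, pupil diameter and eye opening.
#' Lengths are in pixels of the 256-px reference canvas (scaled linearly when
#' rendering on other canvas sizes); angles are degrees in the y-up frame.
#'
#' @param ear_angle direction of the pinna vector against the +x axis (deg).
#' @param ear_length ear-base to posterior-pinna distance (px).
#' @param ear_width distance between the two mid-ear points (px).
#' @param ear_fold interior angle at the posterior pinna edge between the ear
#'   base and the outer mid-ear point (deg); smaller = more folded.
#' @param mouth_inclination interior angle at the inner eye corner between
#'   the nostril centre and the anterior lower lip (deg).
#' @param snout_mouth_length nose-tip to lower-lip distance (px).
#' @param nose_extension nose-tip to nose-bridge distance (px).
#' @param whisker_angle whisker direction against the -x axis (deg);
#'   smaller = more forward-pointing.
#' @param pupil_diameter vertical pupil extent (px).
#' @param eye_opening upper-to-lower eyelid distance (px).
#' @return an object of class `face_phenotype` (named list).
#' @export
face_phenotype <- function(ear_angle = 60, ear_length = 55, ear_width = 30,
                           ear_fold = 35, mouth_inclination = 17,
                           snout_mouth_length = 35, nose_extension = 22,
                           whisker_angle = 25, pupil_diameter = 8,
                           eye_opening = 14) {
  p <- list(ear_angle = ear_angle, ear_length = ear_length,
            ear_width = ear_width, ear_fold = ear_fold,
            mouth_inclination = mouth_inclination,
            snout_mouth_length = snout_mouth_length,
            nose_extension = nose_extension, whisker_angle = whisker_angle,
            pupil_diameter = pupil_diameter, eye_opening = eye_opening)
  validate_phenotype(p)
  structure(p, class = "face_phenotype")
}

#' @export
print.face_phenotype <- function(x, ...) {
  cat("<face_phenotype>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %.3f\n", nm, x[[nm]]))
  invisible(x)
}

phenotype_fields <- function() {
  c("ear_angle", "ear_length", "ear_width", "ear_fold", "mouth_inclination",
    "snout_mouth_length", "nose_extension", "whisker_angle",
    "pupil_diameter", "eye_opening")
}

validate_phenotype <- function(p) {
  lens <- c("ear_length", "ear_width", "snout_mouth_length",
            "nose_extension", "pupil_diameter", "eye_opening")
  angs <- c("ear_angle", "ear_fold", "mouth_inclination", "whisker_angle")
  for (f in lens) stopifnot_scalar_num(p[[f]], f, min = 1e-9)
  for (f in angs) stopifnot_scalar_num(p[[f]], f, min = 0, max = 180)
  invisible(p)
}

#' Perturb a phenotype by additive offsets
#'
#' Adds named offsets to phenotype fields and clips the result into the
#' valid range (lengths > 0.5 px, angles in [0, 180] deg) so that transient
#' noise excursions never produce an invalid face.
#'
#' @param p a [face_phenotype()].
#' @param offsets named numeric vector of additive offsets (any subset of
#'   the phenotype fields).
#' @return a `face_phenotype`.
#' @export
perturb_phenotype <- function(p, offsets) {
  q <- unclass(p)
  for (nm in names(offsets)) {
    if (!nm %in% phenotype_fields()) stop("unknown phenotype field: ", nm)
    q[[nm]] <- q[[nm]] + offsets[[nm]]
  }
  angs <- c("ear_angle", "ear_fold", "mouth_inclination", "whisker_angle")
  for (f in phenotype_fields()) {
    q[[f]] <- if (f %in% angs) min(179, max(1, q[[f]])) else max(0.5, q[[f]])
  }
  structure(q, class = "face_phenotype")
}

#' Valence-dependent effect specification for the synthetic generator
#'
#' Per-stimulus additive offsets to the phenotype fields, together with the
#' per-mouse identity-offset scale, the per-frame feature noise, and the
#' latency/decay time constants of each feature's response. The default
#' offsets encode the qualitative pattern reported for real mice: sucrose
#' and NaCl share offset signs, bitterness and shock share the opposite
#' signs, ear angle moves in opposite directions for the two valences, and
#' the pupil dilates for every non-neutral stimulus.
#'
#' @param offsets named list of per-stimulus named offset vectors for the
#'   five stimulus labels `sucrose`, `nacl`, `bitter`, `shock`, `water`.
#' @param identity_sd standard deviation of the per-mouse identity offsets
#'   (same units as the fields), applied to every field.
#' @param noise_sd standard deviation of the per-frame white feature noise.
#' @param latency named numeric vector of response latencies (s) per field.
#' @param decay exponential return time constant (s).
#' @param rise rise time constant after latency (s).
#' @param effect_scale multiplier applied to every stimulus offset (1 =
#'   default effect size).
#' @param validate enforce the valence sign structure (shared signs within
#'   valence, opposing ear angle, positive pupil offsets). Disable only for
#'   deliberately non-physiological control constructions, e.g. restricting
#'   the class signal to a single region.
#' @return an object of class `valence_effects`.
#' @export
valence_effects <- function(offsets = NULL, identity_sd = 1.5,
                            noise_sd = 0.4, latency = NULL, decay = 2,
                            rise = 0.1, effect_scale = 1, validate = TRUE) {
  if (is.null(offsets)) {
    offsets <- list(
      sucrose = c(ear_angle = 20, ear_length = 7, ear_width = 3,
                  ear_fold = 8, mouth_inclination = 6,
                  snout_mouth_length = 5, nose_extension = 3,
                  whisker_angle = -14, pupil_diameter = 4, eye_opening = -2),
      nacl    = c(ear_angle = 14, ear_length = 5, ear_width = 2,
                  ear_fold = 6, mouth_inclination = 4,
                  snout_mouth_length = 4, nose_extension = 2,
                  whisker_angle = -10, pupil_diameter = 3, eye_opening = -1.5),
      bitter  = c(ear_angle = -16, ear_length = -5, ear_width = -2,
                  ear_fold = -6, mouth_inclination = -4,
                  snout_mouth_length = -4, nose_extension = -2,
                  whisker_angle = 11, pupil_diameter = 3, eye_opening = -3),
      shock   = c(ear_angle = -22, ear_length = -7, ear_width = -3,
                  ear_fold = -8, mouth_inclination = -5,
                  snout_mouth_length = -5, nose_extension = -3,
                  whisker_angle = 14, pupil_diameter = 4, eye_opening = -4),
      water   = c(ear_angle = 0, ear_length = 0, ear_width = 0, ear_fold = 0,
                  mouth_inclination = 0, snout_mouth_length = 0,
                  nose_extension = 0, whisker_angle = 0, pupil_diameter = 0,
                  eye_opening = 0))
  }
  stopifnot(setequal(names(offsets), stimulus_labels()))
  offsets <- lapply(offsets, function(o) o * effect_scale)
  if (is.null(latency)) {
    latency <- c(ear_angle = 0.3, ear_length = 0.3, ear_width = 0.3,
                 ear_fold = 0.3, mouth_inclination = 0.3,
                 snout_mouth_length = 0.3, nose_extension = 0.3,
                 whisker_angle = 0.1, pupil_diameter = 1.0, eye_opening = 1.0)
  }
  eff <- structure(list(offsets = offsets, identity_sd = identity_sd,
                        noise_sd = noise_sd, latency = latency,
                        decay = decay, rise = rise),
                   class = "valence_effects")
  if (validate) validate_effects(eff)
  eff
}

validate_effects <- function(eff) {
  o <- eff$offsets
  same_sign <- function(a, b) all(sign(a) == sign(b) | a == 0 | b == 0)
  if (!same_sign(o$sucrose, o$nacl)) {
    stop("sucrose and NaCl offsets must share signs")
  }
  if (!same_sign(o$bitter, o$shock)) {
    stop("bitterness and shock offsets must share signs")
  }
  ea <- c(o$sucrose["ear_angle"], o$shock["ear_angle"])
  if (prod(ea) >= 0 && any(ea != 0)) {
    stop("ear_angle offsets must have opposite signs between valences")
  }
  for (s in c("sucrose", "nacl", "bitter", "shock")) {
    if (o[[s]]["pupil_diameter"] <= 0) {
      stop("pupil_diameter offset must be > 0 for all non-neutral stimuli")
    }
  }
  invisible(eff)
}

#' Stimulus labels and their valences
#'
#' @return `stimulus_labels()` returns the five-label stimulus set;
#'   `stimulus_valence()` returns a named vector mapping each label to
#'   `"positive"`, `"negative"` or `"neutral"`.
#' @export
stimulus_labels <- function() c("sucrose", "nacl", "bitter", "shock", "water")

#' @rdname stimulus_labels
#' @export
stimulus_valence <- function() {
  c(sucrose = "positive", nacl = "positive", bitter = "negative",
    shock = "negative", water = "neutral")
}

#' Synthetic cohort specification
#'
#' @param n_mice number of mice.
#' @param trials_per_stimulus trials per stimulus label and mouse.
#' @param fps video frame rate (Hz).
#' @param frame_size canvas side (px), >= 128.
#' @param stimulus_duration stimulus-on duration (s).
#' @param pre_s,post_s pre- and post-stimulus window (s).
#' @param seed integer master seed; a fixed seed reproduces the cohort
#'   byte-identically.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mice = 3, trials_per_stimulus = 2, fps = 30,
                        frame_size = 256, stimulus_duration = 2,
                        pre_s = 4, post_s = 4, seed = 0) {
  stopifnot_scalar_num(n_mice, "n_mice", min = 1)
  stopifnot_scalar_num(fps, "fps", min = 1e-9)
  stopifnot_scalar_num(frame_size, "frame_size", min = 128)
  stopifnot_scalar_num(trials_per_stimulus, "trials_per_stimulus", min = 1)
  structure(list(n_mice = as.integer(n_mice),
                 trials_per_stimulus = as.integer(trials_per_stimulus),
                 fps = fps, frame_size = as.integer(frame_size),
                 stimulus_duration = stimulus_duration,
                 pre_s = pre_s, post_s = post_s, seed = as.integer(seed)),
            class = "cohort_spec")
}
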