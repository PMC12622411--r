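# Valence-specific expression prototypes and similarity scoring.

#' Build positive and negative expression prototypes
#'
#' Element-wise mean of the subprototype HOG vectors of each valence
#' (positive: sucrose and NaCl; negative: bitterness and shock). The
#' prototype-source mouse should be excluded from every downstream
#' analysis.
#'
#' @param subprototypes named list mapping stimulus labels to matrices of
#'   subprototype HOG row vectors.
#' @param valence_map named character vector mapping stimulus labels to
#'   `"positive"` / `"negative"`; defaults to [stimulus_valence()].
#' @param source_mouse optional mouse id recorded for provenance.
#' @return object of class `valence_prototype` with `positive`, `negative`
#'   vectors, `n_frames` per stimulus and `source_mouse`.
#' @export
build_prototype <- function(subprototypes,
                            valence_map = stimulus_valence(),
                            source_mouse = NA_character_) {
  val <- valence_map[names(subprototypes)]
  pool <- function(v) {
    use <- names(subprototypes)[val == v & !is.na(val)]
    if (length(use) == 0) stop("no stimuli with valence '", v, "'")
    m <- do.call(rbind, subprototypes[use])
    colMeans(m)
  }
  pos <- pool("positive")
  neg <- pool("negative")
  if (sum(pos^2) == 0 || sum(neg^2) == 0) {
    stop("prototype vectors must be nonzero")
  }
  structure(list(positive = pos, negative = neg,
                 n_frames = vapply(subprototypes, nrow, integer(1)),
                 source_mouse = source_mouse),
            class = "valence_prototype")
}

#' @export
print.valence_prototype <- function(x, ...) {
  cat(sprintf("<valence_prototype> %d features, source mouse %s\n",
              length(x$positive), x$source_mouse))
  invisible(x)
}

#' Score a frame stream against a valence prototype
#'
#' Per-frame cosine similarities to the positive and negative prototype
#' vectors, and their difference (`diff > 0`: the frame resembles the
#' positive prototype more).
#'
#' @param frame_hogs numeric matrix, frames x features (frames aligned to
#'   the prototype template).
#' @param proto a [build_prototype()] result.
#' @param time_s optional per-frame timestamps (s).
#' @return object of class `similarity_timecourse`: data.frame with
#'   `time_s`, `sim_pos`, `sim_neg`, `diff`.
#' @export
score_stream <- function(frame_hogs, proto, time_s = NULL) {
  if (ncol(frame_hogs) != length(proto$positive)) {
    stop("frame descriptor length does not match the prototype")
  }
  sp <- as.numeric(cosine_matrix(frame_hogs, matrix(proto$positive, 1)))
  sn <- as.numeric(cosine_matrix(frame_hogs, matrix(proto$negative, 1)))
  out <- data.frame(time_s = time_s %||% (seq_len(nrow(frame_hogs)) - 1),
                    sim_pos = sp, sim_neg = sn, diff = sp - sn)
  class(out) <- c("similarity_timecourse", "data.frame")
  out
}

#' Cumulative prototype similarity over a window
#'
#' @param tc a `similarity_timecourse`.
#' @param window numeric length-2 time window `[t0, t1)`; frames with
#'   `t0 <= time_s < t1` are summed. A zero-length window gives `(0, 0)`.
#' @return named numeric vector `c(cum_pos, cum_neg)`.
#' @export
cumulative_similarity <- function(tc, window) {
  sel <- tc$time_s >= window[1] & tc$time_s < window[2]
  c(cum_pos = sum(tc$sim_pos[sel]), cum_neg = sum(tc$sim_neg[sel]))
}

#' Valence summary of a drug session
#'
#' Per-epoch normalized similarity difference (epoch mean of `diff` minus
#' the baseline mean, divided by the baseline standard deviation of
#' `diff`), plus the proportions of frames classified positive
#' (`diff > 0`) and negative (`diff < 0`) and their ratio. Frames with
#' `diff` exactly zero are excluded from the proportions.
#'
#' @param tc a `similarity_timecourse` covering the session.
#' @param baseline_window numeric length-2 pre-injection window (s).
#' @param epochs named list of numeric length-2 epoch windows (s), e.g.
#'   `list(early = c(0, 900), late = c(900, 1800))`.
#' @return object of class `valence_summary`: data.frame with one row per
#'   epoch and columns `epoch`, `normalized_diff`, `proportion_positive`,
#'   `proportion_negative`, `pos_neg_ratio`, `n_classified`; attribute
#'   `flag` is `"zero_baseline_sd"` when normalization fell back to the
#'   unscaled difference.
#' @export
drug_valence_index <- function(tc, baseline_window, epochs) {
  if (baseline_window[2] > min(vapply(epochs, `[`, numeric(1), 1))) {
    stop("baseline window must precede the epochs")
  }
  bsel <- tc$time_s >= baseline_window[1] & tc$time_s < baseline_window[2]
  if (!any(bsel)) stop("empty baseline window")
  bmu <- mean(tc$diff[bsel])
  bsd <- sd(tc$diff[bsel])
  flag <- NA_character_
  if (!is.finite(bsd) || bsd == 0) {
    bsd <- 1
    flag <- "zero_baseline_sd"
  }
  rows <- lapply(names(epochs), function(nm) {
    w <- epochs[[nm]]
    sel <- tc$time_s >= w[1] & tc$time_s < w[2]
    d <- tc$diff[sel]
    npos <- sum(d > 0); nneg <- sum(d < 0)
    ncl <- npos + nneg
    data.frame(epoch = nm,
               normalized_diff = (mean(d) - bmu) / bsd,
               proportion_positive = if (ncl > 0) npos / ncl else NA_real_,
               proportion_negative = if (ncl > 0) nneg / ncl else NA_real_,
               pos_neg_ratio = if (nneg > 0) npos / nneg else NA_real_,
               n_classified = ncl)
  })
  out <- do.call(rbind, rows)
  attr(out, "flag") <- flag
  class(out) <- c("valence_summary", "data.frame")
  out
}

#' Build a valence prototype from a cohort's designated prototype mouse
#'
#' Convenience wrapper: renders stimulus-window and neutral frames of the
#' prototype mouse, selects `k` subprototype frames per non-neutral
#' stimulus against the neutral baseline, and averages them per valence.
#'
#' @param cohort a `synthetic_cohort`.
#' @param k subprototype frames per stimulus.
#' @param canvas render side for HOG extraction.
#' @param config optional [hog_config()].
#' @return a `valence_prototype`.
#' @export
cohort_prototype <- function(cohort, k = 10, canvas = 128, config = NULL) {
  config <- config %||% hog_config(canvas)
  mouse <- cohort$mice[[cohort$prototype_mouse]]
  stims <- setdiff(stimulus_labels(), "water")
  rcanvas <- max(canvas, 128)
  hogs_of <- function(tr, frames) {
    fr <- render_trial(tr, frames, rcanvas)
    if (rcanvas != canvas) fr <- lapply(fr, resize_image, side = canvas)
    hog_matrix(fr, config)
  }
  neutral <- do.call(rbind, lapply(mouse$trials, function(tr) {
    hogs_of(tr, trial_window_frames(tr, c(-2, 0)))
  }))
  subs <- list()
  for (s in stims) {
    trs <- Filter(function(tr) tr$stimulus == s, mouse$trials)
    H <- do.call(rbind, lapply(trs, function(tr) {
      hogs_of(tr, trial_window_frames(tr, c(0, cohort$spec$stimulus_duration)))
    }))
    idx <- select_subprototypes(H, neutral, k = min(k, nrow(H)),
                                shortlist_k = min(10, nrow(H)))
    subs[[s]] <- H[idx, , drop = FALSE]
  }
  build_prototype(subs, source_mouse = cohort$prototype_mouse)
}
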