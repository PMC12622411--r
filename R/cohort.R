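# Synthetic cohort assembly and on-disk export.

#' Build a synthetic cohort of sessions
#'
#' Draws one identity offset vector per mouse (applied to all of that
#' mouse's trials), simulates `trials_per_stimulus` trials for each of the
#' five stimulus labels per mouse, and optionally simulates a photometry
#' recording per mouse. All randomness derives deterministically from
#' `spec$seed`, so rebuilding with the same spec is bit-identical.
#'
#' @param spec a [cohort_spec()].
#' @param effects a [valence_effects()].
#' @param photometry `NULL`, or a neuron type (`"DA"`, `"GABA"`, `"Glu"`,
#'   `"pan"`) to attach one recording per mouse.
#' @param out_dir optional directory; when given the cohort is written to
#'   disk via [write_cohort()].
#' @param track forward to [simulate_trial()]; `FALSE` skips keypoints.
#' @param ... forwarded to [write_cohort()].
#' @return object of class `synthetic_cohort`: `spec`, `effects`, `mice`
#'   (list with `base` phenotype and `trials`), `events` (cohort event
#'   table), `prototype_mouse`, and optional `photometry`.
#' @export
build_cohort <- function(spec, effects = valence_effects(),
                         photometry = NULL, out_dir = NULL, track = TRUE,
                         ...) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- stimulus_labels()
  trial_len <- spec$pre_s + spec$stimulus_duration + spec$post_s
  mice <- list()
  events <- list()
  for (m in seq_len(spec$n_mice)) {
    mid <- sprintf("m%02d", m)
    idoff <- with_seed(derive_seed(spec$seed, paste0("identity_", mid)),
                       rnorm(length(phenotype_fields()),
                             sd = effects$identity_sd))
    names(idoff) <- phenotype_fields()
    base <- perturb_phenotype(face_phenotype(), idoff)
    order_seed <- derive_seed(spec$seed, paste0("order_", mid))
    stims <- rep(labels, each = spec$trials_per_stimulus)
    stims <- with_seed(order_seed, sample(stims))
    trials <- list()
    for (k in seq_along(stims)) {
      tid <- sprintf("%s_t%03d", mid, k)
      tr <- simulate_trial(base, effects, stims[k], spec,
                           seed = derive_seed(spec$seed, tid),
                           track = track)
      tr$trial_id <- tid
      tr$mouse_id <- mid
      tr$session_onset_s <- (k - 1) * trial_len + spec$pre_s
      trials[[tid]] <- tr
      events[[tid]] <- data.frame(trial_id = tid, mouse_id = mid,
                                  stimulus = stims[k],
                                  valence = stimulus_valence()[[stims[k]]],
                                  onset_s = tr$session_onset_s,
                                  duration_s = spec$stimulus_duration)
    }
    mice[[mid]] <- list(mouse_id = mid, base = base, identity = idoff,
                        trials = trials)
  }
  events <- do.call(rbind, events)
  rownames(events) <- NULL

  pm <- NULL
  if (!is.null(photometry)) {
    pm <- lapply(mice, function(mo) {
      ev <- events[events$mouse_id == mo$mouse_id, ]
      simulate_photometry(photometry, ev,
                          duration_s = max(ev$onset_s) + trial_len,
                          seed = derive_seed(spec$seed,
                                             paste0("pm_", mo$mouse_id)))
    })
  }

  cohort <- structure(list(spec = spec, effects = effects, mice = mice,
                           events = events, prototype_mouse = "m01",
                           photometry = pm),
                      class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir, ...)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d mice, %d trials (%d per stimulus), %g fps\n",
              x$spec$n_mice, nrow(x$events), x$spec$trials_per_stimulus,
              x$spec$fps))
  invisible(x)
}

#' All trials of a cohort as a flat list
#' @param cohort a `synthetic_cohort`.
#' @return named list of trial fixtures.
#' @export
cohort_trials <- function(cohort) {
  do.call(c, unname(lapply(cohort$mice, function(m) m$trials)))
}

#' Write a cohort to disk
#'
#' Layout: `manifest.yaml` (spec, seed, file checksums), `events.csv`,
#' one pose-estimation-style keypoint CSV per trial under `keypoints/`
#' (three header rows: scorer / bodypart / x,y,likelihood), optional PNG
#' frames under `frames/<trial_id>/`, and one `time_s,f470,f410` CSV per
#' photometry recording under `photometry/`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param write_frames `"none"`, `"apex"` (one mid-stimulus frame per
#'   trial) or `"all"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_frames = c("none", "apex", "all")) {
  write_frames <- match.arg(write_frames)
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- character(0)

  evp <- file.path(dir, "events.csv")
  write.csv(cohort$events, evp, row.names = FALSE)
  files <- c(files, evp)

  dir.create(file.path(dir, "keypoints"), showWarnings = FALSE)
  for (tr in cohort_trials(cohort)) {
    if (is.null(tr$track)) next
    kpp <- file.path(dir, "keypoints", paste0(tr$trial_id, ".csv"))
    write_dlc_csv(tr$track, kpp)
    files <- c(files, kpp)
  }

  if (write_frames != "none") {
    for (tr in cohort_trials(cohort)) {
      fd <- file.path(dir, "frames", tr$trial_id)
      dir.create(fd, recursive = TRUE, showWarnings = FALSE)
      idx <- if (write_frames == "apex") {
        round((tr$onset_s + cohort$spec$stimulus_duration / 2) *
                cohort$spec$fps)
      } else seq_along(tr$time)
      imgs <- render_trial(tr, idx)
      for (i in seq_along(idx)) {
        fp <- file.path(fd, sprintf("f%04d.png", idx[i]))
        png::writePNG(imgs[[i]], fp)
        files <- c(files, fp)
      }
    }
  }

  if (!is.null(cohort$photometry)) {
    dir.create(file.path(dir, "photometry"), showWarnings = FALSE)
    for (mid in names(cohort$photometry)) {
      rec <- cohort$photometry[[mid]]
      pp <- file.path(dir, "photometry", paste0(mid, ".csv"))
      write.csv(data.frame(time_s = rec$time, f470 = rec$f470,
                           f410 = rec$f410), pp, row.names = FALSE)
      files <- c(files, pp)
    }
  }

  manifest <- list(
    generator = "facevalence synthetic cohort",
    spec = unclass(cohort$spec),
    seed = cohort$spec$seed,
    prototype_mouse = cohort$prototype_mouse,
    n_trials = nrow(cohort$events),
    checksums = as.list(tools::md5sum(sort(files))))
  names(manifest$checksums) <-
    sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", dir), "/?"),
        "", sort(files))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
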