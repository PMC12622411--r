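# Configuration-driven orchestration of the full synthetic pipeline.

pipeline_stages <- function() {
  c("synth", "register", "hog", "prototype", "kinematics", "decoders",
    "photometry", "report")
}

default_config <- function() {
  list(
    seed = 0L,
    out_dir = "facevalence_run",
    log_level = "info",
    synth = list(n_mice = 3L, trials_per_stimulus = 2L, fps = 30,
                 frame_size = 128L, stimulus_duration = 2, pre_s = 4,
                 post_s = 4, neuron_type = "DA", effect_scale = 1),
    hog = list(canvas = 64L),
    prototype = list(k_frames = 5L),
    kinematics = list(conf_threshold = 0.9, median_window = 5L),
    decoders = list(epochs = 4L, batch_size = 32L, input_side = 32L,
                    channels = 6L, frames_per_trial = 10L),
    photometry = list(lambda = 1e8, psth_post_s = 6)
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, and range-checks values. All
#' problems are collected and reported together, not just the first.
#'
#' @param raw a YAML string, a path to a YAML file, or a named list; an
#'   empty input yields the defaults-only configuration.
#' @return list with `config` (merged configuration) and `errors`
#'   (character vector; empty when valid).
#' @export
validate_config <- function(raw = NULL) {
  user <- NULL
  if (is.null(raw) || (is.character(raw) && !nzchar(trimws(raw[1])))) {
    user <- list()
  } else if (is.list(raw)) {
    user <- raw
  } else if (is.character(raw)) {
    user <- if (file.exists(raw)) yaml::read_yaml(raw) else
      yaml::yaml.load(raw)
    user <- user %||% list()
  } else {
    return(list(config = default_config(),
                errors = "configuration must be YAML text, a path or a list"))
  }
  def <- default_config()
  errors <- character(0)
  merged <- def
  for (key in names(user)) {
    if (!key %in% names(def)) {
      errors <- c(errors, paste0("unknown configuration key: ", key))
      next
    }
    if (is.list(def[[key]])) {
      for (sub in names(user[[key]])) {
        if (!sub %in% names(def[[key]])) {
          errors <- c(errors,
                      paste0("unknown configuration key: ", key, "$", sub))
        } else {
          merged[[key]][[sub]] <- user[[key]][[sub]]
        }
      }
    } else {
      merged[[key]] <- user[[key]]
    }
  }
  pos <- list(c("synth", "fps"), c("synth", "n_mice"),
              c("synth", "trials_per_stimulus"), c("synth", "frame_size"),
              c("hog", "canvas"), c("decoders", "epochs"),
              c("photometry", "lambda"))
  for (p in pos) {
    v <- merged[[p[1]]][[p[2]]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      errors <- c(errors,
                  paste0(p[1], "$", p[2], " must be a positive number"))
    }
  }
  if (!merged$synth$neuron_type %in% c("DA", "GABA", "Glu", "pan")) {
    errors <- c(errors, "synth$neuron_type must be DA, GABA, Glu or pan")
  }
  list(config = merged, errors = errors)
}

plog <- function(cfg, level, ...) {
  lv <- c(debug = 0, info = 1, warn = 2, quiet = 3)
  if (lv[[cfg$log_level %||% "info"]] <= lv[[level]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
}

write_provenance <- function(out_dir, stage, params, seed, outputs) {
  pd <- file.path(out_dir, "provenance")
  dir.create(pd, recursive = TRUE, showWarnings = FALSE)
  rec <- list(stage = stage, params = params, seed = seed,
              outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])),
              package_version = as.character(utils::packageVersion("facevalence")))
  jsonlite::write_json(rec, file.path(pd, paste0(stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the stages in dependency order (`synth`, `register`, `hog`,
#' `prototype`, `kinematics`, `decoders`, `photometry`, `report`), writing
#' per-stage outputs and provenance records (parameters, derived seed,
#' output checksums) under the configured output directory. Stage results
#' are cached in `.rds` files so a stage subset can be rerun against
#' cached upstream artifacts.
#'
#' @param config a configuration (see [validate_config()]); a list, YAML
#'   string/path, or `NULL` for defaults.
#' @param stages subset of stages to run (default: all, in order).
#' @return run report (named list per completed stage), invisibly the
#'   full state.
#' @export
run_pipeline <- function(config = NULL, stages = pipeline_stages()) {
  vc <- validate_config(config)
  if (length(vc$errors) > 0) {
    stop("invalid configuration:\n  ", paste(vc$errors, collapse = "\n  "))
  }
  cfg <- vc$config
  out <- cfg$out_dir
  dir.create(file.path(out, "state"), recursive = TRUE,
             showWarnings = FALSE)
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  stages <- pipeline_stages()[pipeline_stages() %in% stages]

  state_path <- function(nm) file.path(out, "state", paste0(nm, ".rds"))
  load_state <- function(nm, needed_by) {
    p <- state_path(nm)
    if (!file.exists(p)) {
      stop("stage '", needed_by, "' needs the output of stage '", nm,
           "'; run that stage first")
    }
    readRDS(p)
  }
  save_state <- function(nm, val) saveRDS(val, state_path(nm))
  report <- list()

  if ("synth" %in% stages) {
    plog(cfg, "info", "stage synth")
    sp <- cfg$synth
    spec <- cohort_spec(sp$n_mice, sp$trials_per_stimulus, sp$fps,
                        sp$frame_size, sp$stimulus_duration, sp$pre_s,
                        sp$post_s, seed = derive_seed(cfg$seed, "synth"))
    cohort <- build_cohort(spec,
                           valence_effects(effect_scale = sp$effect_scale),
                           photometry = sp$neuron_type)
    cdir <- file.path(out, "cohort")
    write_cohort(cohort, cdir)
    save_state("synth", cohort)
    write_provenance(out, "synth", sp, spec$seed,
                     file.path(cdir, c("manifest.yaml", "events.csv")))
    report$synth <- list(n_trials = nrow(cohort$events))
  }

  if ("register" %in% stages) {
    plog(cfg, "info", "stage register")
    cohort <- load_state("synth", "register")
    proto_kp <- face_keypoints(cohort$mice[[cohort$prototype_mouse]]$base,
                               cohort$spec$frame_size)
    tpl <- landmarks_from_keypoints(proto_kp)
    transforms <- lapply(cohort$mice, function(mo) {
      lm <- landmarks_from_keypoints(
        face_keypoints(mo$base, cohort$spec$frame_size))
      fit <- fit_affine(lm, tpl)
      ref <- refine_similarity(lm, tpl, fit$transform)
      list(mouse = mo$mouse_id, affine = unclass(fit$transform),
           similarity = unclass(ref$transform), rmse = fit$rmse)
    })
    save_state("register", transforms)
    tf_path <- file.path(out, "transforms.yaml")
    yaml::write_yaml(lapply(transforms, function(t) {
      list(mouse = t$mouse, affine = as.list(as.data.frame(t$affine)),
           rmse = t$rmse)
    }), tf_path)
    write_provenance(out, "register", list(), cfg$seed, tf_path)
    report$register <- list(n_transforms = length(transforms))
  }

  if ("hog" %in% stages) {
    plog(cfg, "info", "stage hog")
    cohort <- load_state("synth", "hog")
    canvas <- cfg$hog$canvas
    config_h <- hog_config(canvas)
    rcanvas <- max(canvas, 128)
    hogs <- lapply(cohort_trials(cohort), function(tr) {
      idx <- trial_window_frames(tr, c(-2, cohort$spec$stimulus_duration))
      fr <- render_trial(tr, idx, rcanvas)
      if (rcanvas != canvas) fr <- lapply(fr, resize_image, side = canvas)
      hog_matrix(fr, config_h)
    })
    save_state("hog", list(hogs = hogs, canvas = canvas))
    write_provenance(out, "hog", cfg$hog, cfg$seed, character(0))
    report$hog <- list(n_trials = length(hogs),
                       n_features = ncol(hogs[[1]]))
  }

  if ("prototype" %in% stages) {
    plog(cfg, "info", "stage prototype")
    cohort <- load_state("synth", "prototype")
    proto <- cohort_prototype(cohort, k = cfg$prototype$k_frames,
                              canvas = cfg$hog$canvas)
    hs <- load_state("hog", "prototype")
    eval_trials <- Filter(function(tr) tr$mouse_id != cohort$prototype_mouse,
                          cohort_trials(cohort))
    diffs <- vapply(eval_trials, function(tr) {
      tc <- score_stream(hs$hogs[[tr$trial_id]], proto)
      mean(tail(tc$diff, 2 * cohort$spec$fps))
    }, numeric(1))
    val <- vapply(eval_trials, function(tr) tr$valence, character(1))
    sm <- tapply(diffs, val, mean)
    save_state("prototype", proto)
    write_provenance(out, "prototype", cfg$prototype, cfg$seed,
                     character(0))
    report$prototype <- list(mean_diff_by_valence = as.list(sm))
  }

  if ("kinematics" %in% stages) {
    plog(cfg, "info", "stage kinematics")
    cohort <- load_state("synth", "kinematics")
    kin <- cohort_kinematics(cohort,
                             conf_threshold = cfg$kinematics$conf_threshold,
                             median_window = cfg$kinematics$median_window)
    kpath <- file.path(out, "kinematics.csv")
    write.csv(kin$peaks, kpath, row.names = FALSE)
    save_state("kinematics", kin)
    write_provenance(out, "kinematics", cfg$kinematics, cfg$seed, kpath)
    report$kinematics <- list(
      ear_angle_sign = as.list(kin$sign_by_stimulus[["ear_angle"]]))
  }

  if ("decoders" %in% stages) {
    plog(cfg, "info", "stage decoders")
    cohort <- load_state("synth", "decoders")
    dc <- cfg$decoders
    ds <- cohort_frame_dataset(cohort, side = dc$input_side,
                               frames_per_trial = dc$frames_per_trial)
    fit <- train_frame_classifier(ds,
                                  classifier_config(epochs = dc$epochs,
                                                    batch_size = dc$batch_size,
                                                    input_side = dc$input_side,
                                                    channels = dc$channels,
                                                    seed = derive_seed(cfg$seed,
                                                                       "decoders")))
    save_state("decoders", fit)
    mpath <- file.path(out, "classifier_metrics.json")
    jsonlite::write_json(list(accuracy = fit$accuracy,
                              per_mouse = as.list(fit$per_mouse)),
                         mpath, auto_unbox = TRUE, digits = NA)
    write_provenance(out, "decoders", dc, cfg$seed, mpath)
    report$decoders <- list(accuracy = fit$accuracy)
  }

  if ("photometry" %in% stages) {
    plog(cfg, "info", "stage photometry")
    cohort <- load_state("synth", "photometry")
    if (is.null(cohort$photometry)) {
      stop("stage 'photometry' needs a cohort built with photometry")
    }
    trial_len <- cohort$spec$pre_s + cohort$spec$stimulus_duration +
      cohort$spec$post_s
    post_eff <- min(cfg$photometry$psth_post_s, trial_len - 4)
    ratios <- lapply(names(cohort$photometry), function(mid) {
      rec <- cohort$photometry[[mid]]
      ct <- process_photometry(rec, lambda = cfg$photometry$lambda)
      ps <- compute_psth(ct$dff, rec$time, rec$events, post_s = post_eff)
      wp <- ps$peaks[ps$stimulus == "water"]
      sapply(setdiff(stimulus_labels(), "water"), function(s) {
        if (!any(ps$stimulus == s)) return(NA_real_)
        peak_ratio_vs_water(ps$peaks[ps$stimulus == s], wp)
      })
    })
    names(ratios) <- names(cohort$photometry)
    save_state("photometry", ratios)
    ppath <- file.path(out, "peak_ratios.json")
    jsonlite::write_json(ratios, ppath, digits = NA)
    write_provenance(out, "photometry", cfg$photometry, cfg$seed, ppath)
    report$photometry <- list(mean_ratios =
                                as.list(colMeans(do.call(rbind, ratios),
                                                 na.rm = TRUE)))
  }

  if ("report" %in% stages) {
    plog(cfg, "info", "stage report")
    done <- character(0)
    for (st in setdiff(pipeline_stages(), "report")) {
      if (file.exists(state_path(st))) done <- c(done, st)
    }
    report$report <- list(stages_completed = c(done, "report"),
                          out_dir = out)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

#' Kinematics summary of a cohort
#'
#' QCs each trial's track, computes the geometry battery, extracts
#' baseline-relative peak changes per feature, and applies the
#' nearest-water correction within each mouse.
#'
#' @param cohort a `synthetic_cohort` with tracks.
#' @param conf_threshold,median_window forwarded to [qc_track()].
#' @return list with `peaks` (tidy data.frame: trial, mouse, stimulus,
#'   feature, peak, corrected) and `sign_by_stimulus` (per-feature named
#'   sign of the mean corrected change).
#' @export
cohort_kinematics <- function(cohort, conf_threshold = 0.9,
                              median_window = 5) {
  rows <- list()
  for (mo in cohort$mice) {
    per_trial <- lapply(mo$trials, function(tr) {
      g <- compute_geometry(qc_track(tr$track, conf_threshold,
                                     median_window))
      pk <- vapply(names(g), function(f) {
        change_from_baseline(g[[f]], tr$onset_s, cohort$spec$fps,
                             "peak",
                             window_s = c(0, cohort$spec$stimulus_duration))$peak
      }, numeric(1))
      list(stimulus = tr$stimulus, onset = tr$session_onset_s, peak = pk)
    })
    stims <- vapply(per_trial, `[[`, character(1), "stimulus")
    onsets <- vapply(per_trial, `[[`, numeric(1), "onset")
    water <- which(stims == "water")
    for (i in seq_along(per_trial)) {
      for (f in names(per_trial[[i]]$peak)) {
        corrected <- if (length(water) > 0) {
          water_correct(per_trial[[i]]$peak[[f]], onsets[i],
                        vapply(per_trial[water], function(p) p$peak[[f]],
                               numeric(1)),
                        onsets[water])
        } else NA_real_
        rows[[length(rows) + 1L]] <-
          data.frame(trial_id = names(mo$trials)[i],
                     mouse_id = mo$mouse_id, stimulus = stims[i],
                     onset_s = onsets[i], feature = f,
                     peak = per_trial[[i]]$peak[[f]],
                     corrected = corrected)
      }
    }
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  nonwater <- peaks[peaks$stimulus != "water", ]
  sign_by_stimulus <- lapply(split(nonwater, nonwater$feature),
                             function(d) {
                               sign(tapply(d$corrected, d$stimulus, mean))
                             })
  list(peaks = peaks, sign_by_stimulus = sign_by_stimulus)
}
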