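# End-to-end workflow: configuration, per-recording feature extraction and
# the cohort pipeline (simulate -> extract -> categorise -> exclude ->
# model).

#' Pipeline configuration
#'
#' All rule thresholds live here with the analysis defaults: 15-ms arousal
#' drop over 5-45 s within the 150-500 ms validity range, 17-beat PTT2
#' smoothing, 50-ms spike rule, 3-h PTT and 4-h oximetry minima, ODI gates
#' at 7 (ODI3) and 4 (ODI4) events/h.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param n_subjects cohort size for synthetic runs.
#' @param mix named category proportions (`NULL` = configured prevalences).
#' @param min_ptt_hours,min_oximetry_hours inclusion rules, h.
#' @param odi3_threshold,odi4_threshold oximetry-score gates, events/h.
#' @param spike_threshold PTT spike rule, ms.
#' @param arousal_drop PTT2 arousal drop rule, ms.
#' @param arousal_window permissible arousal descent duration, s.
#' @param ptt_valid_range valid PTT range, ms.
#' @param ptt2_points PTT2 averaging window, beats.
#' @param alpha variable-selection retention threshold.
#' @param tree_split decision-tree training proportion.
#' @param artefacts inject per-subject artefact burden.
#' @param cohort_params generator parameter list ([cohort_parameters()]
#'   defaults when `NULL`).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param verbose log per-stage progress.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, n_subjects = 40L, mix = NULL,
                       min_ptt_hours = 3, min_oximetry_hours = 4,
                       odi3_threshold = 7, odi4_threshold = 4,
                       spike_threshold = 50, arousal_drop = 15,
                       arousal_window = c(5, 45),
                       ptt_valid_range = c(150, 500), ptt2_points = 17L,
                       alpha = 0.05, tree_split = 0.7, artefacts = TRUE,
                       cohort_params = NULL, out_dir = NULL, verbose = FALSE) {
  cfg <- structure(list(
    seed = as.integer(seed), n_subjects = as.integer(n_subjects), mix = mix,
    min_ptt_hours = min_ptt_hours, min_oximetry_hours = min_oximetry_hours,
    odi3_threshold = odi3_threshold, odi4_threshold = odi4_threshold,
    spike_threshold = spike_threshold, arousal_drop = arousal_drop,
    arousal_window = arousal_window, ptt_valid_range = ptt_valid_range,
    ptt2_points = as.integer(ptt2_points), alpha = alpha,
    tree_split = tree_split, artefacts = isTRUE(artefacts),
    cohort_params = cohort_params,
    out_dir = out_dir, verbose = isTRUE(verbose)
  ), class = "run_config")
  for (f in c("min_ptt_hours", "min_oximetry_hours", "odi3_threshold",
              "odi4_threshold", "spike_threshold", "arousal_drop")) {
    check_field(cfg[[f]] > 0, f, "must be positive")
  }
  check_field(all(cfg$arousal_window > 0) && diff(cfg$arousal_window) > 0,
              "arousal_window", "must be an increasing positive pair")
  cfg
}

#' Serialise / restore a configuration
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `read_config()` returns a `run_config`; `write_config()` the
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  raw <- unclass(config)
  if (!is.null(raw$mix)) raw$mix <- as.list(raw$mix)   # keep names in YAML
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$mix)) raw$mix <- unlist(raw$mix)
  do.call(run_config, raw)
}

#' Extract the per-subject feature row from a recording
#'
#' Runs the PTT chain and the oximetry chain, assigns the diagnostic
#' category from the video-surrogate labels plus the oximetry score, and
#' assembles the model-variable row. Demographics travel with the
#' recording's subject record (generator truth in synthetic mode).
#'
#' @param recording a `sleep_recording`.
#' @param config a [run_config()].
#' @return one-row data.frame of features, inclusion flags and category.
#' @export
extract_features <- function(recording, config = run_config()) {
  ptt <- ptt_summary(recording, min_hours = config$min_ptt_hours,
                     spike_threshold = config$spike_threshold,
                     drop_threshold = config$arousal_drop,
                     window = config$arousal_window,
                     valid_range = config$ptt_valid_range)
  ox <- compute_oximetry_summary(recording$spo2,
                                 min_hours = config$min_oximetry_hours,
                                 odi3_threshold = config$odi3_threshold,
                                 odi4_threshold = config$odi4_threshold)
  n_obs <- nrow(recording$video_labels)
  n_ar <- sum(recording$video_labels$has_arousal)
  category <- tryCatch(
    assign_category(study_assessment(recording$snoring, n_obs, n_ar, ox, ptt)),
    error = function(e) NA_character_)
  rri <- diff(recording$r_peaks)
  hr <- 60 / rri
  prof <- recording$truth$profile
  gv <- function(f) if (!is.null(prof[[f]])) prof[[f]] else NA
  data.frame(
    pttrs = ptt$pttrs,
    ptt_ai = ptt$ptt_ai,
    ptt_duration = ptt$ptt_duration_hours,
    oximetry_score = ox$score,
    odi3 = ox$odi3, odi4 = ox$odi4,
    min_spo2 = ox$min_spo2, mean_spo2 = ox$mean_spo2,
    mean_nadir = ox$mean_nadir,
    study_duration = recording$duration / 3600,
    sex = factor(gv("sex"), levels = c("F", "M")),
    weight = gv("weight_kg"), height = gv("height_cm"),
    heart_rate = mean(hr), heart_rate_sd = stats::sd(hr),
    age_months = gv("age_months"),
    n_obstructive = n_obs, episodes_with_arousal = n_ar,
    snoring = recording$snoring,
    oximetry_included = isTRUE(ox$included),
    ptt_included = isTRUE(ptt$included),
    category = category,
    truth_category = if (!is.null(prof$category)) prof$category else NA_character_
  )
}

#' Run the full synthetic pipeline
#'
#' Simulates a cohort, extracts PTT and oximetry features, categorises and
#' applies the exclusion flow, then fits the statistical layer on the
#' included subjects: iterated logistic variable selection (15 variables
#' down to the two principal ones), the multinomial severity model, the
#' decision-tree cross-check and a 4-h PTT-duration sensitivity refit.
#' Artifacts (feature CSV, exclusion table, metrics JSON, ROC points) are
#' written when `config$out_dir` is set.
#'
#' @param config a [run_config()].
#' @return a `pipeline_report` list: `features`, `included`, `exclusions`,
#'   `models`, `metrics`, `sensitivity_4h`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  say <- function(...) if (config$verbose) message(sprintf(...))
  say("simulating %d subjects (seed %d)", config$n_subjects, config$seed)
  recs <- simulate_cohort(config$n_subjects, config$mix, config$seed,
                          params = config$cohort_params %||% cohort_parameters(),
                          artefacts = config$artefacts)
  say("extracting features")
  features <- do.call(rbind, lapply(recs, extract_features, config = config))
  features$subject <- seq_len(nrow(features))
  features$disorder <- disorder_flag(features$category)
  excl <- apply_exclusions(features)
  inc <- excl$included
  say("included %d / %d subjects", nrow(inc), nrow(features))
  for (r in seq_len(nrow(excl$reasons))) {
    say("excluded (%s): %d", excl$reasons$reason[r], excl$reasons$n[r])
  }

  models <- list(selection = NULL, multinomial = NULL, tree = NULL)
  sens4 <- NULL
  enough <- nrow(inc) >= 40 && length(unique(inc$disorder)) == 2L
  if (enough) {
    say("fitting logistic selection cascade")
    models$selection <- select_variables(inc, alpha = config$alpha)
    principal <- models$selection$selected$principal
    if (length(principal) == 2L) {
      say("decision-tree cross-check on {%s}", paste(principal, collapse = ", "))
      models$tree <- tryCatch(
        fit_tree(inc, principal, split = config$tree_split, seed = config$seed),
        error = function(e) { say("tree skipped: %s", conditionMessage(e)); NULL })
    }
    if (nlevels(droplevels(severity_score3(inc$category))) == 3L) {
      models$multinomial <- tryCatch(
        fit_multinomial(inc),
        error = function(e) { say("multinomial skipped: %s", conditionMessage(e)); NULL })
    }
    sub4 <- inc[inc$ptt_duration >= 4, , drop = FALSE]
    if (nrow(sub4) >= 40 && length(unique(sub4$disorder)) == 2L &&
        length(principal) >= 1L) {
      m4 <- fit_logistic(sub4, principal)
      sens4 <- list(n = nrow(sub4), model = m4,
                    metrics = model_metrics(m4, sub4))
    }
  } else {
    say("cohort too small for the statistical layer (n included = %d)", nrow(inc))
  }

  report <- structure(list(
    config = config, features = features, included = inc,
    exclusions = excl$reasons, excluded = excl$excluded,
    models = models,
    metrics = if (!is.null(models$selection)) models$selection$metrics else NULL,
    sensitivity_4h = sens4
  ), class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

metrics_as_list <- function(m) {
  if (is.null(m)) return(NULL)
  cm <- m$metrics
  list(tn = cm$tn, fp = cm$fp, fn = cm$fn, tp = cm$tp,
       accuracy = cm$accuracy, accuracy_ci = cm$accuracy_ci,
       no_information_rate = cm$no_information_rate, kappa = cm$kappa,
       mcnemar_p = cm$mcnemar_p, sensitivity = cm$sensitivity,
       specificity = cm$specificity, ppv = cm$ppv, npv = cm$npv,
       prevalence = cm$prevalence, detection_rate = cm$detection_rate,
       detection_prevalence = cm$detection_prevalence,
       balanced_accuracy = cm$balanced_accuracy, auc = m$auc)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  out <- list(seed = report$config$seed,
              n_total = nrow(report$features),
              n_included = nrow(report$included),
              models = lapply(report$metrics, metrics_as_list))
  if (!is.null(report$models$tree)) {
    tm <- report$models$tree
    out$tree <- metrics_as_list(list(metrics = tm$metrics, auc = tm$auc))
  }
  if (!is.null(report$sensitivity_4h)) {
    out$sensitivity_4h <- c(list(n = report$sensitivity_4h$n),
                            metrics_as_list(report$sensitivity_4h$metrics))
  }
  jsonlite::write_json(out, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  if (!is.null(report$models$selection$metrics$principal)) {
    p <- report$models$selection$metrics$principal$prob
    roc <- roc_auc(p, report$included$disorder)
    utils::write.csv(roc$curve, file.path(out_dir, "roc_principal.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d subjects, %d included\n",
              nrow(x$features), nrow(x$included)))
  print(x$exclusions, row.names = FALSE)
  if (!is.null(x$metrics)) {
    for (nm in names(x$metrics)) {
      m <- x$metrics[[nm]]
      if (is.null(m)) next
      cat(sprintf("  %-12s accuracy %.3f  AUC %.3f\n", nm,
                  m$metrics$accuracy, m$auc))
    }
  }
  invisible(x)
}

#' Write a cohort of recordings to EDF files plus manifest
#'
#' @param recordings list of `sleep_recording` objects.
#' @param dir output directory.
#' @return manifest data.frame, invisibly.
#' @export
write_cohort <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(recordings), function(i) {
    f <- file.path(dir, sprintf("subject_%03d.edf", i))
    write_recording(recordings[[i]], f)
    p <- recordings[[i]]$truth$profile
    data.frame(file = basename(f),
               category = if (!is.null(p$category)) p$category else NA,
               study_hours = recordings[[i]]$duration / 3600)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
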