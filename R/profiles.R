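#' Diagnostic categories used throughout the package
#'
#' Five reportable sleep-study categories plus the "abnormal other" bucket
#' used for exclusions (oximetry abnormality without video evidence of
#' obstruction).
#'
#' @export
sleep_categories <- c("normal", "primary_snoring", "uars_mild_osa",
                      "moderate_osa", "severe_osa", "abnormal_other")

#' Construct a synthetic subject profile
#'
#' A profile is the generator-side ground truth for one subject: the target
#' respiratory swing of the PTT channel, arousal and desaturation event
#' rates, artefact burden and demographics. [simulate_subject()] turns a
#' profile into synthetic signals; the extraction modules should recover the
#' configured quantities.
#'
#' @param category one of [sleep_categories] (excluding `abnormal_other`,
#'   which arises from oximetry abnormality without obstruction and can be
#'   produced by setting `desat_rate` high with `n_obstructive = 0`).
#' @param swing_amplitude target trough-to-peak respiratory swing of the
#'   derived 1-Hz PTT channel, ms. This is the quantity PTTrs estimates.
#' @param ptt_baseline mean pulse transit time, ms (valid range 150-500).
#' @param arousal_rate PTT arousal events per hour.
#' @param arousal_drop depth of each arousal dip in the PTT channel, ms.
#' @param desat_rate desaturation events per hour.
#' @param desat_depth mean event depth below baseline saturation, percentage
#'   points.
#' @param desat_duration mean event duration, s.
#' @param baseline_spo2 baseline oxygen saturation, percent.
#' @param heart_rate mean heart rate, bpm (R-R intervals get 3% CV jitter).
#' @param respiratory_rate breaths per minute; must lie in (6, 19) so the
#'   respiratory oscillation survives the 1-Hz/3-sample smoothing chain.
#' @param artefact_fraction proportion of study time affected by
#'   plethysmograph artefact when the recording is passed through
#'   [inject_artefacts()].
#' @param spo2_artefact_fraction proportion of study time affected by SpO2
#'   motion artefact.
#' @param study_hours recording duration in hours.
#' @param age_months,weight_kg,height_cm,sex demographics carried into the
#'   feature table (`sex` is `"M"` or `"F"`).
#' @param n_obstructive number of video-witnessed obstructive episodes; `NULL`
#'   draws a category-consistent count.
#' @param ptt_noise_sd beat-to-beat PTT measurement noise, ms.
#' @param spo2_noise_sd SpO2 sensor noise before integer quantisation, percent.
#' @return an object of class `subject_profile`.
#' @examples
#' p <- subject_profile("uars_mild_osa", swing_amplitude = 20)
#' p$swing_amplitude
#' @export
subject_profile <- function(category = "normal",
                            swing_amplitude = 14,
                            ptt_baseline = 250,
                            arousal_rate = 6,
                            arousal_drop = 25,
                            desat_rate = 1,
                            desat_depth = 5,
                            desat_duration = 30,
                            baseline_spo2 = 98,
                            heart_rate = 95,
                            respiratory_rate = 13,
                            artefact_fraction = 0,
                            spo2_artefact_fraction = 0,
                            study_hours = 8,
                            age_months = 78,
                            weight_kg = 27,
                            height_cm = 119,
                            sex = "M",
                            n_obstructive = NULL,
                            ptt_noise_sd = 1,
                            spo2_noise_sd = 0.15) {
  p <- structure(list(
    category = match.arg(category, sleep_categories),
    swing_amplitude = swing_amplitude, ptt_baseline = ptt_baseline,
    arousal_rate = arousal_rate, arousal_drop = arousal_drop,
    desat_rate = desat_rate, desat_depth = desat_depth,
    desat_duration = desat_duration, baseline_spo2 = baseline_spo2,
    heart_rate = heart_rate, respiratory_rate = respiratory_rate,
    artefact_fraction = artefact_fraction,
    spo2_artefact_fraction = spo2_artefact_fraction,
    study_hours = study_hours, age_months = age_months,
    weight_kg = weight_kg, height_cm = height_cm, sex = sex,
    n_obstructive = n_obstructive,
    ptt_noise_sd = ptt_noise_sd, spo2_noise_sd = spo2_noise_sd
  ), class = "subject_profile")
  validate_profile(p)
  p
}

#' @keywords internal
#' @noRd
validate_profile <- function(p) {
  check_field(is.numeric(p$swing_amplitude) && p$swing_amplitude >= 0,
              "swing_amplitude", "must be >= 0 ms")
  check_field(p$ptt_baseline >= 150 && p$ptt_baseline <= 500,
              "ptt_baseline", "must lie in [150, 500] ms")
  check_field(p$artefact_fraction >= 0 && p$artefact_fraction < 1,
              "artefact_fraction", "must lie in [0, 1)")
  check_field(p$spo2_artefact_fraction >= 0 && p$spo2_artefact_fraction < 1,
              "spo2_artefact_fraction", "must lie in [0, 1)")
  check_field(p$study_hours > 0, "study_hours", "must be > 0")
  check_field(p$desat_depth >= 0, "desat_depth", "must be >= 0")
  check_field(p$baseline_spo2 <= 100 && p$baseline_spo2 > 50,
              "baseline_spo2", "must lie in (50, 100]")
  check_field(p$heart_rate > 30 && p$heart_rate < 220,
              "heart_rate", "must be a plausible bpm")
  check_field(p$respiratory_rate > 6 && p$respiratory_rate < 19,
              "respiratory_rate",
              "must lie in (6, 19) breaths/min for the 1-Hz smoothing chain")
  check_field(p$arousal_rate >= 0, "arousal_rate", "must be >= 0")
  check_field(p$arousal_drop >= 0, "arousal_drop", "must be >= 0")
  check_field(p$desat_rate >= 0, "desat_rate", "must be >= 0")
  check_field(p$sex %in% c("M", "F"), "sex", "must be \"M\" or \"F\"")
  invisible(p)
}

#' @export
print.subject_profile <- function(x, ...) {
  cat("<subject_profile>", x$category,
      sprintf("| swing %.1f ms | %g h | HR %g bpm | artefact %.0f%%\n",
              x$swing_amplitude, x$study_hours, x$heart_rate,
              100 * x$artefact_fraction))
  invisible(x)
}

#' Default per-category generator parameters
#'
#' Category prevalences follow the included-cohort breakdown
#' (174/239/132/63/21 of 629); per-category PTTrs swing means and SDs are
#' 13.68 (5.16), 15.23 (6.14), 20.73 (7.31), 23.69 (8.05) and 26.68 (9.07) ms
#' for normal, primary snoring, UARS/mild, moderate and severe respectively.
#' Demographics (age, weight, height, sex ratio) follow the included-cohort
#' summaries. Desaturation-event rates and depths are chosen so the derived
#' oximetry score is category-consistent (score 1 for normal through
#' UARS/mild, 2-3 for moderate, 4 for severe with at least three sub-80%
#' nadirs); arousal rates and desaturation distributions are plausible
#' configuration defaults rather than published values. Artefact burden is
#' drawn per subject (Beta(4, 3) for the plethysmograph, Beta(1, 4) for
#' SpO2) so that roughly 31% of a large cohort fails the 3-h artefact-free
#' PTT rule and a few percent fail the 4-h oximetry rule.
#'
#' @return a nested list of per-category distribution parameters; pass an
#'   edited copy to [draw_cohort_profiles()] or [simulate_cohort()].
#' @export
cohort_parameters <- function() {
  list(
    mix = c(normal = 174, primary_snoring = 239, uars_mild_osa = 132,
            moderate_osa = 63, severe_osa = 21) / 629,
    study_hours = c(mean = 9, sd = 0.8),
    artefact_beta = c(shape1 = 4, shape2 = 3),
    spo2_artefact_beta = c(shape1 = 1, shape2 = 4),
    categories = list(
      normal = list(
        swing = c(mean = 13.68, sd = 5.16), arousal_rate = 8,
        desat_rate = 0.8, desat_depth = 5, n_below_80 = 0,
        age_months = c(mean = 81.6, sd = 38.4), weight = c(mean = 27.9, sd = 15.0),
        height = c(mean = 120.9, sd = 20.0), male = 0.48,
        odi3 = c(meanlog = log(0.8), sdlog = 0.7),
        ptt_ai = c(mean = 10, sd = 6),
        min_spo2 = c(mean = 92, sd = 2), mean_spo2 = c(mean = 97.6, sd = 0.5),
        mean_nadir = c(mean = 93.2, sd = 1.3)),
      primary_snoring = list(
        swing = c(mean = 15.23, sd = 6.14), arousal_rate = 9,
        desat_rate = 1.2, desat_depth = 5, n_below_80 = 0,
        age_months = c(mean = 84.0, sd = 38.4), weight = c(mean = 30.1, sd = 18.3),
        height = c(mean = 122.0, sd = 20.8), male = 0.59,
        odi3 = c(meanlog = log(1.3), sdlog = 0.65),
        ptt_ai = c(mean = 10, sd = 6),
        min_spo2 = c(mean = 92, sd = 2), mean_spo2 = c(mean = 97.6, sd = 0.5),
        mean_nadir = c(mean = 93.2, sd = 1.3)),
      uars_mild_osa = list(
        swing = c(mean = 20.73, sd = 7.31), arousal_rate = 10,
        desat_rate = 2, desat_depth = 5.5, n_below_80 = 0,
        age_months = c(mean = 69.6, sd = 31.2), weight = c(mean = 23.3, sd = 13.7),
        height = c(mean = 114.2, sd = 18.2), male = 0.52,
        odi3 = c(meanlog = log(3.2), sdlog = 0.55),
        ptt_ai = c(mean = 10, sd = 6),
        min_spo2 = c(mean = 92, sd = 2), mean_spo2 = c(mean = 97.6, sd = 0.5),
        mean_nadir = c(mean = 93.2, sd = 1.3)),
      moderate_osa = list(
        swing = c(mean = 23.69, sd = 8.05), arousal_rate = 12,
        desat_rate = 12, desat_depth = 7, n_below_80 = 0,
        age_months = c(mean = 69.6, sd = 37.2), weight = c(mean = 26.1, sd = 20.0),
        height = c(mean = 115.3, sd = 21.4), male = 0.51,
        odi3 = c(min = 7.5, shape = 2, scale = 2.5),
        ptt_ai = c(mean = 13, sd = 6),
        min_spo2 = c(mean = 87, sd = 3), mean_spo2 = c(mean = 96.8, sd = 0.7),
        mean_nadir = c(mean = 91, sd = 2)),
      severe_osa = list(
        swing = c(mean = 26.68, sd = 9.07), arousal_rate = 14,
        desat_rate = 14, desat_depth = 21, n_below_80 = 4,
        age_months = c(mean = 51.6, sd = 18.0), weight = c(mean = 18.8, sd = 6.6),
        height = c(mean = 105.2, sd = 13.5), male = 0.57,
        odi3 = c(min = 10, shape = 2, scale = 4),
        ptt_ai = c(mean = 15, sd = 7),
        min_spo2 = c(mean = 75, sd = 4), mean_spo2 = c(mean = 95.5, sd = 1.0),
        mean_nadir = c(mean = 84, sd = 3))
    )
  )
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lower), upper)
}

#' Draw subject profiles for a synthetic cohort
#'
#' Draws categories from `mix` and, within each category, generator
#' parameters from [cohort_parameters()]. This is the cheap (signal-free)
#' half of [simulate_cohort()]; use it directly when only cohort composition
#' or artefact/duration structure is needed.
#'
#' @param n number of subjects.
#' @param mix named category proportions (must sum to 1); defaults to the
#'   configured prevalences.
#' @param seed integer seed.
#' @param params parameter list as returned by [cohort_parameters()].
#' @param artefacts draw per-subject artefact fractions (set `FALSE` for
#'   artefact-free cohorts).
#' @return list of [subject_profile()] objects.
#' @export
draw_cohort_profiles <- function(n, mix = NULL, seed = 1L,
                                 params = cohort_parameters(),
                                 artefacts = TRUE) {
  stopifnot(n > 0)
  if (is.null(mix)) mix <- params$mix
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("category proportions in `mix` must sum to 1", call. = FALSE)
  }
  if (is.null(names(mix)) || !all(names(mix) %in% sleep_categories)) {
    stop("`mix` must be named with sleep categories", call. = FALSE)
  }
  set.seed(seed)
  cats <- sample(names(mix), n, replace = TRUE, prob = mix)
  lapply(seq_len(n), function(i) {
    cat_i <- cats[i]
    cp <- params$categories[[cat_i]]
    hours <- rnorm_trunc(1, params$study_hours["mean"], params$study_hours["sd"],
                         lower = 5, upper = 12)
    af <- if (artefacts) {
      stats::rbeta(1, params$artefact_beta["shape1"], params$artefact_beta["shape2"])
    } else 0
    af_sp <- if (artefacts) {
      stats::rbeta(1, params$spo2_artefact_beta["shape1"],
                   params$spo2_artefact_beta["shape2"])
    } else 0
    subject_profile(
      category = cat_i,
      swing_amplitude = rnorm_trunc(1, cp$swing["mean"], cp$swing["sd"], lower = 2),
      arousal_rate = cp$arousal_rate,
      desat_rate = cp$desat_rate,
      desat_depth = cp$desat_depth,
      artefact_fraction = min(af, 0.95),
      spo2_artefact_fraction = min(af_sp, 0.95),
      study_hours = hours,
      age_months = rnorm_trunc(1, cp$age_months["mean"], cp$age_months["sd"],
                               lower = 6, upper = 215),
      weight_kg = rnorm_trunc(1, cp$weight["mean"], cp$weight["sd"],
                              lower = 6, upper = 130),
      height_cm = rnorm_trunc(1, cp$height["mean"], cp$height["sd"],
                              lower = 60, upper = 198),
      sex = if (stats::runif(1) < cp$male) "M" else "F",
      heart_rate = rnorm_trunc(1, 95, 10, lower = 60, upper = 140),
      respiratory_rate = rnorm_trunc(1, 13, 0.8, lower = 11, upper = 15)
    )
  })
}
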