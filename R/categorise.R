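# Rule-based diagnostic categorisation from video-surrogate obstruction
# labels plus the oximetry score, and the cohort exclusion flow.

#' Bundle one study's evidence for categorisation
#'
#' @param snoring_present snoring heard on the recording?
#' @param n_obstructive_episodes video-witnessed discrete obstructive
#'   episodes.
#' @param episodes_with_arousal how many of those episodes had an associated
#'   arousal (movement plus pulse-rate rise).
#' @param oximetry an `oximetry_summary` (or a list with at least `score`
#'   and `included`).
#' @param ptt a `ptt_summary` (or a list with at least `included`).
#' @return a `study_assessment` list.
#' @export
study_assessment <- function(snoring_present, n_obstructive_episodes,
                             episodes_with_arousal, oximetry, ptt) {
  check_field(n_obstructive_episodes >= 0, "n_obstructive_episodes",
              "must be a non-negative count")
  check_field(episodes_with_arousal >= 0 &&
                episodes_with_arousal <= n_obstructive_episodes,
              "episodes_with_arousal",
              "must be between 0 and n_obstructive_episodes")
  structure(list(snoring_present = isTRUE(snoring_present),
                 n_obstructive_episodes = n_obstructive_episodes,
                 episodes_with_arousal = episodes_with_arousal,
                 oximetry = oximetry, ptt = ptt),
            class = "study_assessment")
}

#' Assign the diagnostic category
#'
#' Categories follow the reporting rules: normal = no snoring, no
#' obstruction, oximetry score 1; primary snoring = snoring with fewer than
#' 3 witnessed obstructive episodes and score 1; UARS/mild OSA = at least 3
#' obstructive episodes with associated arousals and score 1; moderate OSA =
#' obstruction with arousals and score 2 or 3; severe OSA = obstruction with
#' arousals and score 4; abnormal other = score of 2 or more with no video
#' evidence of obstruction (or obstruction without any arousal, where the
#' obstructive surrogate is not established). With score 1, obstruction
#' seen fewer than 3 times - or without at least 3 arousal-associated
#' episodes - is reported as primary snoring. The mapping is total on valid
#' assessments.
#'
#' @param assessment a [study_assessment()].
#' @return one of [sleep_categories].
#' @export
assign_category <- function(assessment) {
  stopifnot(inherits(assessment, "study_assessment"))
  score <- assessment$oximetry$score
  n_obs <- assessment$n_obstructive_episodes
  n_ar <- assessment$episodes_with_arousal
  if (is.na(score)) stop("oximetry score undefined; cannot categorise",
                         call. = FALSE)
  if (score >= 2L) {
    if (n_obs == 0L || n_ar == 0L) return("abnormal_other")
    return(if (score == 4L) "severe_osa" else "moderate_osa")
  }
  if (n_obs >= 3L && n_ar >= 3L) return("uars_mild_osa")
  if (assessment$snoring_present || n_obs > 0L) return("primary_snoring")
  "normal"
}

#' Apply the cohort exclusion flow
#'
#' Removes technical failures (insufficient artefact-free oximetry, then
#' insufficient artefact-free PTT), studies categorised abnormal-other, and
#' rows with incomplete model variables, in that order of precedence, and
#' tabulates the reasons.
#'
#' @param features cohort feature data.frame (one row per subject) with at
#'   least `oximetry_included`, `ptt_included`, `category` and the model
#'   variable columns named in `required`.
#' @param required columns that must be complete for inclusion; defaults to
#'   the 15 model variables.
#' @return list with `included` (feature rows retained), `excluded` (rows
#'   with an `exclusion_reason` column) and `reasons` (count table).
#' @export
apply_exclusions <- function(features, required = model_variables()) {
  stopifnot(is.data.frame(features))
  reason <- rep(NA_character_, nrow(features))
  reason[!features$oximetry_included] <- "insufficient oximetry data"
  tech_ok <- is.na(reason)
  reason[tech_ok & !features$ptt_included] <- "insufficient PTT data"
  left <- is.na(reason)
  reason[left & features$category == "abnormal_other"] <- "abnormal other"
  left <- is.na(reason)
  req <- intersect(required, names(features))
  incomplete <- rowSums(is.na(features[, req, drop = FALSE])) > 0
  reason[left & incomplete] <- "incomplete data"
  keep <- is.na(reason)
  excluded <- features[!keep, , drop = FALSE]
  excluded$exclusion_reason <- reason[!keep]
  reasons <- as.data.frame(table(reason = factor(
    reason[!keep],
    levels = c("insufficient oximetry data", "insufficient PTT data",
               "abnormal other", "incomplete data"))),
    responseName = "n")
  list(included = features[keep, , drop = FALSE],
       excluded = excluded,
       reasons = reasons)
}

#' The binary disorder outcome
#'
#' Normal and primary snoring count as no-disorder; UARS/mild, moderate and
#' severe OSA count as disorder.
#'
#' @param category character vector of categories.
#' @return integer vector (0 = no disorder, 1 = disorder).
#' @export
disorder_flag <- function(category) {
  as.integer(category %in% c("uars_mild_osa", "moderate_osa", "severe_osa"))
}
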