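# Feature-level cohort generator: draws per-subject feature rows directly
# from the per-category distributions, bypassing waveform synthesis. This
# is the generator used for the statistical layer at full cohort size;
# signal-level recordings come from simulate_cohort().

draw_cat_features <- function(n, cat, cp) {
  odi3 <- if (!is.null(cp$odi3["meanlog"]) && !is.na(cp$odi3["meanlog"])) {
    # truncated lognormal below the score gate (inverse-CDF, no boundary atom)
    p_hi <- stats::plnorm(6.5, cp$odi3["meanlog"], cp$odi3["sdlog"])
    stats::qlnorm(stats::runif(n, 0, p_hi), cp$odi3["meanlog"], cp$odi3["sdlog"])
  } else {
    pmin(cp$odi3["min"] + stats::rgamma(n, cp$odi3["shape"], scale = cp$odi3["scale"]), 60)
  }
  score1 <- cat %in% c("normal", "primary_snoring", "uars_mild_osa")
  if (cat == "moderate_osa") {
    # some moderate studies gate on ODI4 >= 4 with ODI3 below its threshold
    low <- stats::runif(n) < 0.25
    odi3[low] <- stats::runif(sum(low), 4.5, 6.9)
  }
  odi4 <- if (score1) {
    pmin(odi3 * stats::runif(n, 0.2, 0.6), 3.8)
  } else {
    pmax(odi3 * stats::runif(n, 0.4, 0.7), 4.2)
  }
  n80 <- switch(cat,
                moderate_osa = sample(0:2, n, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
                severe_osa = 3L + stats::rpois(n, 1.5),
                rep(0L, n))
  min_spo2 <- rnorm_trunc(n, cp$min_spo2["mean"], cp$min_spo2["sd"], 55, 99)
  min_spo2 <- ifelse(n80 > 0, pmin(min_spo2, 79), min_spo2)
  mean_nadir <- pmax(rnorm_trunc(n, cp$mean_nadir["mean"], cp$mean_nadir["sd"], 58, 99),
                     min_spo2 + 0.5)
  ptt_duration <- rnorm_trunc(n, 4.79, 1.32, lower = 3, upper = 11)
  data.frame(
    category = cat,
    pttrs = rnorm_trunc(n, cp$swing["mean"], cp$swing["sd"], lower = 2),
    ptt_ai = rnorm_trunc(n, cp$ptt_ai["mean"], cp$ptt_ai["sd"], lower = 0.5),
    ptt_duration = ptt_duration,
    odi3 = odi3, odi4 = odi4,
    min_spo2 = min_spo2,
    mean_spo2 = rnorm_trunc(n, cp$mean_spo2["mean"], cp$mean_spo2["sd"], 90, 100),
    mean_nadir = mean_nadir,
    n_below_80 = n80,
    study_duration = pmax(stats::rnorm(n, 9, 0.8), ptt_duration + 0.3),
    sex = factor(ifelse(stats::runif(n) < cp$male, "M", "F"), levels = c("F", "M")),
    weight = rnorm_trunc(n, cp$weight["mean"], cp$weight["sd"], 6, 130),
    height = rnorm_trunc(n, cp$height["mean"], cp$height["sd"], 60, 198),
    age_months = rnorm_trunc(n, cp$age_months["mean"], cp$age_months["sd"], 6, 215),
    heart_rate = rnorm_trunc(n, 95, 10, 60, 140),
    heart_rate_sd = rnorm_trunc(n, 10, 3, lower = 2)
  )
}

#' Simulate a feature-table cohort
#'
#' Draws one complete 15-variable feature row per subject directly from the
#' per-category distributions of [cohort_parameters()] (PTTrs from the
#' published per-category means/SDs; oximetry indices consistent with the
#' category's expected oximetry score; demographics from the cohort
#' summaries). The binary outcome is either the category truth
#' (`outcome = "category"`: disorder = UARS/mild, moderate or severe), a
#' Bernoulli draw from a two-variable logistic model in ODI3 and PTTrs
#' (`outcome = "logistic"`, coefficients `beta`), or independent noise
#' (`outcome = "null"`) for calibration experiments.
#'
#' @param n cohort size.
#' @param mix named category proportions; defaults to the configured
#'   prevalences.
#' @param seed integer seed.
#' @param params [cohort_parameters()] list.
#' @param outcome outcome mechanism (see above).
#' @param beta intercept and (ODI3, PTTrs) coefficients for
#'   `outcome = "logistic"`; defaults to the published two-variable model.
#' @param null_prevalence disorder probability under `outcome = "null"`.
#' @return data.frame with the fifteen model variables, `age_months`,
#'   `oximetry_score`, `category`, `score3` and `disorder`.
#' @export
simulate_feature_cohort <- function(n, mix = NULL, seed = 1L,
                                    params = cohort_parameters(),
                                    outcome = c("category", "logistic", "null"),
                                    beta = c(-4.40943, 0.56794, 0.09504),
                                    null_prevalence = 0.35) {
  outcome <- match.arg(outcome)
  stopifnot(n > 0)
  if (is.null(mix)) mix <- params$mix
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("category proportions in `mix` must sum to 1", call. = FALSE)
  }
  set.seed(seed)
  cats <- sample(names(mix), n, replace = TRUE, prob = mix)
  parts <- lapply(names(mix), function(cat) {
    k <- sum(cats == cat)
    if (k == 0L) return(NULL)
    draw_cat_features(k, cat, params$categories[[cat]])
  })
  tab <- do.call(rbind, parts)
  tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
  rownames(tab) <- NULL
  tab$oximetry_score <- oximetry_score(tab$odi3, tab$odi4, tab$min_spo2,
                                       tab$n_below_80)
  tab$score3 <- severity_score3(tab$category)
  tab$disorder <- switch(outcome,
    category = disorder_flag(tab$category),
    logistic = stats::rbinom(nrow(tab), 1,
                             stats::plogis(beta[1] + beta[2] * tab$odi3 +
                                             beta[3] * tab$pttrs)),
    null = stats::rbinom(nrow(tab), 1, null_prevalence))
  tab
}
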