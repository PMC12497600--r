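# Statistical layer: multinomial severity model, logistic disorder model
# with iterated variable selection, and the decision-tree cross-check.

#' The fifteen candidate predictors of the disorder model
#' @return character vector of column names.
#' @export
model_variables <- function() {
  c("pttrs", "ptt_ai", "ptt_duration", "oximetry_score", "odi3", "odi4",
    "min_spo2", "mean_spo2", "mean_nadir", "study_duration", "sex",
    "weight", "height", "heart_rate", "heart_rate_sd")
}

#' Covariates of the three-level severity (multinomial) model
#' @return character vector of column names.
#' @export
multinomial_variables <- function() {
  c("pttrs", "sex", "mean_nadir", "age_months", "oximetry_score",
    "weight", "height", "odi4")
}

#' Map diagnostic categories to the three-level severity score
#'
#' Level 1 = normal or primary snoring, level 2 = UARS/mild OSA, level 3 =
#' moderate or severe OSA. The returned factor puts `reference` first so a
#' baseline-category multinomial fit models log-odds against it.
#'
#' @param category character vector of categories.
#' @param reference reference level, default `"3"`.
#' @return factor with levels 1-3, reference first.
#' @export
severity_score3 <- function(category, reference = "3") {
  lev <- ifelse(category %in% c("normal", "primary_snoring"), "1",
                ifelse(category == "uars_mild_osa", "2", "3"))
  stats::relevel(factor(lev, levels = c("1", "2", "3")), ref = reference)
}

coef_table_glm <- function(fit) {
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             z = sm[, 3], p = sm[, 4], row.names = NULL)
}

# variable-level p: smallest p over the terms a variable generates
variable_p <- function(coefs, variables, data) {
  vapply(variables, function(v) {
    terms <- if (is.factor(data[[v]]) || is.character(data[[v]])) {
      grep(paste0("^", v), coefs$term, value = TRUE)
    } else v
    min(coefs$p[coefs$term %in% terms], na.rm = TRUE)
  }, numeric(1))
}

#' Fit the binary disorder logistic model
#'
#' Maximum-likelihood logistic regression of the binary disorder outcome
#' (`disorder`: 1 = UARS/mild, moderate or severe OSA) on the requested
#' variables, fitted on the full dataset. Quasi-separation or
#' non-convergence raises an explicit warning with diagnostics rather than
#' failing silently.
#'
#' @param table feature data.frame containing `disorder` and the variables.
#' @param variables predictor columns; defaults to all fifteen.
#' @return a `fitted_model` list: `kind`, `fit` (the glm), `coef`
#'   (term/estimate/se/z/p), `variables`.
#' @export
fit_logistic <- function(table, variables = model_variables()) {
  stopifnot(all(c("disorder", variables) %in% names(table)))
  f <- stats::reformulate(variables, response = "disorder")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, family = stats::binomial(), data = table),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep || !fit$converged) {
    warning(sprintf(
      "possible separation or non-convergence (converged = %s, max |coef| = %.3g)",
      fit$converged, max(abs(stats::coef(fit)), na.rm = TRUE)), call. = FALSE)
  }
  structure(list(kind = "logistic", fit = fit, coef = coef_table_glm(fit),
                 variables = variables),
            class = "fitted_model")
}

#' Fit the three-level severity multinomial model
#'
#' Baseline-category multinomial logit of the severity score on the eight
#' severity-model covariates, with `reference` as the baseline, so each
#' equation models the log-odds of a level against the reference.
#'
#' @param table feature data.frame with `category` (or a precomputed
#'   `score3` factor) and the covariates.
#' @param variables covariates; defaults to [multinomial_variables()].
#' @param reference baseline level of the three-level score.
#' @param maxit,reltol optimiser controls.
#' @return a `fitted_model` with `coef` carrying one block per non-reference
#'   level (`equation` column) and a `predict_probs(newdata)` closure.
#' @export
fit_multinomial <- function(table, variables = multinomial_variables(),
                            reference = "3", maxit = 500, reltol = 1e-8) {
  stopifnot(all(variables %in% names(table)))
  dat <- table
  if (!"score3" %in% names(dat)) {
    dat$score3 <- severity_score3(dat$category, reference)
  } else {
    dat$score3 <- stats::relevel(factor(dat$score3), ref = reference)
  }
  if (nlevels(droplevels(dat$score3)) != 3L) {
    stop("the severity outcome must have 3 observed levels", call. = FALSE)
  }
  f <- stats::reformulate(variables, response = "score3")
  fit <- nnet::multinom(f, data = dat, trace = FALSE, maxit = maxit,
                        reltol = reltol, Hess = TRUE)
  if (fit$convergence != 0) {
    warning("multinomial optimiser did not converge; interpret coefficients cautiously",
            call. = FALSE)
  }
  sm <- summary(fit)
  est <- sm$coefficients
  se <- sm$standard.errors
  coefs <- do.call(rbind, lapply(rownames(est), function(lv) {
    z <- est[lv, ] / se[lv, ]
    data.frame(equation = paste0(lv, " vs ", reference),
               term = colnames(est), estimate = est[lv, ], se = se[lv, ],
               z = z, p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  }))
  structure(list(kind = "multinomial", fit = fit, coef = coefs,
                 variables = variables, reference = reference,
                 predict_probs = function(newdata) {
                   p <- stats::predict(fit, newdata = newdata, type = "probs")
                   if (is.null(dim(p))) p <- matrix(p, nrow = 1,
                                                    dimnames = list(NULL, names(p)))
                   p
                 }),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("<fitted_model>", x$kind, "on",
      paste(utils::head(x$variables, 6), collapse = ", "),
      if (length(x$variables) > 6) "..." else "", "\n")
  if (!is.null(x$coef)) print(format(x$coef, digits = 4), row.names = FALSE)
  invisible(x)
}

#' In-sample (or new-data) performance of a binary model
#'
#' Classifies at `threshold` on the predicted disorder probability and
#' returns the full metric suite plus the ROC AUC.
#'
#' @param model a logistic `fitted_model`.
#' @param table data with `disorder` and the model variables.
#' @param threshold classification threshold on the predicted probability.
#' @param positive_class passed to [confusion_metrics()].
#' @return list with `metrics` (a `confusion_metrics`), `auc`, `prob`.
#' @export
model_metrics <- function(model, table, threshold = 0.5,
                          positive_class = "negative") {
  p <- stats::predict(model$fit, newdata = table, type = "response")
  pred <- as.integer(p >= threshold)
  cc <- confusion_counts(table$disorder, pred)
  list(metrics = confusion_metrics(cc$tn, cc$fp, cc$fn, cc$tp,
                                   positive_class = positive_class),
       auc = roc_auc(p, table$disorder)$auc,
       prob = p)
}

#' Iterated logistic variable selection
#'
#' Iteration 1 fits all candidate variables and drops those with p >
#' `alpha`; iteration 2 refits the survivors; iteration 3 keeps the two
#' survivors with the smallest p-values (the principal variables). All
#' three fitted models and their in-sample metric panels are returned.
#'
#' @param table feature data.frame with `disorder` and the candidates.
#' @param alpha retention threshold on the Wald p-value.
#' @param variables candidate set; defaults to the fifteen.
#' @return list with `iterations` (named fitted models `full`,
#'   `significant`, `principal`), `selected` (variable sets), `metrics`
#'   (metric panels per iteration).
#' @export
select_variables <- function(table, alpha = 0.05,
                             variables = model_variables()) {
  it1 <- fit_logistic(table, variables)
  p1 <- variable_p(it1$coef, variables, table)
  sig <- names(p1)[p1 <= alpha]
  if (length(sig) < 2L) {
    warning(sprintf("only %d variable(s) significant at alpha = %g",
                    length(sig), alpha), call. = FALSE)
  }
  it2 <- if (length(sig) >= 1L) fit_logistic(table, sig) else NULL
  principal <- if (!is.null(it2)) {
    p2 <- variable_p(it2$coef, sig, table)
    names(sort(p2))[seq_len(min(2L, length(p2)))]
  } else character(0)
  it3 <- if (length(principal) >= 1L) fit_logistic(table, principal) else NULL
  iterations <- list(full = it1, significant = it2, principal = it3)
  metrics <- lapply(iterations, function(m) {
    if (is.null(m)) NULL else model_metrics(m, table)
  })
  list(iterations = iterations,
       selected = list(significant = sort(sig), principal = sort(principal)),
       metrics = metrics)
}

#' Decision-tree cross-check
#'
#' Depth-limited classification tree on a stratified train/test split
#' (70/30 by default); performance is reported on the held-out test set.
#' Deterministic for a fixed seed.
#'
#' @param table feature data.frame with `disorder`.
#' @param variables predictor columns.
#' @param split training proportion.
#' @param seed integer seed for the stratified split.
#' @param maxdepth tree depth limit.
#' @return a `fitted_model` with `fit` (rpart), `metrics` (test-set panel),
#'   `train_idx`.
#' @export
fit_tree <- function(table, variables = c("odi3", "pttrs"), split = 0.7,
                     seed = 1L, maxdepth = 4L) {
  stopifnot(all(c("disorder", variables) %in% names(table)))
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(table)), table$disorder),
                       function(ix) sample(ix, max(1L, round(split * length(ix))))))
  idx <- sort(idx)
  train <- table[idx, , drop = FALSE]
  test <- table[-idx, , drop = FALSE]
  if (length(unique(train$disorder)) < 2L) {
    stop("training split contains a single outcome class", call. = FALSE)
  }
  train$disorder_f <- factor(train$disorder, levels = c(0, 1))
  f <- stats::reformulate(variables, response = "disorder_f")
  fit <- rpart::rpart(f, data = train, method = "class",
                      control = rpart::rpart.control(maxdepth = maxdepth,
                                                     cp = 0.005, xval = 0))
  prob <- stats::predict(fit, newdata = test, type = "prob")[, "1"]
  pred <- as.integer(prob >= 0.5)
  cc <- confusion_counts(test$disorder, pred)
  metrics <- confusion_metrics(cc$tn, cc$fp, cc$fn, cc$tp)
  structure(list(kind = "tree", fit = fit, coef = NULL,
                 variables = variables, metrics = metrics,
                 auc = tryCatch(roc_auc(prob, test$disorder)$auc,
                                error = function(e) NA_real_),
                 train_idx = idx),
            class = "fitted_model")
}
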