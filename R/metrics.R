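# Diagnostic-accuracy metric suite, ROC/AUC and summary-statistics t tests.

#' Full confusion-matrix metric suite
#'
#' Takes the four cell counts in the disorder-as-positive caption convention
#' (`tp` = disorder correctly predicted, `tn` = no-disorder correctly
#' predicted) and computes the complete diagnostic-performance panel.
#' `positive_class` names the class treated as "positive" for sensitivity,
#' PPV and the detection metrics; the default `"negative"` treats the
#' majority no-disorder class as positive, the convention under which the
#' published panels are internally consistent.
#'
#' Accuracy gets an exact (Clopper-Pearson) binomial interval and a
#' one-sided exact test against the no-information rate; kappa is
#' chance-corrected agreement; McNemar's chi-square uses the continuity
#' correction on the discordant cells. Metrics with zero denominators are
#' reported as `NA`.
#'
#' @param tn,fp,fn,tp non-negative integer counts (disorder = positive
#'   labelling).
#' @param positive_class `"negative"` (no-disorder treated as the positive
#'   class) or `"positive"`.
#' @param conf_level confidence level for the accuracy interval.
#' @return a `confusion_metrics` list.
#' @examples
#' m <- confusion_metrics(tn = 372, fp = 35, fn = 72, tp = 143)
#' round(c(m$accuracy, m$sensitivity, m$specificity), 4)
#' @export
confusion_metrics <- function(tn, fp, fn, tp,
                              positive_class = c("negative", "positive"),
                              conf_level = 0.95) {
  positive_class <- match.arg(positive_class)
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)

  # relabel so that (TP*, FP*, FN*, TN*) describe the requested positive class
  if (positive_class == "negative") {
    TP <- tn; FN <- fp; FP <- fn; TN <- tp
  } else {
    TP <- tp; FN <- fn; FP <- fp; TN <- tn
  }
  rate <- function(num, den) if (den > 0) num / den else NA_real_

  accuracy <- (TP + TN) / total
  sens <- rate(TP, TP + FN)
  spec <- rate(TN, TN + FP)
  ppv <- rate(TP, TP + FP)
  npv <- rate(TN, TN + FN)
  prevalence <- (TP + FN) / total
  detection_rate <- TP / total
  detection_prevalence <- (TP + FP) / total
  balanced_accuracy <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2

  nir <- max(prevalence, 1 - prevalence)
  correct <- TP + TN
  bt <- stats::binom.test(correct, total, conf.level = conf_level)
  acc_ci <- as.numeric(bt$conf.int)
  p_acc_gt_nir <- stats::binom.test(correct, total, p = nir,
                                    alternative = "greater")$p.value

  pe <- ((TP + FN) / total) * ((TP + FP) / total) +
    ((TN + FP) / total) * ((TN + FN) / total)
  kappa <- if (pe < 1) (accuracy - pe) / (1 - pe) else NA_real_

  disc <- FP + FN
  if (disc > 0) {
    mcnemar_stat <- (abs(FP - FN) - 1)^2 / disc
    mcnemar_p <- stats::pchisq(mcnemar_stat, df = 1, lower.tail = FALSE)
  } else {
    mcnemar_stat <- NA_real_
    mcnemar_p <- NA_real_
  }

  structure(list(
    tn = tn, fp = fp, fn = fn, tp = tp,
    positive_class = positive_class,
    accuracy = accuracy, accuracy_ci = acc_ci, conf_level = conf_level,
    no_information_rate = nir, p_acc_gt_nir = p_acc_gt_nir,
    kappa = kappa, mcnemar_stat = mcnemar_stat, mcnemar_p = mcnemar_p,
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    prevalence = prevalence, detection_rate = detection_rate,
    detection_prevalence = detection_prevalence,
    balanced_accuracy = balanced_accuracy
  ), class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, digits = 4, ...) {
  cat("Confusion-matrix metrics (positive class:", x$positive_class, "class)\n")
  cat(sprintf("  Accuracy             %.*f  (%.*f, %.*f)\n", digits, x$accuracy,
              digits, x$accuracy_ci[1], digits, x$accuracy_ci[2]))
  cat(sprintf("  No information rate  %.*f   P[Acc > NIR] %.3g\n", digits,
              x$no_information_rate, x$p_acc_gt_nir))
  cat(sprintf("  Kappa                %.*f   McNemar p %.4g\n", digits,
              x$kappa, x$mcnemar_p))
  for (f in c("sensitivity", "specificity", "ppv", "npv", "prevalence",
              "detection_rate", "detection_prevalence", "balanced_accuracy")) {
    cat(sprintf("  %-20s %.*f\n", gsub("_", " ", f), digits, x[[f]]))
  }
  invisible(x)
}

#' Confusion counts from truth/prediction vectors
#'
#' @param truth,pred vectors coercible to 0/1 (1 = disorder).
#' @return list with `tn`, `fp`, `fn`, `tp` in the disorder-as-positive
#'   convention, ready for [confusion_metrics()].
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred),
            all(truth %in% 0:1), all(pred %in% 0:1))
  list(tn = sum(truth == 0 & pred == 0),
       fp = sum(truth == 0 & pred == 1),
       fn = sum(truth == 1 & pred == 0),
       tp = sum(truth == 1 & pred == 1))
}

#' ROC curve and area under the curve
#'
#' Sweeps every threshold of the score, accumulates the true- and
#' false-positive rates and integrates by the trapezoidal rule, which
#' equals the Mann-Whitney pairwise-concordance statistic (ties counted
#' half).
#'
#' @param scores numeric scores; larger = more disorder-like.
#' @param labels binary labels (1/TRUE = disorder).
#' @return list with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # collapse tied scores into single thresholds
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp_g <- tapply(l == 1L, grp, sum)
  fp_g <- tapply(l == 0L, grp, sum)
  tpr <- c(0, cumsum(tp_g) / n_pos)
  fpr <- c(0, cumsum(fp_g) / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  thr <- c(Inf, s[!duplicated(grp)])
  list(auc = auc,
       curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr))
}

#' Two-sample t comparison from printed summary statistics
#'
#' Pooled-variance two-sample t computed from the group sizes, means and
#' SDs alone, so published summary tables can be re-analysed without raw
#' data. The difference is reported as `mean2 - mean1`.
#'
#' @param n1,mean1,sd1 first group summaries.
#' @param n2,mean2,sd2 second group summaries.
#' @param conf_level confidence level for the difference interval.
#' @return list with `difference`, `se`, `conf_int`, `t`, `df`, `p`.
#' @examples
#' group_summary_t(413, 82.86, 38.0, 216, 67.73, 32.1)$t
#' @export
group_summary_t <- function(n1, mean1, sd1, n2, mean2, sd2,
                            conf_level = 0.95) {
  check_field(n1 >= 2 && n2 >= 2, "n", "both group sizes must be >= 2")
  check_field(sd1 > 0 && sd2 > 0, "sd", "both SDs must be > 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- mean2 - mean1
  tval <- diff / se
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  list(difference = diff, se = se,
       conf_int = c(diff - q * se, diff + q * se),
       t = tval, df = df,
       p = 2 * stats::pt(-abs(tval), df))
}
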