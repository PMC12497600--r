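test_that("perfect diagonal gives unit accuracy, sensitivity and kappa", {
  m <- confusion_metrics(40, 0, 0, 25)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$kappa, 1)
  expect_error(confusion_metrics(-1, 0, 0, 2), "non-negative")
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
})

test_that("metric suite equals a brute-force per-record counting oracle", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(20:200, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- ifelse(rbinom(n, 1, 0.8) == 1, truth, 1 - truth)
    if (length(unique(truth)) < 2) next
    cc <- confusion_counts(truth, pred)
    m <- confusion_metrics(cc$tn, cc$fp, cc$fn, cc$tp)
    # oracle: direct counting with the no-disorder class as positive
    expect_equal(m$accuracy, mean(truth == pred))
    expect_equal(m$sensitivity, mean(pred[truth == 0] == 0))
    if (any(truth == 1)) expect_equal(m$specificity, mean(pred[truth == 1] == 1))
    if (any(pred == 0)) expect_equal(m$ppv, mean(truth[pred == 0] == 0))
    expect_equal(m$prevalence, mean(truth == 0))
    expect_equal(m$detection_rate, mean(truth == 0 & pred == 0))
    expect_equal(m$detection_prevalence, mean(pred == 0))
  }
})

test_that("metric suite agrees with caret's confusionMatrix", {
  skip_if_not_installed("caret")
  set.seed(3)
  for (rep in 1:5) {
    tn <- sample(50:300, 1); fp <- sample(5:80, 1)
    fn <- sample(5:80, 1); tp <- sample(30:200, 1)
    m <- confusion_metrics(tn, fp, fn, tp)
    tab <- table(factor(rep(c(0, 1, 0, 1), c(tn, fn, fp, tp)), levels = c(0, 1)),
                 factor(rep(c(0, 0, 1, 1), c(tn, fn, fp, tp)), levels = c(0, 1)))
    cm <- caret::confusionMatrix(t(tab), positive = "0")
    expect_equal(m$accuracy, unname(cm$overall["Accuracy"]))
    expect_equal(m$kappa, unname(cm$overall["Kappa"]))
    expect_equal(m$no_information_rate, unname(cm$overall["AccuracyNull"]))
    expect_equal(m$mcnemar_p, unname(cm$overall["McnemarPValue"]))
    expect_equal(m$sensitivity, unname(cm$byClass["Sensitivity"]))
    expect_equal(m$specificity, unname(cm$byClass["Specificity"]))
    expect_equal(m$ppv, unname(cm$byClass["Pos Pred Value"]))
    expect_equal(m$npv, unname(cm$byClass["Neg Pred Value"]))
    expect_equal(m$balanced_accuracy, unname(cm$byClass["Balanced Accuracy"]))
    expect_equal(m$accuracy_ci, unname(cm$overall[c("AccuracyLower", "AccuracyUpper")]))
  }
})

test_that("kappa is 1 only with empty off-diagonals and ~0 under independence", {
  expect_lt(confusion_metrics(50, 1, 0, 50)$kappa, 1)
  set.seed(21)
  ks <- replicate(200, {
    truth <- rbinom(300, 1, 0.5)
    pred <- rbinom(300, 1, 0.5)      # independent of truth
    cc <- confusion_counts(truth, pred)
    confusion_metrics(cc$tn, cc$fp, cc$fn, cc$tp)$kappa
  })
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("AUC: separation, null behaviour, and the O(n^2) concordance oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  set.seed(5)
  null_auc <- roc_auc(rnorm(2000), rbinom(2000, 1, 0.5))$auc
  expect_lt(abs(null_auc - 0.5), 0.03)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
  for (rep in 1:20) {
    n <- 30
    s <- round(rnorm(n), 1)            # ties on purpose
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    pos <- s[l == 1]; neg <- s[l == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(s, l)$auc, mean(pairs))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  s <- rnorm(300); l <- rbinom(300, 1, 0.4)
  a <- roc_auc(s, l)$auc
  expect_equal(roc_auc(exp(s), l)$auc, a)
  expect_equal(roc_auc(2 * s - 7, l)$auc, a)
})

test_that("AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(13)
  s <- rnorm(400); l <- rbinom(400, 1, 0.35)
  a <- roc_auc(s, l)$auc
  b <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE, direction = "<")))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("summary-statistics t matches t.test on raw data", {
  set.seed(17)
  x <- rnorm(40, 10, 2); y <- rnorm(55, 12, 2.5)
  r <- group_summary_t(length(x), mean(x), sd(x), length(y), mean(y), sd(y))
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  expect_equal(r$df, unname(tt$parameter))
  expect_equal(r$conf_int, as.numeric(tt$conf.int), tolerance = 1e-8)
})

test_that("identical groups give zero difference and t", {
  r <- group_summary_t(50, 20, 5, 50, 20, 5)
  expect_equal(r$difference, 0)
  expect_equal(r$t, 0)
  expect_error(group_summary_t(1, 5, 1, 30, 5, 1), "group sizes")
  expect_error(group_summary_t(10, 5, 0, 30, 5, 1), "SD")
})
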