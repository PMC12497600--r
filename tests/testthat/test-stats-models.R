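test_that("logistic refit recovers known coefficients at n = 5,000", {
  set.seed(101)
  cover <- c()
  for (rep in 1:8) {
    tab <- simulate_feature_cohort(5000, seed = 100 + rep, outcome = "logistic")
    fm <- suppressWarnings(fit_logistic(tab, c("odi3", "pttrs")))
    beta <- c(-4.40943, 0.56794, 0.09504)
    cover <- c(cover, abs(fm$coef$estimate - beta) <= 2 * fm$coef$se)
  }
  expect_gte(mean(cover), 0.90)
})

test_that("an uninformative covariate gets a near-zero coefficient", {
  tab <- simulate_feature_cohort(3000, seed = 9, outcome = "logistic")
  tab$flat <- 0
  fm <- suppressWarnings(fit_logistic(tab, c("odi3", "pttrs", "flat")))
  row <- fm$coef[fm$coef$term == "flat", ]
  # an all-zero column is aliased out of the fit, or estimated at ~0
  expect_true(nrow(row) == 0 || row$p > 0.9 || abs(row$estimate) < 1e-6)
})

test_that("perfect separation raises an explicit warning", {
  tab <- data.frame(x = c(rnorm(50, -3), rnorm(50, 3)),
                    disorder = rep(c(0, 1), each = 50))
  w <- capture_warnings(fit_logistic(tab, "x"))
  expect_true(any(grepl("separation|converge", w)))
})

test_that("pure-noise covariate is flagged significant at ~5% across seeds", {
  set.seed(33)
  hits <- 0
  for (rep in 1:40) {
    tab <- simulate_feature_cohort(800, seed = 500 + rep, outcome = "logistic")
    tab$noise <- rnorm(nrow(tab))
    fm <- suppressWarnings(fit_logistic(tab, c("odi3", "pttrs", "noise")))
    hits <- hits + (fm$coef$p[fm$coef$term == "noise"] < 0.05)
  }
  expect_lte(hits / 40, 0.15)          # |z| < 1.96 in the large majority
})

test_that("multinomial class probabilities sum to one", {
  tab <- simulate_feature_cohort(400, seed = 4)
  fm <- fit_multinomial(tab)
  pr <- fm$predict_probs(tab[1:25, ])
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))
  expect_identical(sort(unique(fm$coef$equation)), c("1 vs 3", "2 vs 3"))
})

test_that("multinomial refit recovers known coefficients", {
  set.seed(55)
  b12 <- c(2.2, -0.5, 0.9)     # intercept, x1, x2 for level 1 vs 3
  b22 <- c(1.1, 0.4, -0.6)     # level 2 vs 3
  cover <- c()
  for (rep in 1:5) {
    n <- 5000
    x1 <- rnorm(n); x2 <- rnorm(n)
    l1 <- exp(b12[1] + b12[2] * x1 + b12[3] * x2)
    l2 <- exp(b22[1] + b22[2] * x1 + b22[3] * x2)
    p <- cbind(l1, l2, 1) / (l1 + l2 + 1)
    y <- apply(p, 1, function(pr) sample(c("1", "2", "3"), 1, prob = pr))
    tab <- data.frame(score3 = y, x1 = x1, x2 = x2)
    fm <- fit_multinomial(tab, variables = c("x1", "x2"))
    est <- fm$coef
    truth <- c(b12, b22)
    got <- est$estimate[order(est$equation, match(est$term, c("(Intercept)", "x1", "x2")))]
    ses <- est$se[order(est$equation, match(est$term, c("(Intercept)", "x1", "x2")))]
    cover <- c(cover, abs(got - truth) <= 2 * ses)
  }
  expect_gte(mean(cover), 0.90)
})

test_that("iterated selection keeps everything at alpha = 1 and obeys column order", {
  tab <- simulate_feature_cohort(629, seed = 12, outcome = "category")
  sel_all <- suppressWarnings(select_variables(tab, alpha = 1))
  expect_setequal(sel_all$selected$significant, model_variables())
  sel_a <- suppressWarnings(select_variables(tab))
  tab_shuffled <- tab[, sample(ncol(tab))]
  sel_b <- suppressWarnings(select_variables(tab_shuffled))
  expect_identical(sel_a$selected, sel_b$selected)
})

test_that("selection returns near-empty survivor set on pure noise", {
  set.seed(77)
  sizes <- vapply(1:10, function(rep) {
    tab <- simulate_feature_cohort(629, seed = 900 + rep, outcome = "null")
    sel <- suppressWarnings(select_variables(tab))
    length(sel$selected$significant)
  }, numeric(1))
  expect_lte(stats::median(sizes), 1)
  expect_lte(mean(sizes), 2)
})

test_that("selection finds the two informative variables", {
  hits <- 0
  for (sd in 1:10) {
    tab <- simulate_feature_cohort(629, seed = 200 + sd, outcome = "logistic")
    sel <- suppressWarnings(select_variables(tab))
    hits <- hits + identical(sel$selected$principal, c("odi3", "pttrs"))
  }
  expect_gte(hits, 9)
})

test_that("decision tree learns an exact threshold rule", {
  set.seed(8)
  tab <- simulate_feature_cohort(2000, seed = 21, outcome = "category")
  tab$disorder <- as.integer(tab$odi3 > 7 | tab$pttrs > 20)
  tr <- fit_tree(tab, c("odi3", "pttrs"), seed = 3)
  expect_gte(tr$metrics$accuracy, 0.95)
})

test_that("tree is deterministic for a fixed seed", {
  tab <- simulate_feature_cohort(629, seed = 31, outcome = "category")
  a <- fit_tree(tab, c("odi3", "pttrs"), seed = 7)
  b <- fit_tree(tab, c("odi3", "pttrs"), seed = 7)
  expect_identical(a$train_idx, b$train_idx)
  expect_equal(a$metrics$accuracy, b$metrics$accuracy)
  d <- data.frame(odi3 = rnorm(30), pttrs = rnorm(30), disorder = rep(0L, 30))
  expect_error(fit_tree(d, c("odi3", "pttrs"), seed = 1), "single outcome class")
})

test_that("tree and two-variable logistic reach similar accuracy", {
  # cohort large enough that the tree's held-out test split estimates
  # accuracy to ~1 percentage point
  tab <- simulate_feature_cohort(2500, seed = 41, outcome = "category")
  fm <- suppressWarnings(fit_logistic(tab, c("odi3", "pttrs")))
  mm <- model_metrics(fm, tab)
  tr <- fit_tree(tab, c("odi3", "pttrs"), seed = 41)
  expect_lt(abs(mm$metrics$accuracy - tr$metrics$accuracy), 0.05)
})
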