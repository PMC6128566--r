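test_that("a perfectly separable table cross-validates with zero error", {
  tab <- simulate_feature_table(seed = 81, n_pos = 40, n_neg = 30, q = 40,
                                n_informative = 10, delta = 4, rho = 0)
  cv <- cross_validate(tab$X, tab$y, folds = 5, repeats = 2, seed = 2,
                       top_n = 20, n_components = 5, relieff_k = 5)
  expect_equal(cv$summary$error, 0)
  expect_equal(cv$summary$sensitivity, 1)
  expect_equal(cv$summary$specificity, 1)
})

test_that("confusion identities hold exactly for every repeat", {
  tab <- simulate_feature_table(seed = 82, n_pos = 30, n_neg = 20, q = 30,
                                n_informative = 5, delta = 1, rho = 0)
  cv <- cross_validate(tab$X, tab$y, folds = 5, repeats = 3, seed = 4,
                       top_n = 15, n_components = 4, relieff_k = 4)
  per <- cv$per_repeat
  p <- nrow(tab$X)
  expect_equal(per$TP + per$FP + per$TN + per$FN, rep(p, 3))
  expect_equal(per$error, (per$FP + per$FN) / p)
  expect_equal(per$sensitivity, per$TP / (per$TP + per$FN))
  expect_equal(per$specificity, per$TN / (per$TN + per$FP))
  # stratified folds and fixed seed: bit-reproducible
  cv2 <- cross_validate(tab$X, tab$y, folds = 5, repeats = 3, seed = 4,
                        top_n = 15, n_components = 4, relieff_k = 4)
  expect_identical(cv$per_repeat, cv2$per_repeat)
  expect_error(cross_validate(tab$X, tab$y, folds = 99), "folds")
})

test_that("label-permuted null data gives chance-level error", {
  # balanced n = 100; the tolerance is three binomial standard errors of a
  # chance-level error rate at this sample size (3 * sqrt(0.25 / 100))
  tab <- simulate_feature_table(seed = 83, n_pos = 50, n_neg = 50, q = 100,
                                n_informative = 10, delta = 0)
  cv <- cross_validate(tab$X, tab$y, folds = 10, repeats = 5, seed = 5,
                       top_n = 30, n_components = 8)
  expect_lt(abs(cv$summary$error - 0.5), 0.15)
})

test_that("leave-one-out runs one fit per sample, none trained on it", {
  tab <- simulate_feature_table(seed = 84, n_pos = 16, n_neg = 14, q = 20,
                                n_informative = 5, delta = 2, rho = 0)
  p <- nrow(tab$X)
  calls <- 0L
  seen_test_rows <- TRUE
  real_fit <- dermwave_fit
  testthat::local_mocked_bindings(
    dermwave_fit = function(X, y, ...) {
      calls <<- calls + 1L
      if (nrow(X) != p - 1L) seen_test_rows <<- FALSE
      real_fit(X, y, ...)
    },
    .package = "dermwave")
  cv <- cross_validate(tab$X, tab$y, folds = p, seed = 6,
                       top_n = 10, n_components = 4, relieff_k = 4)
  expect_equal(calls, p)
  expect_true(seen_test_rows)
  expect_true(cv$loo)
  expect_equal(cv$repeats, 1L)
})

test_that("ROC curves behave at the extremes and match pROC in between", {
  y <- rep(c(0, 1), each = 50)
  expect_equal(roc_curve(y, y)$auc, 1)
  set.seed(85)
  pr <- runif(100)
  rc <- roc_curve(pr, y)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[length(rc$fpr)], 1)
  expect_equal(rc$tpr[length(rc$tpr)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  expect_equal(rc$auc,
               as.numeric(pROC::auc(pROC::roc(y, pr, quiet = TRUE))),
               tolerance = 1e-12)
  # reversing scores mirrors the area
  expect_equal(roc_curve(1 - pr, y)$auc, 1 - rc$auc, tolerance = 1e-12)
  expect_error(roc_curve(pr, rep(1, 100)), "both classes")
})

test_that("scores independent of labels give AUC one half", {
  set.seed(86)
  pr <- runif(10000)
  y <- rbinom(10000, 1, 0.5)
  expect_equal(roc_curve(pr, y)$auc, 0.5, tolerance = 0.02)
})

test_that("the diagnostic odds ratio follows its closed form", {
  expect_equal(diagnostic_odds_ratio(0.5, 0.5), 1)
  # closed form: 0.97 * 0.89 / (0.03 * 0.11)
  expect_equal(diagnostic_odds_ratio(0.97, 0.89), 261.60606060606,
               tolerance = 1e-10)
  dors <- vapply(seq(0.5, 0.95, by = 0.05), function(s)
    diagnostic_odds_ratio(0.9, s), 0)
  expect_true(all(diff(dors) > 0))
  expect_error(diagnostic_odds_ratio(1, 0.5), "strictly inside")
  expect_error(diagnostic_odds_ratio(0.9, 0), "strictly inside")
})

test_that("global selection is reported and differs from the clean protocol", {
  tab <- simulate_feature_table(seed = 87, n_pos = 30, n_neg = 25, q = 50,
                                n_informative = 5, delta = 0.8)
  clean <- cross_validate(tab$X, tab$y, folds = 5, seed = 8,
                          top_n = 15, n_components = 5, relieff_k = 5)
  leaky <- cross_validate(tab$X, tab$y, folds = 5, seed = 8,
                          top_n = 15, n_components = 5, relieff_k = 5,
                          global_selection = TRUE)
  expect_false(clean$global_selection)
  expect_true(leaky$global_selection)
  expect_output(print(leaky), "global selection")
})
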