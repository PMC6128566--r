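make_blobs <- function(n = 40, sep = 4, seed = 71) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n, -sep / 2), n / 2, 2),
             matrix(rnorm(n, sep / 2), n / 2, 2))
  list(X = X, y = rep(c(0, 1), each = n / 2))
}

test_that("a separable toy problem is fit perfectly by the RBF SVM", {
  b <- make_blobs()
  m <- train_svm(b$X, b$y, svm_config(C = 10, gamma = 0.5))
  pr <- predict_prob(m, b$X)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(mean((pr >= 0.5) == b$y), 1)
  expect_error(train_svm(b$X, rep(1, nrow(b$X))), "both classes")
})

test_that("increasing C weakly decreases the SVM training error", {
  set.seed(72)
  X <- rbind(matrix(rnorm(60, -0.6), 30, 2), matrix(rnorm(60, 0.6), 30, 2))
  y <- rep(c(0, 1), each = 30)
  errs <- vapply(c(0.1, 1, 10, 100, 1000), function(C) {
    m <- train_svm(X, y, svm_config(C = C, gamma = 0.5, tolerance = 1e-6))
    mean((predict(m$fit, X) == "excise") != y)
  }, 0)
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("the decision function depends only on the support vectors", {
  set.seed(73)
  X <- rbind(matrix(rnorm(60, -0.6), 30, 2), matrix(rnorm(60, 0.6), 30, 2))
  y <- rep(c(0, 1), each = 30)
  cfg <- svm_config(C = 1, gamma = 0.5, tolerance = 1e-9)
  m <- train_svm(X, y, cfg)
  non_sv <- setdiff(seq_len(60), m$fit$index)[1]
  m2 <- train_svm(X[-non_sv, ], y[-non_sv], cfg)
  d1 <- attr(predict(m$fit, X, decision.values = TRUE), "decision.values")
  d2 <- attr(predict(m2$fit, X, decision.values = TRUE), "decision.values")
  expect_equal(abs(as.vector(d1)), abs(as.vector(d2)), tolerance = 1e-6)
})

test_that("random-forest probabilities are vote fractions and reproducible", {
  b <- make_blobs(seed = 74)
  cfg <- rf_config(n_trees = 50, seed = 5)
  m <- train_rf(b$X, b$y, cfg)
  pr <- predict_prob(m, b$X)
  expect_true(all(abs(pr * 50 - round(pr * 50)) < 1e-9))
  m2 <- train_rf(b$X, b$y, cfg)
  expect_identical(pr, predict_prob(m2, b$X))
  # a single full-depth tree memorises a conflict-free training set
  m1 <- train_rf(b$X, b$y, rf_config(n_trees = 1, min_leaf_size = 1, seed = 6))
  expect_equal(mean((predict_prob(m1, b$X) >= 0.5) == b$y), 1)
})

test_that("random forest recovers planted structure out of bag", {
  tab <- simulate_feature_table(seed = 75, n_pos = 100, n_neg = 100, q = 50,
                                n_informative = 5, delta = 2, rho = 0)
  m <- train_rf(tab$X, tab$y, rf_config(n_trees = 100, seed = 7))
  oob <- m$fit$err.rate[m$fit$ntree, "OOB"]
  expect_lt(unname(oob), 0.1)
})

test_that("logistic regression behaves like its penalised-likelihood limits", {
  set.seed(76)
  # null data: probabilities near 0.5 and coefficients shrink with the penalty
  Xn <- matrix(rnorm(200 * 4), 200, 4)
  yn <- rep(c(0, 1), 100)
  m_null <- train_lr(Xn, yn, lr_config("L2", 0.5))
  expect_equal(mean(predict_prob(m_null, Xn)), 0.5, tolerance = 0.05)
  co_small <- as.vector(coef(train_lr(Xn, yn,
    lr_config("L2", 0.01))$fit))[-1]
  co_big <- as.vector(coef(train_lr(Xn, yn,
    lr_config("L2", 5))$fit))[-1]
  expect_lt(sum(abs(co_big)), sum(abs(co_small)) + 1e-12)
  # L1 with a strong penalty keeps only the informative coefficient
  Xs <- matrix(rnorm(200 * 5), 200, 5)
  ys <- as.integer(Xs[, 3] + rnorm(200, sd = 0.3) > 0)
  m_l1 <- train_lr(Xs, ys, lr_config("L1", 0.1))
  co <- as.vector(coef(m_l1$fit))[-1]
  expect_gt(abs(co[3]), 0)
  expect_equal(co[-3], rep(0, 4), tolerance = 1e-10)
  # probability is monotone in the linear score
  sc <- predict_prob(m_l1, Xs)
  lin <- as.vector(cbind(Xs) %*% co)
  expect_true(all(diff(sc[order(lin)]) >= -1e-12))
})

test_that("decisions at the threshold boundary favour excision", {
  b <- make_blobs(seed = 77)
  m <- train_svm(b$X, b$y, svm_config(C = 10, gamma = 0.5))
  pr <- predict_prob(m, b$X)
  res <- classify_lesions(m, b$X, threshold = pr[1])
  expect_equal(res$decision[1], 1L)
  expect_equal(res$label[1], "excise")
  # threshold 1: flagged only at probability exactly 1
  res1 <- classify_lesions(m, b$X, threshold = 1 - 1e-12)
  expect_true(all(res1$decision[res1$probability < 1 - 1e-12] == 0L))
  expect_error(predict_prob(m, b$X[, 1, drop = FALSE]), "mismatch")
})

test_that("the fitted pipeline object predicts, prints and serialises", {
  tab <- simulate_feature_table(seed = 78, n_pos = 40, n_neg = 30, q = 80,
                                n_informative = 10, delta = 2)
  fit <- dermwave_fit(tab$X, tab$y, top_n = 30, n_components = 8)
  expect_s3_class(fit, "dermwave_fit")
  expect_output(print(fit), "ReliefF top 30")
  expect_output(summary(fit), "variance retained")
  res <- predict(fit, tab$X)
  expect_named(res, c("probability", "decision", "label"))
  expect_equal(predict(fit, tab$X, type = "class"),
               as.integer(res$probability >= 0.5))
  # one-lesion case: a bare feature vector
  one <- predict(fit, tab$X[1, ], type = "prob")
  expect_equal(one, res$probability[1], tolerance = 1e-12)
  # round trip through the bundle: identical probabilities
  path <- withr::local_tempfile(fileext = ".bundle")
  save_bundle(fit, path)
  fit2 <- load_bundle(path)
  expect_equal(predict(fit2, tab$X, type = "prob"), res$probability,
               tolerance = 1e-12)
  expect_error(predict(fit, tab$X[, 1:10]), "mismatch")
})
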