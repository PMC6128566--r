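test_that("ReliefF matches the exhaustive hand-rollout oracle", {
  set.seed(51)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rep(c(0, 1), 15)
  X[, 3] <- y + rnorm(30, sd = 0.1)
  r <- relieff_rank(X, y, k_neighbors = 4)
  expect_equal(r$weights, oracle_relieff(X, y, 4), tolerance = 1e-12)
  expect_equal(r$order, order(-r$weights, seq_along(r$weights)))
})

test_that("a feature equal to the label ranks first with weight near one", {
  set.seed(52)
  p <- 100
  X <- matrix(rnorm(p * 100), p, 100)
  y <- rep(c(0, 1), each = 50)
  X[, 1] <- y                    # feature 0 of the planted design
  r <- relieff_rank(X, y, k_neighbors = 10)
  expect_equal(r$order[1], 1)
  expect_gt(r$weights[1], 0.9)
  expect_true(all(r$weights >= -1 & r$weights <= 1))
})

test_that("constant features get weight exactly zero", {
  set.seed(53)
  X <- matrix(rnorm(40 * 5), 40, 5)
  X[, 2] <- 7
  y <- rep(c(0, 1), each = 20)
  r <- relieff_rank(X, y, k_neighbors = 5)
  expect_identical(r$weights[2], 0)
})

test_that("duplicating every sample preserves the informative ranking", {
  set.seed(54)
  X <- matrix(rnorm(30 * 12), 30, 12)
  y <- rep(c(0, 1), each = 15)
  X[, 1:3] <- X[, 1:3] + 3 * y
  r1 <- relieff_rank(X, y, k_neighbors = 5)
  r2 <- relieff_rank(rbind(X, X), c(y, y), k_neighbors = 5)
  # exact weight equality is not expected (each point's duplicate enters its
  # hit list at distance zero), but the informative features stay on top
  expect_setequal(r1$order[1:3], 1:3)
  expect_setequal(r2$order[1:3], 1:3)
})

test_that("weights are invariant to affine rescaling of one feature", {
  set.seed(55)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c(0, 1), each = 20)
  X[, 4] <- X[, 4] + y
  r1 <- relieff_rank(X, y, k_neighbors = 6)
  X2 <- X
  X2[, 4] <- 1000 * X[, 4] - 37
  r2 <- relieff_rank(X2, y, k_neighbors = 6)
  expect_equal(r1$weights, r2$weights, tolerance = 1e-9)
})

test_that("class-size guards fire", {
  X <- matrix(rnorm(12 * 4), 12, 4)
  expect_error(relieff_rank(X, rep(c(0, 1), each = 6), k_neighbors = 10),
               "more than")
  expect_error(relieff_rank(X, rep(0, 12), k_neighbors = 2), "two classes")
})

test_that("the performance sweep plateaus at the planted feature count", {
  tab <- simulate_feature_table(seed = 56, n_pos = 60, n_neg = 40, q = 60,
                                n_informative = 5, delta = 2.5, rho = 0)
  r <- relieff_rank(tab$X, tab$y, k_neighbors = 8)
  sw <- sweep_feature_count(tab$X, tab$y, r,
                            n_values = c(1, 3, 5, 10, 20, 40, 60),
                            folds = 5, seed = 7,
                            config = svm_config(C = 10, gamma = 0.05))
  expect_s3_class(sw, "feature_sweep")
  expect_equal(nrow(sw), 7)
  perf_at_5 <- sw$performance[sw$n == 5]
  # noise features beyond the plateau must not add information
  expect_lte(max(sw$performance[sw$n > 5]) - perf_at_5, 0.02)
  expect_lte(attr(sw, "plateau_n"), 10)
  expect_error(sweep_feature_count(tab$X, tab$y, r, integer(0)), "non-empty")
})

test_that("using all ranked features reproduces the all-feature CV result", {
  tab <- simulate_feature_table(seed = 57, n_pos = 30, n_neg = 30, q = 20,
                                n_informative = 4, delta = 1.5, rho = 0)
  r <- relieff_rank(tab$X, tab$y, k_neighbors = 5)
  sw <- sweep_feature_count(tab$X, tab$y, r, n_values = 20, folds = 5,
                            seed = 3, config = svm_config(C = 5, gamma = 0.05))
  cv <- cross_validate(tab$X, tab$y, folds = 5, seed = 3,
                       config = svm_config(C = 5, gamma = 0.05),
                       top_n = NULL, n_components = NULL)
  expect_equal(sw$sensitivity[1], cv$summary$sensitivity, tolerance = 1e-12)
  expect_equal(sw$specificity[1], cv$summary$specificity, tolerance = 1e-12)
})
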