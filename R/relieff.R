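#' ReliefF feature ranking
#'
#' Standard ReliefF (Kononenko) for a two-class feature table: every instance
#' is visited exhaustively (making the ranking deterministic); for each, the
#' `k` nearest same-class "hits" and `k` nearest other-class "misses" are
#' found by Manhattan distance on range-normalised features, and each feature
#' weight is decreased by the mean hit difference and increased by the mean
#' miss difference. Weights lie in `[-1, 1]`; a feature constant across all
#' samples has zero range and weight exactly 0.
#'
#' @param X numeric p x q matrix (rows = lesions).
#' @param y binary labels (1 = excise, 0 = no excise), length p.
#' @param k_neighbors neighbours per class, default 10; each class must have
#'   more than `k_neighbors` members.
#' @return An object of class `relieff_ranking`: list with `order` (feature
#'   indices sorted by non-increasing weight, ties broken by ascending index)
#'   and `weights` (length q).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 20, 10)
#' y <- rep(c(0, 1), each = 10)
#' X[, 1] <- y + rnorm(20, sd = 0.05)
#' relieff_rank(X, y, k_neighbors = 3)$order[1]
#' @export
relieff_rank <- function(X, y, k_neighbors = 10L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  p <- nrow(X); q <- ncol(X)
  if (length(y) != p) stop("length(y) must equal nrow(X)")
  if (anyNA(X)) stop("missing values are not supported")
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("exactly two classes are required")
  k <- as.integer(k_neighbors)
  counts <- table(y)
  if (any(counts <= k))
    stop("each class must have more than k_neighbors members")
  rng <- apply(X, 2, max) - apply(X, 2, min)
  active <- rng > 0
  Xn <- X[, active, drop = FALSE]
  Xn <- sweep(Xn, 2, apply(Xn, 2, min), "-")
  Xn <- sweep(Xn, 2, rng[active], "/")
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  w <- numeric(sum(active))
  for (i in seq_len(p)) {
    d <- D[i, ]
    same <- which(y == y[i]); same <- same[same != i]
    other <- which(y != y[i])
    hits <- same[order(d[same])][seq_len(k)]
    misses <- other[order(d[other])][seq_len(k)]
    dh <- abs(Xn[hits, , drop = FALSE] -
                matrix(Xn[i, ], k, ncol(Xn), byrow = TRUE))
    dm <- abs(Xn[misses, , drop = FALSE] -
                matrix(Xn[i, ], k, ncol(Xn), byrow = TRUE))
    w <- w + (colMeans(dm) - colMeans(dh)) / p
  }
  weights <- numeric(q)
  weights[active] <- pmin(1, pmax(-1, w))  # guard against float overshoot
  ord <- order(-weights, seq_len(q))
  out <- list(order = ord, weights = weights, k_neighbors = k)
  class(out) <- "relieff_ranking"
  out
}

#' @export
print.relieff_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("ReliefF ranking of %d features (k = %d)\n",
              length(x$weights), x$k_neighbors))
  top <- utils::head(x$order, n)
  cat("Top features:\n")
  print(data.frame(feature = top, weight = signif(x$weights[top], 4)),
        row.names = FALSE)
  invisible(x)
}

#' Performance versus cumulative feature count
#'
#' Sweeps the number of top-ranked features used by a cross-validated
#' classifier and records sensitivity, specificity and their mean (the
#' performance measure) per feature count, locating the plateau: the smallest
#' count whose performance is within `plateau_tol` of the sweep maximum. This
#' is the curve used to find the ~125-feature plateau on full-scale tables.
#'
#' @param X p x q feature matrix.
#' @param y binary labels (1 = excise).
#' @param ranked a [relieff_rank()] result for (`X`, `y`).
#' @param n_values increasing integer vector of feature counts to evaluate.
#' @param folds cross-validation folds, default 10.
#' @param repeats CV repeats per count, default 1.
#' @param seed RNG seed for fold assignment.
#' @param classifier,config classifier applied to the selected features
#'   (default an RBF SVM via [svm_config()]); no PCA step is applied in the
#'   sweep, matching its use to choose the native feature count.
#' @param plateau_tol tolerance for plateau detection, default 0.005.
#' @return A data.frame of class `feature_sweep` with columns `n`,
#'   `sensitivity`, `specificity`, `performance`, and attributes `plateau_n`
#'   and `best_n`.
#' @export
sweep_feature_count <- function(X, y, ranked, n_values, folds = 10L,
                                repeats = 1L, seed = 1L,
                                classifier = "svm", config = svm_config(),
                                plateau_tol = 0.005) {
  X <- as.matrix(X)
  n_values <- as.integer(n_values)
  if (length(n_values) == 0L) stop("n_values must be non-empty")
  if (max(n_values) > ncol(X)) stop("n_values exceed the feature count")
  res <- lapply(n_values, function(n) {
    idx <- ranked$order[seq_len(n)]
    cv <- cross_validate(X[, idx, drop = FALSE], y, folds = folds,
                         repeats = repeats, seed = seed,
                         classifier = classifier, config = config,
                         top_n = NULL, n_components = NULL)
    c(sensitivity = cv$summary$sensitivity,
      specificity = cv$summary$specificity)
  })
  res <- do.call(rbind, res)
  out <- data.frame(n = n_values,
                    sensitivity = res[, "sensitivity"],
                    specificity = res[, "specificity"])
  out$performance <- (out$sensitivity + out$specificity) / 2
  best <- max(out$performance)
  attr(out, "best_n") <- out$n[which.max(out$performance)]
  attr(out, "plateau_n") <- min(out$n[out$performance >= best - plateau_tol])
  class(out) <- c("feature_sweep", "data.frame")
  out
}
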