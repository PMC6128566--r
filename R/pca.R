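#' Fit PCA by singular value decomposition of standardised training data
#'
#' Columns are standardised to zero mean and unit variance using the training
#' data's mean and (sample, n-1 denominator) standard deviation; the SVD
#' `X = W D V'` of the standardised matrix is computed, and the loading matrix
#' `V` (eigenvectors of `X'X`) together with the singular values is stored.
#' The training principal components are `PC_train = X V`. The variance of
#' the i-th component equals `d_i^2 / (p - 1)`.
#'
#' Constant columns carry no information and cannot be standardised; by
#' default they are dropped with a warning (`strict = TRUE` turns this into an
#' error). Each column of `V` is sign-fixed so its largest-magnitude entry is
#' positive, making results deterministic across platforms.
#'
#' @param X numeric p x q training matrix, p >= 2.
#' @param strict error (rather than warn-and-drop) on constant columns.
#' @return An object of class `dermwave_pca`: `train_mean`, `train_sd`
#'   (length q' after dropping), `V` (q' x r loading matrix, r = min(p-1
#'   limited rank, q')), `singular_values`, `n_train`, `kept` (indices of
#'   retained columns of the input).
#' @seealso [pca_transform()], [eigenvalue_curve()]
#' @export
fit_pca <- function(X, strict = FALSE) {
  X <- as.matrix(X)
  p <- nrow(X); q <- ncol(X)
  if (p < 2L) stop("at least two training rows are required")
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  constant <- sd == 0
  if (any(constant)) {
    if (strict) stop("constant column(s): ",
                     paste(which(constant), collapse = ", "))
    warning("dropping ", sum(constant), " constant column(s)")
  }
  kept <- which(!constant)
  Xs <- sweep(sweep(X[, kept, drop = FALSE], 2, mu[kept], "-"),
              2, sd[kept], "/")
  sv <- svd(Xs)
  V <- sv$v
  # deterministic sign convention: largest-magnitude entry of each loading > 0
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  out <- list(train_mean = mu[kept], train_sd = sd[kept], V = V,
              singular_values = sv$d, n_train = p, q = length(kept),
              kept = kept)
  class(out) <- "dermwave_pca"
  out
}

#' Transform data into the training principal-component space
#'
#' Standardises `Y` with the *training* mean and standard deviation (never
#' refitting on test data), multiplies by the training loading matrix `V` and
#' keeps the first `n_components` columns. A single lesion is the one-row
#' case.
#'
#' @param model a [fit_pca()] result.
#' @param Y r x q matrix (or a length-q vector, treated as one row) with the
#'   same columns as the training data.
#' @param n_components number of leading components to keep; defaults to all
#'   available.
#' @return r x n_components matrix of principal-component scores.
#' @export
pca_transform <- function(model, Y, n_components = NULL) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  Y <- as.matrix(Y)
  # accept either the reduced column count or the original one (the same
  # constant columns as in training are then dropped)
  if (ncol(Y) != model$q) {
    if (ncol(Y) >= max(model$kept)) {
      Y <- Y[, model$kept, drop = FALSE]
    } else {
      stop("column-count mismatch: expected ", model$q, " got ", ncol(Y))
    }
  }
  r <- ncol(model$V)
  if (is.null(n_components)) n_components <- r
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > r)
    stop("n_components must be in 1..", r)
  Ys <- sweep(sweep(Y, 2, model$train_mean, "-"), 2, model$train_sd, "/")
  Ys %*% model$V[, seq_len(n_components), drop = FALSE]
}

#' @export
predict.dermwave_pca <- function(object, newdata, n_components = NULL, ...) {
  pca_transform(object, newdata, n_components)
}

#' Eigenvalues of the training covariance matrix
#'
#' Returns `d_i^2 / (p - 1)`, the non-increasing eigenvalues of the
#' covariance matrix of the standardised training data, padded with zeros up
#' to the feature count for rank-deficient tables. Their decay guides the
#' choice of the number of components (the curve flattens around 25 on
#' full-scale tables, supporting the 22-component operating point).
#'
#' @param model a [fit_pca()] result.
#' @return Non-negative, non-increasing numeric vector of length q.
#' @export
eigenvalue_curve <- function(model) {
  ev <- model$singular_values^2 / (model$n_train - 1)
  if (length(ev) < model$q) ev <- c(ev, numeric(model$q - length(ev)))
  ev[seq_len(model$q)]
}

#' @export
print.dermwave_pca <- function(x, ...) {
  ev <- eigenvalue_curve(x)
  cat(sprintf("PCA model: %d features, %d training rows\n", x$q, x$n_train))
  cat(sprintf("  leading eigenvalues: %s\n",
              paste(signif(utils::head(ev, 5), 4), collapse = " ")))
  cat(sprintf("  variance in first 22 components: %.1f%%\n",
              100 * sum(ev[seq_len(min(22, length(ev)))]) / sum(ev)))
  invisible(x)
}
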