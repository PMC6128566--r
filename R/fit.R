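#' Fit the full lesion decision-support pipeline
#'
#' The umbrella fitting function: ReliefF-ranks the features of a training
#' table, keeps the top `top_n`, fits PCA on them (training
#' mean/sd + SVD), projects onto the leading `n_components` principal
#' components and trains the classifier on the scores. The defaults —
#' top 125 ReliefF features, 22 principal components, an RBF SVM with
#' `C = 30`, `gamma = 0.007` and a 0.5 probability cut-off — are the
#' pipeline's canonical operating point.
#'
#' Setting `top_n = NULL` skips the ReliefF selection stage (all features are
#' used) and `n_components = NULL` skips PCA (the classifier sees the native
#' features); both stages cap their size at what the table supports.
#'
#' @param X p x q numeric feature matrix (rows = lesions; q = 1152 for the
#'   canonical wavelet feature bank).
#' @param y binary labels (1 = excise, 0 = no excise).
#' @param classifier `"svm"`, `"rf"` or `"lr"`.
#' @param config classifier configuration ([svm_config()], [rf_config()] or
#'   [lr_config()]); defaults to the classifier's default configuration.
#' @param top_n number of top-ranked native features kept (default 125).
#' @param n_components number of principal components (default 22).
#' @param relieff_k ReliefF neighbours per class (default 10).
#' @param seed seed for the stochastic parts of training.
#' @return An object of class `dermwave_fit` with `print`, `summary`,
#'   `predict` and `plot` methods.
#' @examples
#' tab <- simulate_feature_table(seed = 1, n_pos = 30, n_neg = 20, q = 60,
#'                               n_informative = 8)
#' fit <- dermwave_fit(tab$X, tab$y, top_n = 20, n_components = 5,
#'                     relieff_k = 5)
#' predict(fit, tab$X[1:3, ])
#' @export
dermwave_fit <- function(X, y, classifier = c("svm", "rf", "lr"),
                         config = NULL, top_n = 125L, n_components = 22L,
                         relieff_k = 10L, seed = 1L) {
  classifier <- match.arg(classifier)
  if (is.null(config))
    config <- switch(classifier, svm = svm_config(), rf = rf_config(),
                     lr = lr_config())
  X <- as.matrix(X)
  y <- as.integer(y > 0)
  q <- ncol(X)
  ranking <- NULL
  if (!is.null(top_n)) {
    top_n <- min(as.integer(top_n), q)
    ranking <- relieff_rank(X, y, k_neighbors = relieff_k)
    top_idx <- ranking$order[seq_len(top_n)]
  } else {
    top_idx <- seq_len(q)
  }
  Xt <- X[, top_idx, drop = FALSE]
  pca <- NULL
  if (!is.null(n_components)) {
    pca <- fit_pca(Xt)
    n_components <- min(as.integer(n_components), ncol(pca$V))
    Z <- pca_transform(pca, Xt, n_components)
  } else {
    Z <- Xt
  }
  clf <- switch(classifier,
                svm = train_svm(Z, y, config, seed = seed),
                rf = train_rf(Z, y, config, seed = seed),
                lr = train_lr(Z, y, config, seed = seed))
  out <- list(classifier = classifier, config = config,
              ranking = ranking, top_idx = top_idx,
              pca = pca, n_components = n_components,
              clf = clf, q = q, n_train = nrow(X),
              class_counts = c(noexcise = sum(y == 0), excise = sum(y == 1)),
              seed = seed, call = match.call())
  class(out) <- "dermwave_fit"
  out
}

.chain_scores <- function(object, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$q)
    stop("column-count mismatch: expected ", object$q, " got ", ncol(newdata))
  Z <- newdata[, object$top_idx, drop = FALSE]
  if (!is.null(object$pca))
    Z <- pca_transform(object$pca, Z, object$n_components)
  Z
}

#' Predict excision probability and decision for new lesions
#'
#' Applies the identical preprocessing chain fitted at training time (top
#' ranked features, training-statistics PCA projection) and returns the
#' classifier's probability of the excise class and the thresholded decision.
#'
#' @param object a [dermwave_fit()] model.
#' @param newdata r x q matrix (or length-q vector) of feature rows.
#' @param type `"response"` (data.frame of probability + decision),
#'   `"prob"` (probabilities only) or `"class"` (0/1 decisions only).
#' @param threshold decision cut-off; defaults to the fitted configuration's.
#' @param ... unused.
#' @export
predict.dermwave_fit <- function(object, newdata,
                                 type = c("response", "prob", "class"),
                                 threshold = object$config$probability_threshold,
                                 ...) {
  type <- match.arg(type)
  Z <- .chain_scores(object, newdata)
  p <- predict_prob(object$clf, Z)
  if (type == "prob") return(p)
  dec <- as.integer(p >= threshold)
  if (type == "class") return(dec)
  data.frame(probability = p, decision = dec,
             label = ifelse(dec == 1L, "excise", "do not excise"))
}

#' @export
print.dermwave_fit <- function(x, ...) {
  cat("dermwave pipeline fit\n")
  cat(sprintf("  training: %d lesions (%d excise / %d no-excise), %d features\n",
              x$n_train, x$class_counts["excise"],
              x$class_counts["noexcise"], x$q))
  cat(sprintf("  chain: %s -> %s -> %s classifier\n",
              if (is.null(x$ranking)) "all features"
              else sprintf("ReliefF top %d", length(x$top_idx)),
              if (is.null(x$pca)) "no PCA"
              else sprintf("%d principal components", x$n_components),
              toupper(x$classifier)))
  invisible(x)
}

#' @export
summary.dermwave_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$pca)) {
    ev <- eigenvalue_curve(object$pca)
    kept <- sum(ev[seq_len(object$n_components)]) / sum(ev)
    cat(sprintf("  variance retained by %d components: %.1f%%\n",
                object$n_components, 100 * kept))
  }
  if (!is.null(object$ranking)) {
    top <- utils::head(object$ranking$order, 5)
    cat("  top-ranked features:",
        paste(sprintf("%d (w=%.3f)", top, object$ranking$weights[top]),
              collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
plot.dermwave_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (!is.null(x$ranking)) {
    w <- sort(x$ranking$weights, decreasing = TRUE)
    graphics::plot(w, type = "l", xlab = "feature rank",
                   ylab = "ReliefF weight", main = "Feature ranking", ...)
    graphics::abline(v = length(x$top_idx), lty = 2)
  }
  if (!is.null(x$pca)) {
    ev <- eigenvalue_curve(x$pca)
    graphics::plot(ev, type = "b", pch = 20, xlab = "component",
                   ylab = "eigenvalue", main = "Eigenvalue curve", ...)
    graphics::abline(v = x$n_components, lty = 2)
  }
  invisible(x)
}
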