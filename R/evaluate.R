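.make_folds <- function(y, folds, stratify, rng_ok = 100L) {
  p <- length(y)
  for (attempt in seq_len(rng_ok)) {
    assign <- integer(p)
    if (stratify) {
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        assign[idx] <- rep(seq_len(folds), length.out = length(idx))
      }
    } else {
      assign <- sample(rep(seq_len(folds), length.out = p))
    }
    ok <- all(vapply(seq_len(folds), function(f)
      length(unique(y[assign != f])) == 2L, TRUE))
    if (ok) return(assign)
    warning("fold with a single training class; refolding")
  }
  stop("could not build valid folds")
}

#' Repeated stratified k-fold / leave-one-out cross-validation
#'
#' Cross-validates the full decision-support pipeline with every
#' preprocessing stage — ReliefF ranking and the PCA projection — refit
#' inside each training fold, so no information from held-out lesions leaks
#' into feature selection or extraction. Folds are stratified by default
#' (class ratios preserved; the 165/85 imbalance otherwise destabilises
#' specificity). Leave-one-out is requested with `folds = nrow(X)`; it is
#' deterministic in fold structure, runs once, and its sensitivity and
#' specificity are pooled over the held-out predictions.
#'
#' `global_selection = TRUE` reproduces the optimistic variant in which
#' ReliefF and PCA are fit once on the full table before cross-validation;
#' only the classifier is then refit per fold.
#'
#' @param X p x q feature matrix.
#' @param y binary labels (1 = excise).
#' @param folds number of folds (2..p); `p` means leave-one-out.
#' @param repeats number of repetitions with fresh fold assignments
#'   (ignored for leave-one-out).
#' @param seed seed controlling fold assignment and classifier training.
#' @param classifier,config,top_n,n_components,relieff_k passed to
#'   [dermwave_fit()] for every training fold.
#' @param stratify preserve class ratios across folds (default TRUE).
#' @param global_selection fit ReliefF + PCA once on all data (leaky
#'   variant), default FALSE.
#' @param threshold decision cut-off applied to the held-out probabilities.
#' @return An object of class `dermwave_cv`: `per_repeat` data.frame (error,
#'   sensitivity, specificity, TP/FP/TN/FN per repeat), `summary` (means),
#'   `predictions` (pooled held-out probability and label per repeat),
#'   plus the call parameters.
#' @export
cross_validate <- function(X, y, folds = 10L, repeats = 1L, seed = 1L,
                           classifier = "svm", config = NULL,
                           top_n = 125L, n_components = 22L, relieff_k = 10L,
                           stratify = TRUE, global_selection = FALSE,
                           threshold = 0.5) {
  X <- as.matrix(X)
  y <- as.integer(y > 0)
  p <- nrow(X)
  folds <- as.integer(folds)
  if (folds < 2L || folds > p) stop("folds must be in 2..nrow(X)")
  loo <- folds == p
  if (loo) repeats <- 1L
  set.seed(seed)
  global_fit <- NULL
  if (global_selection) {
    ranking <- if (is.null(top_n)) NULL else relieff_rank(X, y, relieff_k)
    g_idx <- if (is.null(top_n)) seq_len(ncol(X))
             else ranking$order[seq_len(min(top_n, ncol(X)))]
    g_pca <- if (is.null(n_components)) NULL else fit_pca(X[, g_idx, drop = FALSE])
    global_fit <- list(idx = g_idx, pca = g_pca)
  }
  per <- vector("list", repeats)
  preds <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    assign <- if (loo) seq_len(p)
              else .make_folds(y, folds, stratify)
    prob <- numeric(p)
    for (f in seq_len(folds)) {
      tr <- which(assign != f); te <- which(assign == f)
      if (length(te) == 0L) next
      if (global_selection) {
        Ztr <- X[tr, global_fit$idx, drop = FALSE]
        Zte <- X[te, global_fit$idx, drop = FALSE]
        if (!is.null(global_fit$pca)) {
          nc <- min(n_components, ncol(global_fit$pca$V))
          Ztr <- pca_transform(global_fit$pca, Ztr, nc)
          Zte <- pca_transform(global_fit$pca, Zte, nc)
        }
        cfg <- if (is.null(config))
          switch(classifier, svm = svm_config(), rf = rf_config(),
                 lr = lr_config()) else config
        clf <- switch(classifier,
                      svm = train_svm(Ztr, y[tr], cfg, seed = seed + r),
                      rf = train_rf(Ztr, y[tr], cfg, seed = seed + r),
                      lr = train_lr(Ztr, y[tr], cfg, seed = seed + r))
        prob[te] <- predict_prob(clf, Zte)
      } else {
        fit <- dermwave_fit(X[tr, , drop = FALSE], y[tr],
                            classifier = classifier, config = config,
                            top_n = top_n, n_components = n_components,
                            relieff_k = relieff_k, seed = seed + r)
        prob[te] <- predict(fit, X[te, , drop = FALSE], type = "prob")
      }
    }
    dec <- as.integer(prob >= threshold)
    TP <- sum(dec == 1L & y == 1L); FP <- sum(dec == 1L & y == 0L)
    TN <- sum(dec == 0L & y == 0L); FN <- sum(dec == 0L & y == 1L)
    per[[r]] <- data.frame(
      repeat_id = r, error = (FP + FN) / p,
      sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
      TP = TP, FP = FP, TN = TN, FN = FN)
    preds[[r]] <- data.frame(repeat_id = r, probability = prob, label = y)
  }
  per <- do.call(rbind, per)
  out <- list(
    per_repeat = per,
    summary = list(error = mean(per$error),
                   sensitivity = mean(per$sensitivity),
                   specificity = mean(per$specificity)),
    predictions = do.call(rbind, preds),
    folds = folds, repeats = repeats, seed = seed, loo = loo,
    classifier = classifier, stratify = stratify,
    global_selection = global_selection, threshold = threshold)
  class(out) <- "dermwave_cv"
  out
}

#' @export
print.dermwave_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation (%s), %d repeat(s), seed %d\n",
              if (x$loo) "Leave-one-out" else paste0(x$folds, "-fold"),
              toupper(x$classifier), x$repeats, x$seed))
  if (x$global_selection)
    cat("  [global selection: ReliefF/PCA fit outside the folds]\n")
  cat(sprintf("  mean error %.3f | sensitivity %.3f | specificity %.3f\n",
              x$summary$error, x$summary$sensitivity, x$summary$specificity))
  invisible(x)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique predicted probabilities and
#' records (false-positive rate, true-positive rate) pairs, from (0, 0) to
#' (1, 1), with the trapezoidal area under the curve.
#'
#' @param probabilities predicted `P(excise)`.
#' @param labels binary labels (1 = excise); both classes must be present.
#' @return An object of class `dermwave_roc`: data.frame-like list with
#'   `fpr`, `tpr`, `threshold` and scalar `auc`.
#' @export
roc_curve <- function(probabilities, labels) {
  labels <- as.integer(labels > 0)
  if (length(unique(labels)) < 2L)
    stop("invalid input: both classes must be present")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  ord <- order(probabilities, decreasing = TRUE)
  pr <- probabilities[ord]; lab <- labels[ord]
  last <- c(pr[-1] != pr[-length(pr)], TRUE)  # last index of each threshold
  tpr <- c(0, cumsum(lab)[last] / np)
  fpr <- c(0, cumsum(1L - lab)[last] / nn)
  th <- c(Inf, pr[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out <- list(fpr = fpr, tpr = tpr, threshold = th, auc = auc)
  class(out) <- "dermwave_roc"
  out
}

#' @export
print.dermwave_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.dermwave_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Diagnostic odds ratio
#'
#' `DOR = (sens * spec) / ((1 - sens) * (1 - spec))`, the single-number
#' summary of a binary diagnostic test; 1 is uninformative. At the ROC
#' operating point sensitivity 0.97 / specificity 0.89 the value is 261.6.
#'
#' @param sensitivity,specificity values strictly inside (0, 1).
#' @return The scalar DOR.
#' @examples
#' diagnostic_odds_ratio(0.97, 0.89)
#' @export
diagnostic_odds_ratio <- function(sensitivity, specificity) {
  if (any(sensitivity <= 0 | sensitivity >= 1 |
          specificity <= 0 | specificity >= 1))
    stop("sensitivity and specificity must be strictly inside (0, 1); ",
         "boundary values give an infinite or undefined DOR")
  (sensitivity * specificity) / ((1 - sensitivity) * (1 - specificity))
}
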