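#' Classifier configurations
#'
#' `svm_config()` parametrises the soft-margin SVM with Gaussian RBF kernel
#' `K(x, x') = exp(-gamma * ||x - x'||^2)` (`gamma = 1/sigma` in the kernel's
#' scale form). `C` trades margin width against classification error. The
#' defaults, `C = 30` and `gamma = 0.007`, are the operating point of the
#' full pipeline; decisions use `P(excise) >= probability_threshold` with the
#' tie at the threshold mapped to "excise" (conservative toward excision).
#'
#' @param C positive margin/error trade-off, default 30.
#' @param gamma positive RBF kernel scale, default 0.007.
#' @param probability_threshold decision cut-off in (0, 1), default 0.5.
#' @param tolerance termination tolerance of the quadratic-programming
#'   solver, default 0.001.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(C = 30, gamma = 0.007, probability_threshold = 0.5,
                       tolerance = 0.001) {
  stopifnot(C > 0, gamma > 0, tolerance > 0,
            probability_threshold > 0, probability_threshold < 1)
  structure(list(C = C, gamma = gamma,
                 probability_threshold = probability_threshold,
                 tolerance = tolerance),
            class = "svm_config")
}

#' @rdname svm_config
#' @param n_trees number of trees, default 200.
#' @param min_leaf_size minimum terminal-node size, default 1.
#' @param seed RNG seed for the forest.
#' @export
rf_config <- function(n_trees = 200L, min_leaf_size = 1L, seed = 1L,
                      probability_threshold = 0.5) {
  stopifnot(n_trees >= 1, min_leaf_size >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 min_leaf_size = as.integer(min_leaf_size),
                 seed = as.integer(seed),
                 probability_threshold = probability_threshold),
            class = "rf_config")
}

#' @rdname svm_config
#' @param penalty `"L1"` or `"L2"`.
#' @param reg_param positive penalty strength (lambda multiplying the penalty
#'   term).
#' @export
lr_config <- function(penalty = c("L2", "L1"), reg_param = 0.1,
                      probability_threshold = 0.5) {
  penalty <- match.arg(penalty)
  stopifnot(reg_param > 0)
  structure(list(penalty = penalty, reg_param = reg_param,
                 probability_threshold = probability_threshold),
            class = "lr_config")
}

.check_xy <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y > 0)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (length(unique(y)) < 2L)
    stop("invalid input: both classes must be present")
  list(X = X, y = y)
}

.ylevels <- c("noexcise", "excise")

#' Train a classifier on a feature (or principal-component) matrix
#'
#' `train_svm()` fits a soft-margin RBF-kernel SVM with Platt-scaled
#' probability output (sigmoid calibration fitted by internal cross-validation
#' with a fixed seed); `train_rf()` a random forest (bagged CART trees,
#' class-vote probabilities); `train_lr()` a penalised logistic regression
#' (L1 or L2). Inputs are not rescaled: principal components are used as-is.
#' The excise class is the positive class throughout.
#'
#' @param X n x d numeric matrix.
#' @param y binary labels (1 = excise, 0 = no excise).
#' @param config an [svm_config()], [rf_config()] or [lr_config()].
#' @param seed seed for the stochastic parts (Platt calibration folds, forest
#'   bootstrap).
#' @return An object of class `dermwave_clf` with fields `algorithm`, `fit`,
#'   `config`, usable with [predict_prob()] and [classify_lesions()].
#' @export
train_svm <- function(X, y, config = svm_config(), seed = 1L) {
  d <- .check_xy(X, y)
  fy <- factor(.ylevels[d$y + 1L], levels = .ylevels)
  set.seed(seed)
  fit <- e1071::svm(x = d$X, y = fy, type = "C-classification",
                    kernel = "radial", cost = config$C, gamma = config$gamma,
                    tolerance = config$tolerance,
                    probability = TRUE, scale = FALSE)
  structure(list(algorithm = "svm", fit = fit, config = config, d = ncol(d$X)),
            class = "dermwave_clf")
}

#' @rdname train_svm
#' @export
train_rf <- function(X, y, config = rf_config(), seed = config$seed) {
  d <- .check_xy(X, y)
  fy <- factor(.ylevels[d$y + 1L], levels = .ylevels)
  set.seed(seed)
  fit <- randomForest::randomForest(x = d$X, y = fy,
                                    ntree = config$n_trees,
                                    nodesize = config$min_leaf_size)
  structure(list(algorithm = "rf", fit = fit, config = config, d = ncol(d$X)),
            class = "dermwave_clf")
}

#' @rdname train_svm
#' @export
train_lr <- function(X, y, config = lr_config(), seed = 1L) {
  d <- .check_xy(X, y)
  Xg <- d$X
  if (ncol(Xg) < 2L) Xg <- cbind(Xg, `.dummy` = 0)  # glmnet needs >= 2 columns
  alpha <- if (config$penalty == "L1") 1 else 0
  fit <- glmnet::glmnet(Xg, d$y, family = "binomial", alpha = alpha,
                        lambda = config$reg_param, standardize = FALSE)
  structure(list(algorithm = "lr", fit = fit, config = config, d = ncol(d$X)),
            class = "dermwave_clf")
}

#' Predicted probability of the excise class
#'
#' @param model a `dermwave_clf` from [train_svm()], [train_rf()] or
#'   [train_lr()].
#' @param X r x d matrix (columns as at training).
#' @return Numeric vector of `P(excise)` in `[0, 1]`.
#' @export
predict_prob <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    stop("column-count mismatch: expected ", model$d, " got ", ncol(X))
  switch(model$algorithm,
    svm = {
      pr <- predict(model$fit, X, probability = TRUE)
      unname(attr(pr, "probabilities")[, "excise"])
    },
    rf = unname(predict(model$fit, X, type = "prob")[, "excise"]),
    lr = {
      Xg <- if (model$d < 2L) cbind(X, `.dummy` = 0) else X
      as.numeric(predict(model$fit, Xg, type = "response"))
    })
}

#' Classify lesions at a probability threshold
#'
#' @inheritParams predict_prob
#' @param threshold decision cut-off; defaults to the model's configured
#'   threshold. A probability equal to the threshold maps to "excise".
#' @return data.frame with columns `probability`, `decision` (1 = excise) and
#'   `label` ("excise" / "do not excise").
#' @export
classify_lesions <- function(model, X,
                             threshold = model$config$probability_threshold) {
  p <- predict_prob(model, X)
  dec <- as.integer(p >= threshold)
  data.frame(probability = p, decision = dec,
             label = ifelse(dec == 1L, "excise", "do not excise"))
}

#' @export
print.dermwave_clf <- function(x, ...) {
  cat(sprintf("dermwave classifier: %s on %d feature(s)\n", x$algorithm, x$d))
  invisible(x)
}
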