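#' Read a feature table CSV
#'
#' Permissive reader for feature tables in the layout of the study's
#' supplementary files (one row per lesion, 1152 numeric columns, class
#' implied by file): an optional header row and an optional leading
#' non-numeric ID column are auto-detected and tolerated; ragged rows,
#' non-numeric cells and unexpected column counts raise errors naming the
#' offending row/column.
#'
#' @param path CSV file path (comma separator, `.` decimal).
#' @param expected_q required feature count (default 1152); `NULL` disables
#'   the check.
#' @return Numeric matrix, one row per lesion.
#' @export
read_feature_csv <- function(path, expected_q = 1152L) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) == 0L) stop("format error: empty file ", path)
  if (length(unique(nf)) != 1L)
    stop("format error: ragged rows (row ", which(nf != nf[1])[1],
         " has ", nf[which(nf != nf[1])[1]], " fields, expected ", nf[1], ")")
  d <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                       colClasses = "character")
  # header detection: any cell of the first row that fails numeric parsing
  first <- suppressWarnings(as.numeric(d[1, ]))
  if (anyNA(first) && nrow(d) > 1L) d <- d[-1, , drop = FALSE]
  # leading ID column: entirely non-numeric
  col1 <- suppressWarnings(as.numeric(d[[1]]))
  if (all(is.na(col1)) && ncol(d) > 1L) d <- d[, -1, drop = FALSE]
  M <- suppressWarnings(vapply(d, as.numeric, numeric(nrow(d))))
  if (nrow(d) == 1L) M <- matrix(M, nrow = 1L)
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop("format error: non-numeric cell at row ", bad[1],
         ", column ", bad[2], " of ", path)
  }
  if (!is.null(expected_q) && ncol(M) != expected_q)
    stop("format error: expected ", expected_q, " columns, found ",
         ncol(M), " in ", path)
  dimnames(M) <- NULL
  M
}

#' Write a feature table CSV
#'
#' Canonical writer: comma-separated, `.` decimal, full precision, with an
#' optional header row naming columns in the canonical schema
#' (`L{level}_{band}_{channel}_{stat}` for 1152-column tables).
#'
#' @param X numeric matrix, one row per lesion.
#' @param path output path.
#' @param header write a header row (default TRUE).
#' @export
write_feature_csv <- function(X, path, header = TRUE) {
  X <- as.matrix(X)
  cn <- colnames(X)
  if (is.null(cn))
    cn <- if (ncol(X) == 1152L) feature_schema(6L)$name
          else sprintf("V%d", seq_len(ncol(X)))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines(paste(cn, collapse = ","), con)
  utils::write.table(format(X, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.BUNDLE_SCHEMA <- "dermwave-bundle"
.BUNDLE_VERSION <- 1L

#' Save / load a trained model bundle
#'
#' The bundle is a single versioned file holding the fitted pipeline — the
#' ReliefF ranking, the PCA model (training mean/sd, loadings, singular
#' values), the classifier state and its configuration — so `predict` needs
#' no other inputs. Loading a bundle and predicting gives results identical
#' to the pre-save model; unknown schema versions and corrupt files raise
#' explicit errors.
#'
#' @param model a [dermwave_fit()] object.
#' @param path bundle file path.
#' @export
save_bundle <- function(model, path) {
  if (!inherits(model, "dermwave_fit"))
    stop("model must be a dermwave_fit object")
  obj <- list(schema = .BUNDLE_SCHEMA, schema_version = .BUNDLE_VERSION,
              package_version = as.character(utils::packageVersion("dermwave")),
              model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_bundle
#' @return `load_bundle` returns the [dermwave_fit()] object.
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("bundle not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt bundle: ", path,
                                           " (", conditionMessage(e), ")"))
  if (!is.list(obj) || !identical(obj$schema, .BUNDLE_SCHEMA))
    stop("corrupt bundle: ", path, " is not a dermwave model bundle")
  if (!identical(obj$schema_version, .BUNDLE_VERSION))
    stop("unsupported bundle schema version: ", obj$schema_version)
  obj$model
}

#' Run the reference evaluation protocol on a pair of feature tables
#'
#' Reads an excision and a no-excision feature CSV (class implied by file),
#' concatenates them, and evaluates the canonical pipeline — ReliefF top
#' `top_n` features, `n_components` principal components, RBF SVM — under
#' repeated stratified 10-fold cross-validation and (optionally)
#' leave-one-out, with every stage refit inside the training folds (or fit
#' globally with `global_selection = TRUE`).
#'
#' @param excision_csv,noexcision_csv paths to the two class tables.
#' @param C,gamma SVM parameters (defaults 30, 0.007).
#' @param top_n,n_components,relieff_k pipeline sizes (defaults 125, 22, 10).
#' @param folds,repeats k-fold settings (defaults 10, 5).
#' @param seed RNG seed.
#' @param loo also run leave-one-out (default TRUE).
#' @param global_selection leaky protocol variant (default FALSE).
#' @param expected_q required feature count of the CSVs (default 1152).
#' @return A list of class `dermwave_study`: row counts, the k-fold
#'   [cross_validate()] result, the LOO result (or NULL), and the DOR at the
#'   k-fold operating point.
#' @export
reproduce_study <- function(excision_csv, noexcision_csv,
                            C = 30, gamma = 0.007,
                            top_n = 125L, n_components = 22L,
                            relieff_k = 10L, folds = 10L, repeats = 5L,
                            seed = 1L, loo = TRUE,
                            global_selection = FALSE, expected_q = 1152L) {
  pos <- read_feature_csv(excision_csv, expected_q)
  neg <- read_feature_csv(noexcision_csv, expected_q)
  X <- rbind(pos, neg)
  y <- c(rep(1L, nrow(pos)), rep(0L, nrow(neg)))
  cfg <- svm_config(C = C, gamma = gamma)
  cv <- cross_validate(X, y, folds = folds, repeats = repeats, seed = seed,
                       classifier = "svm", config = cfg, top_n = top_n,
                       n_components = n_components, relieff_k = relieff_k,
                       global_selection = global_selection)
  cv_loo <- if (loo)
    cross_validate(X, y, folds = nrow(X), seed = seed, classifier = "svm",
                   config = cfg, top_n = top_n, n_components = n_components,
                   relieff_k = relieff_k,
                   global_selection = global_selection) else NULL
  dor <- tryCatch(diagnostic_odds_ratio(cv$summary$sensitivity,
                                        cv$summary$specificity),
                  error = function(e) Inf)
  out <- list(n_excise = nrow(pos), n_noexcise = nrow(neg),
              cv = cv, loo = cv_loo, dor = dor,
              global_selection = global_selection)
  class(out) <- "dermwave_study"
  out
}

#' @export
print.dermwave_study <- function(x, ...) {
  cat(sprintf("Study evaluation: %d excise + %d no-excise lesions%s\n",
              x$n_excise, x$n_noexcise,
              if (x$global_selection) " [global selection]" else ""))
  print(x$cv)
  if (!is.null(x$loo)) print(x$loo)
  cat(sprintf("  DOR at the k-fold operating point: %.1f\n", x$dor))
  invisible(x)
}
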