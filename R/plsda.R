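# Discriminant layer on top of PLS2: indicator encoding, argmax class
# assignment, confusion matrices and the two cross-validation drivers.

#' Encode class labels as a 0/1 indicator matrix
#'
#' @param labels Character vector of class labels.
#' @param class_order Ordered character vector of declared classes; its
#'   order defines the indicator columns.
#' @return n x K 0/1 matrix with column names `class_order`; each row sums
#'   to exactly 1.
#' @export
encode_indicator <- function(labels, class_order) {
  bad <- setdiff(labels, class_order)
  if (length(bad)) stopf("unknown label '%s'", bad[1L])
  Y <- matrix(0, length(labels), length(class_order),
              dimnames = list(NULL, class_order))
  Y[cbind(seq_along(labels), match(labels, class_order))] <- 1
  Y
}

#' Decode an indicator matrix back to labels
#'
#' @param indicator n x K 0/1 matrix with one 1 per row.
#' @param class_order Class names for the columns.
#' @return Character vector of labels.
#' @export
decode_indicator <- function(indicator, class_order) {
  class_order[max.col(indicator, ties.method = "first")]
}

#' Assign classes by the maximum-predicted-value rule
#'
#' Each sample is assigned to the class whose predicted indicator value is
#' largest; exact ties go to the earliest class in `class_order`.
#'
#' @param predicted m x K matrix of continuous predicted responses.
#' @param class_order Class names, one per column.
#' @return Character vector of m assigned class names.
#' @export
assign_class <- function(predicted, class_order) {
  predicted <- as.matrix(predicted)
  if (ncol(predicted) != length(class_order))
    stopf("%d prediction columns but %d classes", ncol(predicted), length(class_order))
  bad <- which(!is.finite(rowSums(predicted)))
  if (length(bad)) stopf("non-finite prediction in row %d", bad[1L])
  class_order[max.col(predicted, ties.method = "first")]
}

#' Confusion matrix of true versus predicted labels
#'
#' @param true_labels,predicted_labels Equal-length character vectors.
#' @param class_order Ordered class names defining rows (true) and
#'   columns (predicted).
#' @return An object of class `confusion_matrix`: K x K integer count
#'   matrix, rows = true class.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, class_order) {
  if (length(true_labels) != length(predicted_labels))
    stopf("length mismatch: %d true vs %d predicted labels",
          length(true_labels), length(predicted_labels))
  counts <- table(factor(true_labels, levels = class_order),
                  factor(predicted_labels, levels = class_order))
  structure(matrix(as.integer(counts), nrow = length(class_order),
                   dimnames = list(true = class_order, predicted = class_order)),
            class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- unclass(x)
  acc <- per_class_accuracy(x)
  out <- cbind(as.data.frame(m), `accuracy (%)` = round(acc, 2))
  print(out)
  cat(sprintf("Overall: %.2f%%\n", overall_accuracy(x)))
  invisible(x)
}

#' Overall classification accuracy of a confusion matrix
#'
#' @param cm A `confusion_matrix` (or plain square count matrix).
#' @return Percentage `100 * trace / total`.
#' @export
overall_accuracy <- function(cm) {
  m <- unclass(cm)
  total <- sum(m)
  if (total <= 0) stopf("empty confusion matrix")
  100 * sum(diag(m)) / total
}

#' Per-class classification accuracy
#'
#' @param cm A `confusion_matrix`.
#' @return Vector of K percentages `100 * diagonal / row sum`; classes with
#'   no samples are reported as `NA` (undefined), not 0.
#' @export
per_class_accuracy <- function(cm) {
  m <- unclass(cm)
  rs <- rowSums(m)
  acc <- ifelse(rs > 0, 100 * diag(m) / rs, NA_real_)
  names(acc) <- rownames(m)
  acc
}

# Resolve a feature subset argument (NULL = all features) to sorted indices.
resolve_subset <- function(p, feature_subset) {
  if (is.null(feature_subset)) return(seq_len(p))
  idx <- sort(unique(as.integer(feature_subset)))
  if (length(idx) < 1L || idx[1L] < 1L || idx[length(idx)] > p)
    stopf("feature subset indices must lie in [1, %d]", p)
  idx
}

#' Fit a PLSDA model on a spectra set
#'
#' PLS2 regression of the class-indicator matrix on the (optionally
#' subsetted) absorbance matrix, packaged with the class order and feature
#' subset for prediction.
#'
#' @param train A `spectra_set`.
#' @param n_components Number of latent variables.
#' @param feature_subset Optional integer indices into the wavenumber grid;
#'   `NULL` uses all features.
#' @return An object of class `plsda_model`.
#' @export
fit_plsda <- function(train, n_components, feature_subset = NULL) {
  idx <- resolve_subset(ncol(train$absorbance), feature_subset)
  Y <- encode_indicator(train$labels, train$class_order)
  pls <- fit_pls2(train$absorbance[, idx, drop = FALSE], Y, n_components)
  structure(list(pls = pls, class_order = train$class_order,
                 feature_subset = idx, wavenumbers = train$wavenumbers[idx],
                 n_components = pls$n_components),
            class = "plsda_model")
}

#' Predict soil classes for new spectra
#'
#' @param object A `plsda_model`.
#' @param newdata A `spectra_set` on the training grid (or a matrix with the
#'   full grid's columns).
#' @param a Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Character vector of predicted class names.
#' @export
predict.plsda_model <- function(object, newdata, a = object$n_components, ...) {
  X <- if (inherits(newdata, "spectra_set")) newdata$absorbance else as.matrix(newdata)
  scores <- predict_pls2(object$pls, X[, object$feature_subset, drop = FALSE], a)
  assign_class(scores, object$class_order)
}

#' Calibration confusion matrix of a fitted PLSDA model
#'
#' @param model A `plsda_model`.
#' @param train The `spectra_set` the model was fitted on.
#' @param a Number of components.
#' @return A `confusion_matrix` of training samples.
#' @export
calibration_confusion <- function(model, train, a = model$n_components) {
  confusion_matrix(train$labels, predict(model, train, a), train$class_order)
}

#' Leave-one-out cross-validated confusion matrix
#'
#' For each sample the model is refitted on the remaining n - 1 samples
#' (with fresh centering, so no information leaks from the held-out
#' spectrum) and the held-out sample is classified.
#'
#' @param train A `spectra_set` with n >= K + 1 samples.
#' @param n_components Number of latent variables (`<= n - 2`).
#' @param feature_subset Optional feature indices; `NULL` uses all.
#' @return A `confusion_matrix` over all n held-out predictions.
#' @export
loo_cv <- function(train, n_components, feature_subset = NULL) {
  n <- nrow(train$absorbance)
  if (n_components > n - 2L)
    stopf("n_components = %d infeasible for LOO with n = %d", n_components, n)
  idx <- resolve_subset(ncol(train$absorbance), feature_subset)
  X <- train$absorbance[, idx, drop = FALSE]
  Y <- encode_indicator(train$labels, train$class_order)
  scores <- cpp_loo_predict(X, Y, as.integer(n_components), 1e-10, 500L, FALSE)
  confusion_matrix(train$labels, assign_class(scores, train$class_order),
                   train$class_order)
}

#' Classification accuracy as a function of component count
#'
#' One row per component count a = 1..`max_components`, with calibration,
#' leave-one-out and (if a test set is given) external validation accuracy.
#' No smoothing is applied; each row is exactly the accuracy at that a.
#'
#' @param train A `spectra_set`.
#' @param test Optional held-out `spectra_set`; `NULL` omits the external
#'   column.
#' @param max_components Largest component count evaluated (default 30).
#' @param feature_subset Optional feature indices.
#' @return Data frame with columns `components`, `calibration`, `loo`, and
#'   optionally `external` (percentages).
#' @export
accuracy_curve <- function(train, test = NULL, max_components = 30L,
                           feature_subset = NULL) {
  n <- nrow(train$absorbance)
  idx <- resolve_subset(ncol(train$absorbance), feature_subset)
  A <- as.integer(max_components)
  if (A > min(n - 2L, length(idx)))
    stopf("max_components = %d infeasible (n = %d, features = %d)", A, n, length(idx))
  X <- train$absorbance[, idx, drop = FALSE]
  Y <- encode_indicator(train$labels, train$class_order)
  full <- fit_pls2(X, Y, A)
  cal <- loo <- ext <- numeric(A)
  # one LOO refit per sample at the largest a; predictions at every a reuse it
  K <- ncol(Y)
  loo_scores <- cpp_loo_predict(X, Y, A, 1e-10, 500L, TRUE)
  loo_pred <- vapply(seq_len(A), function(a)
    assign_class(loo_scores[, (a - 1L) * K + seq_len(K), drop = FALSE],
                 train$class_order), character(n))
  loo_pred <- matrix(loo_pred, nrow = n)
  Xt <- if (!is.null(test)) test$absorbance[, idx, drop = FALSE]
  for (a in seq_len(A)) {
    cal[a] <- overall_accuracy(confusion_matrix(
      train$labels, assign_class(predict_pls2(full, X, a), train$class_order),
      train$class_order))
    loo[a] <- overall_accuracy(confusion_matrix(
      train$labels, loo_pred[, a], train$class_order))
    if (!is.null(test))
      ext[a] <- overall_accuracy(confusion_matrix(
        test$labels, assign_class(predict_pls2(full, Xt, a), train$class_order),
        train$class_order))
  }
  out <- data.frame(components = seq_len(A), calibration = cal, loo = loo)
  if (!is.null(test)) out$external <- ext
  out
}
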