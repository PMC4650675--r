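#' Default soil class order
#'
#' The five FAO soil classes recognised by the package, in the fixed order
#' used for indicator columns, confusion-matrix rows and argmax tie-breaking.
#'
#' @return Character vector of the five class names.
#' @export
soil_classes <- function() {
  c("Albic Luvisols", "Haplic Luvisols", "Chernozems",
    "Eutric Cambisols", "Phaeozems")
}

#' Construct a spectra set
#'
#' The universal input container: a wavenumber grid (strictly decreasing,
#' reciprocal centimetres), an absorbance matrix (rows = samples), unique
#' sample ids and class labels drawn from a declared ordered class list.
#'
#' @param wavenumbers Numeric vector of length p, strictly decreasing (cm^-1).
#' @param absorbance Numeric n x p matrix of unitless absorbance values.
#' @param sample_ids Character vector of n unique sample identifiers.
#' @param labels Character vector of n class labels.
#' @param class_order Ordered character vector of all declared classes;
#'   defaults to [soil_classes()] when the labels are a subset of it,
#'   otherwise to the labels in order of first appearance.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumbers, absorbance, sample_ids, labels,
                        class_order = NULL) {
  absorbance <- as.matrix(absorbance)
  wavenumbers <- as.numeric(wavenumbers)
  sample_ids <- as.character(sample_ids)
  labels <- as.character(labels)
  n <- nrow(absorbance); p <- ncol(absorbance)
  if (n < 1L || p < 1L) stopf("spectra set needs n >= 1 and p >= 1 (got %d x %d)", n, p)
  if (length(wavenumbers) != p)
    stopf("wavenumber grid length %d != %d absorbance columns", length(wavenumbers), p)
  if (any(!is.finite(wavenumbers)) || any(diff(wavenumbers) >= 0))
    stopf("wavenumbers must be finite and strictly decreasing")
  if (any(!is.finite(absorbance)))
    stopf("non-finite absorbance value in sample '%s'",
          sample_ids[which(!is.finite(absorbance), arr.ind = TRUE)[1L, 1L]])
  if (length(sample_ids) != n || length(labels) != n)
    stopf("sample_ids/labels length must equal %d rows", n)
  if (anyDuplicated(sample_ids))
    stopf("duplicate sample id '%s'", sample_ids[duplicated(sample_ids)][1L])
  if (is.null(class_order)) {
    class_order <- if (all(labels %in% soil_classes())) soil_classes()
                   else unique(labels)
  }
  bad <- setdiff(labels, class_order)
  if (length(bad)) stopf("unknown label '%s' (not in declared class list)", bad[1L])
  dimnames(absorbance) <- NULL
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 sample_ids = sample_ids, labels = labels,
                 class_order = as.character(class_order)),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavenumbers (%.0f to %.0f cm-1)\n",
              nrow(x$absorbance), ncol(x$absorbance),
              x$wavenumbers[1L], x$wavenumbers[length(x$wavenumbers)]))
  print(table(factor(x$labels, levels = x$class_order)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set by sample index
#'
#' @param set A `spectra_set`.
#' @param idx Integer vector of sample (row) indices.
#' @return A `spectra_set` with the selected samples.
#' @export
subset_samples <- function(set, idx) {
  spectra_set(set$wavenumbers, set$absorbance[idx, , drop = FALSE],
              set$sample_ids[idx], set$labels[idx], set$class_order)
}

#' Read a wide-format spectra table
#'
#' Expects a CSV whose header row is an id column, a label column, then one
#' numeric wavenumber per remaining column (the column order defines the
#' grid, which must be strictly decreasing unless `reorder = TRUE`).
#'
#' @param path Path to the CSV file.
#' @param class_order Declared class order (default [soil_classes()] when
#'   applicable; see [spectra_set()]).
#' @param reorder If `TRUE`, columns are sorted into decreasing-wavenumber
#'   order instead of rejecting an ascending grid.
#' @return A `spectra_set`.
#' @export
read_spectra_csv <- function(path, class_order = NULL, reorder = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stopf("'%s': need id, label and >= 1 wavenumber column", path)
  wn_names <- colnames(df)[-(1:2)]
  wn <- suppressWarnings(as.numeric(wn_names))
  if (anyNA(wn))
    stopf("'%s': non-numeric wavenumber header '%s'", path, wn_names[which(is.na(wn))[1L]])
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(X)) {
    bad <- which(!vapply(df[-(1:2)], is.numeric, logical(1)))[1L]
    stopf("'%s': non-numeric absorbance in column '%s'", path, wn_names[bad])
  }
  if (any(diff(wn) >= 0)) {
    if (!reorder)
      stopf("'%s': wavenumber columns not strictly decreasing (set reorder = TRUE to sort)", path)
    o <- order(wn, decreasing = TRUE)
    wn <- wn[o]; X <- X[, o, drop = FALSE]
  }
  spectra_set(wn, X, df[[1L]], df[[2L]], class_order)
}

#' Write a spectra set as a wide-format CSV
#'
#' @param set A `spectra_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(set, path) {
  df <- data.frame(id = set$sample_ids, label = set$labels,
                   set$absorbance, check.names = FALSE)
  colnames(df)[-(1:2)] <- sprintf("%.17g", set$wavenumbers)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits every class independently, putting `round(train_fraction * n_c)`
#' samples of each class into the training set (rounding to nearest, which
#' with the default 2:1 ratio reproduces the allocation 36/72/29/45/48 ->
#' 24/48/19/30/32 training samples per class).
#'
#' @param set A `spectra_set`; every class present must have >= 2 samples.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 2/3).
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @return A list with `spectra_set` elements `train` and `test`.
#' @export
stratified_split <- function(set, train_fraction = 2 / 3, seed = 1L) {
  counts <- table(set$labels)
  small <- names(counts)[counts < 2L]
  if (length(small)) stopf("class '%s' has < 2 samples; cannot split", small[1L])
  train_idx <- integer(0)
  with_seed(seed, {
    for (cls in set$class_order) {
      idx <- which(set$labels == cls)
      if (!length(idx)) next
      n_tr <- as.integer(round(train_fraction * length(idx)))
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(set$labels), train_idx)
  list(train = subset_samples(set, train_idx),
       test = subset_samples(set, test_idx))
}
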