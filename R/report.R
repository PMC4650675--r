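# Report writers: confusion matrices in the conventional table layout
# (true-class rows, predicted-class count columns, a per-class accuracy
# column and a Mean row) plus readers that recover the counts.

#' Write a confusion matrix report
#'
#' CSV with one row per true class (counts across predicted classes and
#' the per-class accuracy to 2 decimals) and a final `Mean` row carrying
#' the overall accuracy.
#'
#' @param cm A `confusion_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confusion_report <- function(cm, path) {
  m <- unclass(cm)
  acc <- per_class_accuracy(cm)
  df <- data.frame(true_class = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  df[["Classification accuracy (%)"]] <- sprintf("%.2f", acc)
  mean_row <- data.frame(true_class = "Mean",
                         as.data.frame(matrix("", 1L, ncol(m))),
                         check.names = FALSE)
  colnames(mean_row)[-1L] <- colnames(m)
  mean_row[["Classification accuracy (%)"]] <- sprintf("%.2f", overall_accuracy(cm))
  utils::write.csv(rbind(df, mean_row), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read the counts back from a confusion matrix report
#'
#' @param path Path written by [write_confusion_report()].
#' @return A `confusion_matrix`.
#' @export
read_confusion_report <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df <- df[df$true_class != "Mean", , drop = FALSE]
  classes <- df$true_class
  counts <- as.matrix(df[, classes, drop = FALSE])
  mode(counts) <- "integer"
  cm_from_counts(counts, classes)
}

# Build a confusion_matrix directly from a count matrix.
cm_from_counts <- function(counts, class_order) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || nrow(counts) != length(class_order))
    stopf("count matrix must be %d x %d", length(class_order), length(class_order))
  if (any(counts < 0)) stopf("negative confusion counts")
  structure(matrix(as.integer(counts), nrow = length(class_order),
                   dimnames = list(true = class_order, predicted = class_order)),
            class = c("confusion_matrix", "matrix"))
}

#' Read stacked confusion-count blocks
#'
#' Parses a long CSV with columns `phase`, `true_class`, then one count
#' column per predicted class (the layout used for the reference tables
#' shipped under `inst/extdata/`).
#'
#' @param path Path to the CSV.
#' @return Named list of `confusion_matrix` objects, one per phase, in
#'   order of first appearance.
#' @export
read_confusion_blocks <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  classes <- colnames(df)[-(1:2)]
  phases <- unique(df$phase)
  out <- lapply(phases, function(ph) {
    block <- df[df$phase == ph, , drop = FALSE]
    counts <- as.matrix(block[match(classes, block$true_class), classes])
    cm_from_counts(counts, classes)
  })
  names(out) <- phases
  out
}
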