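# Classification and regression metrics for cohort evaluation.

#' Per-class and macro F-1 scores
#'
#' Computes precision `TP / (TP + FP)`, recall `TP / (TP + FN)` and
#' `F1 = 2 P R / (P + R)` for every class, plus the unweighted (macro) mean
#' over classes. Degenerate ratios (0/0) are defined as 0 and flagged in the
#' `degenerate` column.
#'
#' @param predictions Vector of predicted labels.
#' @param truths Vector of true labels, same length.
#' @param classes Optional class set; defaults to the union of observed
#'   labels, sorted.
#' @return A list with `per_class` (data.frame: class, TP, FP, FN, precision,
#'   recall, f1, degenerate), `macro_f1`, and `accuracy`.
#' @export
f1_scores <- function(predictions, truths, classes = NULL) {
  if (length(predictions) == 0 || length(predictions) != length(truths)) {
    stop("predictions and truths must be non-empty and of equal length")
  }
  if (is.null(classes)) classes <- sort(unique(c(predictions, truths)))
  per <- lapply(classes, function(k) {
    tp <- sum(predictions == k & truths == k)
    fp <- sum(predictions == k & truths != k)
    fn <- sum(predictions != k & truths == k)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(class = as.character(k), TP = tp, FP = fp, FN = fn,
               precision = p, recall = r, f1 = f1,
               degenerate = (tp + fp == 0) || (tp + fn == 0),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_class = per,
       macro_f1 = mean(per$f1),
       accuracy = mean(predictions == truths))
}

#' Mean absolute error
#'
#' @param predictions Numeric vector of predictions.
#' @param truths Numeric vector of ground-truth values, same length.
#' @return Mean of `|truth - prediction|`, in the units of the inputs.
#' @export
mae <- function(predictions, truths) {
  if (length(predictions) == 0 || length(predictions) != length(truths)) {
    stop("predictions and truths must be non-empty and of equal length")
  }
  mean(abs(truths - predictions))
}

#' Confusion matrix with precision normalization
#'
#' Returns raw counts (rows = true class, columns = predicted class) and the
#' column-normalized percentages, i.e. each column scaled to sum to 100 so
#' that diagonal entries read as per-predicted-class precision.
#'
#' @param predictions Vector of predicted labels.
#' @param truths Vector of true labels.
#' @param classes Class set; every label must belong to it.
#' @return List with `counts` and `precision_pct` matrices.
#' @export
confusion_matrix <- function(predictions, truths,
                             classes = sort(unique(c(predictions, truths)))) {
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have equal length")
  }
  if (!all(predictions %in% classes) || !all(truths %in% classes)) {
    stop("labels outside the declared class set")
  }
  f <- function(x) factor(as.character(x), levels = as.character(classes))
  counts <- table(truth = f(truths), predicted = f(predictions))
  counts <- unclass(counts)
  col_tot <- colSums(counts)
  pct <- sweep(counts, 2, ifelse(col_tot > 0, col_tot, 1), "/") * 100
  pct[, col_tot == 0] <- NA_real_
  list(counts = counts, precision_pct = pct)
}
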