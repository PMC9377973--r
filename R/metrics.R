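#' Confusion matrix
#'
#' Tabulates predictions against truth: `table[i, j]` counts samples whose
#' true class is i and predicted class is j (rows = truth, columns =
#' prediction).
#'
#' @param y_true integer labels in `1..k`.
#' @param y_pred integer labels in `1..k`, same length.
#' @param k number of classes.
#' @param labels optional k class names.
#' @return An object of class `"confusion_matrix"` wrapping a k x k
#'   integer matrix with `dimnames = list(true, predicted)`.
#' @export
confusion <- function(y_true, y_pred, k, labels = NULL) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) > 0L &&
      (any(y_true < 1L | y_true > k) || any(y_pred < 1L | y_pred > k)))
    stop("labels out of range 1..k")
  if (is.null(labels)) labels <- paste0("class", seq_len(k))
  if (length(labels) != k) stop("need k labels")
  m <- matrix(0L, k, k, dimnames = list(true = labels, predicted = labels))
  for (i in seq_along(y_true))
    m[y_true[i], y_pred[i]] <- m[y_true[i], y_pred[i]] + 1L
  structure(list(table = m, labels = labels), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted)\n")
  print(x$table)
  invisible(x)
}

cm_parts <- function(cm, i) {
  m <- cm$table
  tp <- m[i, i]
  fn <- sum(m[i, ]) - tp
  fp <- sum(m[, i]) - tp
  tn <- sum(m) - tp - fn - fp
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Missed detection rate (false negative rate)
#'
#' One-vs-rest `FN / (TP + FN)` for one class: the fraction of samples of
#' that class the classifier failed to assign to it.
#'
#' @param cm a [confusion()] matrix.
#' @param class_index class in `1..k`.
#' @return Rate in `[0, 1]`.  Errors (rather than silently returning 0)
#'   when the class has no true samples.
#' @export
fnr <- function(cm, class_index) {
  stopifnot(inherits(cm, "confusion_matrix"))
  p <- cm_parts(cm, class_index)
  if (p$tp + p$fn == 0)
    stop("FNR undefined: class ", class_index, " has no true samples")
  p$fn / (p$tp + p$fn)
}

#' Wrong detection rate (false positive rate)
#'
#' One-vs-rest `FP / (FP + TN)` for one class: the fraction of samples of
#' other classes the classifier wrongly assigned to this one.
#'
#' @inheritParams fnr
#' @return Rate in `[0, 1]`.  Errors when `FP + TN = 0`.
#' @export
fpr <- function(cm, class_index) {
  stopifnot(inherits(cm, "confusion_matrix"))
  p <- cm_parts(cm, class_index)
  if (p$fp + p$tn == 0)
    stop("FPR undefined: no samples outside class ", class_index)
  p$fp / (p$fp + p$tn)
}

#' Per-class precision/recall report
#'
#' Per-class precision (`TP / column sum`), recall (`TP / row sum`),
#' one-vs-rest FNR and FPR, and their macro (unweighted) means over the
#' classes where they are defined.  Undefined rates (empty denominators)
#' are reported as `NA`, never as zero.
#'
#' @param cm a [confusion()] matrix.
#' @return A list with `per_class` (data frame: label, precision, recall,
#'   fnr, fpr), `macro_precision`, `macro_recall`, `macro_fnr`,
#'   `macro_fpr`, and `accuracy`.
#' @export
per_class_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- cm$table
  k <- nrow(m)
  rs <- rowSums(m); cs <- colSums(m); tot <- sum(m)
  tp <- diag(m)
  precision <- ifelse(cs > 0, tp / cs, NA_real_)
  recall <- ifelse(rs > 0, tp / rs, NA_real_)
  fn_rate <- ifelse(rs > 0, (rs - tp) / rs, NA_real_)
  fp_rate <- ifelse(tot - rs > 0, (cs - tp) / (tot - rs), NA_real_)
  list(
    per_class = data.frame(label = cm$labels, precision = precision,
                           recall = recall, fnr = fn_rate, fpr = fp_rate,
                           stringsAsFactors = FALSE, row.names = NULL),
    macro_precision = mean(precision, na.rm = TRUE),
    macro_recall = mean(recall, na.rm = TRUE),
    macro_fnr = mean(fn_rate, na.rm = TRUE),
    macro_fpr = mean(fp_rate, na.rm = TRUE),
    accuracy = if (tot > 0) sum(tp) / tot else NA_real_
  )
}
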