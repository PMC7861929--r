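# Four-class confusion matrix and the per-class Se/Sp/+p/Acc calculus.
#
# For class c: TP = the diagonal cell; FN = the rest of c's row; FP = the
# rest of c's column; TN = everything else.  Se = TP/(TP+FN),
# Sp = TN/(TN+FP), +p = TP/(TP+FP), Acc = (TP+TN)/total.  "Overall" accuracy
# is the micro average trace/total.  Reported percentages are rounded half
# up to 2 decimals, the convention of published clinical tables.

#' Four-class confusion matrix
#'
#' Rows are true classes (N, S, V, F), columns predicted classes
#' (n, s, v, f).
#'
#' @param y_true,y_pred equal-length label vectors over `{N, S, V, F}`.
#' @return 4x4 integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop_bad("y_true and y_pred must have equal length")
  t4 <- as_aami_factor(y_true)
  p4 <- as_aami_factor(y_pred)
  m <- unclass(table(true = t4, pred = p4))
  dimnames(m) <- list(true = AAMI_CLASSES, pred = tolower(AAMI_CLASSES))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

as_confusion_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L))) stop_bad("confusion matrix must be 4x4")
  if (any(m < 0)) stop_bad("confusion matrix entries must be nonnegative")
  dimnames(m) <- list(true = AAMI_CLASSES, pred = tolower(AAMI_CLASSES))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Per-class TP/FN/FP/TN partition
#'
#' @param cm a [confusion_matrix()] (or plain 4x4 matrix).
#' @param cls one of `"N"`, `"S"`, `"V"`, `"F"`.
#' @return list with `tp`, `fn`, `fp`, `tn` (summing to the grand total).
#' @export
class_counts <- function(cm, cls) {
  cm <- as_confusion_matrix(cm)
  i <- match(cls, AAMI_CLASSES)
  if (is.na(i)) stop_bad("cls must be one of N, S, V, F")
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  list(tp = tp, fn = fn, fp = fp, tn = sum(cm) - tp - fn - fp)
}

#' Per-class metrics from a TP/FN/FP/TN partition
#'
#' @param cc a [class_counts()] list.
#' @return list with `se`, `sp`, `ppv`, `acc` in percent (unrounded); `ppv`
#'   is `NA` when `tp + fp` is zero.
#' @export
class_metrics <- function(cc) {
  if (cc$tp + cc$fn <= 0) stop_bad("class has no true members (tp + fn = 0)")
  total <- cc$tp + cc$fn + cc$fp + cc$tn
  list(se = 100 * cc$tp / (cc$tp + cc$fn),
       sp = 100 * cc$tn / (cc$tn + cc$fp),
       ppv = if (cc$tp + cc$fp > 0) 100 * cc$tp / (cc$tp + cc$fp)
             else NA_real_,
       acc = 100 * (cc$tp + cc$tn) / total)
}

#' Overall (micro) accuracy: trace over grand total
#'
#' @param cm a [confusion_matrix()].
#' @return percent.
#' @export
overall_accuracy <- function(cm) {
  cm <- as_confusion_matrix(cm)
  if (sum(cm) == 0) stop_bad("empty confusion matrix")
  100 * sum(diag(cm)) / sum(cm)
}

#' Per-class metrics table plus overall accuracy
#'
#' Deterministic report mirroring the conventional benchmark layout:
#' one row per class with Se/Sp/+p/Acc rounded half up to 2 decimals, with
#' the overall accuracy as an attribute.  Classes absent from the data get
#' `NA` rows.
#'
#' @param cm a [confusion_matrix()].
#' @return data.frame (class `classification_report`) with columns `class`,
#'   `se`, `sp`, `ppv`, `acc`; attribute `overall_accuracy`.
#' @export
classification_report <- function(cm) {
  cm <- as_confusion_matrix(cm)
  if (sum(cm) == 0) stop_bad("empty confusion matrix")
  rows <- lapply(AAMI_CLASSES, function(cls) {
    cc <- class_counts(cm, cls)
    if (cc$tp + cc$fn == 0)
      return(data.frame(class = cls, se = NA_real_, sp = NA_real_,
                        ppv = NA_real_, acc = NA_real_))
    m <- class_metrics(cc)
    data.frame(class = cls, se = round_half_up(m$se), sp = round_half_up(m$sp),
               ppv = round_half_up(m$ppv), acc = round_half_up(m$acc))
  })
  out <- do.call(rbind, rows)
  attr(out, "overall_accuracy") <- round_half_up(overall_accuracy(cm))
  class(out) <- c("classification_report", "data.frame")
  out
}

#' @export
print.classification_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("overall accuracy: %.2f%%\n", attr(x, "overall_accuracy")))
  invisible(x)
}

#' Read / write a confusion matrix as CSV
#'
#' The CSV has a `true` label column and columns `n`, `s`, `v`, `f`.
#'
#' @param cm a [confusion_matrix()].
#' @param path CSV path.
#' @export
write_confusion_csv <- function(cm, path) {
  cm <- as_confusion_matrix(cm)
  df <- data.frame(true = AAMI_CLASSES, unclass(cm))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[match(AAMI_CLASSES, df$true), c("n", "s", "v", "f")])
  as_confusion_matrix(m)
}
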