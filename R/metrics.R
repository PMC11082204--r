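#' Confusion matrix of predictions
#'
#' @param true,pred factors (or vectors coercible to the class levels).
#' @param classes class levels, in order.
#' @return classes x classes integer matrix; rows are true classes, columns
#'   predicted classes.
#' @export
confusion_matrix <- function(true, pred, classes = DBSA_CLASSES) {
  true <- factor(true, levels = classes)
  pred <- factor(pred, levels = classes)
  as.matrix(table(true = true, pred = pred))
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy (OA) is the trace over the total; average accuracy (AA)
#' is the unweighted mean of per-class recalls — the standard usage for
#' patch-based hyperspectral classification, where per-class "accuracy"
#' tables report recalls. Precision, recall and F1 are computed per class
#' and macro-averaged; any division by zero yields 0 and raises the
#' `zero_division` flag.
#'
#' @param confusion square count matrix, rows = true classes.
#' @return Object of class `metrics_report`: the confusion matrix, `oa`,
#'   `aa`, a per-class data frame (precision, recall, f1, support) and
#'   macro averages.
#' @export
metrics_report <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion),
            all(confusion >= 0))
  total <- sum(confusion)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  tp <- diag(confusion)
  support <- rowSums(confusion)
  predicted <- colSums(confusion)
  recall <- safe_div(tp, support)
  precision <- safe_div(tp, predicted)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  zero_div <- any(support == 0) || any(predicted == 0) ||
    any(precision + recall == 0)
  per_class <- data.frame(class = rownames(confusion) %||%
                            paste0("class", seq_along(tp)),
                          precision = precision, recall = recall, f1 = f1,
                          support = support, row.names = NULL)
  structure(list(confusion = confusion,
                 oa = safe_div(sum(tp), total),
                 aa = mean(recall),
                 per_class = per_class,
                 macro_precision = mean(precision),
                 macro_recall = mean(recall),
                 macro_f1 = mean(f1),
                 zero_division = zero_div,
                 n = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("Classification report (n = %d)\n", x$n))
  cat(sprintf("  overall accuracy (OA): %.*f\n", digits, x$oa))
  cat(sprintf("  average accuracy (AA): %.*f\n", digits, x$aa))
  pc <- x$per_class
  pc[, 2:4] <- round(pc[, 2:4], digits)
  print(pc, row.names = FALSE)
  cat(sprintf("  macro P/R/F1: %.*f / %.*f / %.*f\n", digits,
              x$macro_precision, digits, x$macro_recall, digits, x$macro_f1))
  if (x$zero_division)
    cat("  note: zero-division encountered; affected metrics reported as 0\n")
  invisible(x)
}

as_metrics_row <- function(r) {
  out <- c(oa = r$oa, aa = r$aa,
           stats::setNames(r$per_class$recall,
                           paste0("recall_", r$per_class$class)),
           macro_f1 = r$macro_f1)
  as.list(out)
}
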