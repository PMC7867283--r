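# Classification performance metrics: confusion counts, the six rates of a
# performance report, the Matthews correlation coefficient, and ROC analysis
# by pair counting.

#' Confusion counts at a probability cutoff
#'
#' Thresholds per-compound active-class probabilities at `cutoff`
#' (probability >= cutoff predicts active) and cross-tabulates against the
#' true labels.
#'
#' @param labels Factor or character vector of true classes
#'   (`"active"`/`"inactive"`).
#' @param prob Numeric vector of active-class probabilities, same length.
#' @param cutoff Classification cutoff on the probability, default 0.5.
#' @return A list with integer fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(labels, prob, cutoff = 0.5) {
  labels <- as_class_labels(labels)
  if (length(labels) != length(prob)) {
    stop("labels and probabilities differ in length", call. = FALSE)
  }
  pred_active <- prob >= cutoff
  truth_active <- labels == "active"
  counts <- list(
    tp = sum(pred_active & truth_active),
    fp = sum(pred_active & !truth_active),
    tn = sum(!pred_active & !truth_active),
    fn = sum(!pred_active & truth_active)
  )
  lapply(counts, as.integer)
}

as_class_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), CLASS_LEVELS)
  if (length(bad)) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(labels, levels = CLASS_LEVELS)
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), a balanced
#' quality score in \[-1, 1\]: +1 is a perfect forecast, 0 a random one, -1
#' total disagreement. When any marginal factor of the denominator is zero
#' the coefficient is undefined; this implementation returns 0, the random-
#' forecast interpretation.
#'
#' @param tp,fp,tn,fn Non-negative integer confusion counts, summing to at
#'   least one.
#' @return MCC as a single number.
#' @examples
#' matthews_cc(tp = 76, fp = 24, tn = 76, fn = 24) # 0.52
#' @export
matthews_cc <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("confusion counts sum to zero", call. = FALSE)
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

rate <- function(num, den) if (den == 0) NA_real_ else num / den

#' Build a performance report from confusion counts
#'
#' Computes sensitivity (true-active rate), specificity (true-inactive
#' rate), accuracy, PPV, NPV and MCC from the counts; AUC is attached when
#' supplied. Rates with a zero denominator are `NA`.
#'
#' @param counts List with `tp`, `fp`, `tn`, `fn` (see [confusion_counts()]).
#' @param auc Optional area under the ROC curve for the same evaluation.
#' @return An object of class `performance_report`: a list with the six
#'   rates, `auc`, and the raw `counts`.
#' @export
performance_report <- function(counts, auc = NA_real_) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  out <- list(
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    accuracy = rate(tp + tn, tp + tn + fp + fn),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    mcc = matthews_cc(tp, fp, tn, fn),
    auc = auc,
    counts = counts
  )
  structure(out, class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Performance report\n")
  cat(sprintf("  counts: TP=%d FP=%d TN=%d FN=%d\n",
              x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn))
  for (nm in c("sensitivity", "specificity", "accuracy", "ppv", "npv",
               "mcc", "auc")) {
    cat(sprintf("  %-11s %s\n", nm,
                ifelse(is.na(x[[nm]]), "NA", sprintf("%.4f", x[[nm]]))))
  }
  invisible(x)
}

#' Serialize a performance report to JSON
#'
#' Writes the six rates at four decimal places plus the raw counts.
#'
#' @param report A `performance_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_performance_json <- function(report, path) {
  payload <- list(
    sensitivity = round(report$sensitivity, 4),
    specificity = round(report$specificity, 4),
    accuracy = round(report$accuracy, 4),
    ppv = round(report$ppv, 4),
    npv = round(report$npv, 4),
    mcc = round(report$mcc, 4),
    auc = round(report$auc, 4),
    counts = report$counts
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' ROC curve and AUC by pair counting
#'
#' The AUC is the Mann-Whitney concordance probability: over all
#' active-inactive pairs, the fraction in which the active scores higher,
#' counting ties as one half. The curve is the standard step function over
#' score thresholds, (FPR, TPR) from (0, 0) to (1, 1), monotone in both
#' axes; its trapezoidal area equals the pair-counting AUC.
#'
#' @param scores Numeric score per compound (higher = more active-like).
#' @param labels True classes, `"active"`/`"inactive"`, both present.
#' @return An object of class `roc_curve`: list with `curve` (tibble of
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
compute_roc <- function(scores, labels) {
  labels <- as_class_labels(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (anyNA(scores)) stop("scores contain NA", call. = FALSE)
  n_act <- sum(labels == "active")
  n_in <- sum(labels == "inactive")
  if (n_act == 0L || n_in == 0L) {
    stop("ROC analysis needs both classes present", call. = FALSE)
  }
  # Mann-Whitney concordance via ranks (midranks handle ties as 1/2).
  r <- rank(scores)
  auc <- (sum(r[labels == "active"]) - n_act * (n_act + 1) / 2) / (n_act * n_in)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  act <- labels[ord] == "active"
  # one curve point per distinct threshold (ties collapse to one step)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  ctp <- cumsum(act)[last_of_tie]
  cfp <- cumsum(!act)[last_of_tie]
  curve <- tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, cfp / n_in),
    tpr = c(0, ctp / n_act)
  )
  structure(list(curve = curve, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$curve), x$auc))
  invisible(x)
}

#' Write ROC curve points to CSV
#'
#' @param roc A `roc_curve` object.
#' @param path Output path; two columns, `fpr` and `tpr`.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  write.csv(roc$curve[, c("fpr", "tpr")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
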