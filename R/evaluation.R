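#' Confusion counts from observed and predicted cleavage labels
#'
#' @param labels Observed labels: logical (`TRUE` = cleaved) or character
#'   `"cleaved"`/`"not_cleaved"`.
#' @param predictions Predicted labels, same conventions and length.
#' @return A list of class `confusion_counts` with integer fields `tp`
#'   (correctly predicted cleaved), `tn` (correctly predicted
#'   non-cleaved), `fp`, `fn`.
#' @export
count_confusion <- function(labels, predictions) {
  labels <- as_cleaved_logical(labels)
  predictions <- as_cleaved_logical(predictions)
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  confusion_counts(tp = sum(labels & predictions),
                   tn = sum(!labels & !predictions),
                   fp = sum(!labels & predictions),
                   fn = sum(labels & !predictions))
}

as_cleaved_logical <- function(x) {
  if (is.logical(x)) return(x)
  if (is.character(x)) {
    bad <- setdiff(unique(x), c("cleaved", "not_cleaved"))
    if (length(bad) > 0L) stop("unknown label(s): ",
                               paste(bad, collapse = ", "), call. = FALSE)
    return(x == "cleaved")
  }
  stop("labels must be logical or 'cleaved'/'not_cleaved'", call. = FALSE)
}

#' Build a confusion-count object directly
#'
#' @param tp,tn,fp,fn Non-negative integer cell counts.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  cells <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion cells must be non-negative integers", call. = FALSE)
  }
  structure(as.list(setNames(as.integer(cells), names(cells))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP=", x$tp, " TN=", x$tn, " FP=", x$fp,
      " FN=", x$fn, "\n", sep = "")
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Derived performance statistics from confusion counts
#'
#' Computes the standard suite: correct classification rate
#' `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' positive predictive power `TP/(TP+FP)`, negative predictive power
#' `TN/(TN+FN)`, and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Any statistic
#' whose denominator is zero is undefined and reported as `NA` (printed
#' as "undefined"), never silently propagated.
#'
#' @param counts A `confusion_counts` object.
#' @param auc Optional ROC AUC to carry alongside (probabilistic models).
#' @return A list of class `metrics_report` with fields `ccr`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `mcc`, `auc` and the
#'   originating `counts`.
#' @examples
#' compute_metrics(confusion_counts(tp = 181, tn = 1520, fp = 329, fn = 54))
#' @export
compute_metrics <- function(counts, auc = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion cells are zero", call. = FALSE)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  structure(list(
    ccr = (tp + tn) / total,
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp),
    ppv = safe_ratio(tp, tp + fp),
    npv = safe_ratio(tn, tn + fn),
    mcc = if (denom == 0) NA_real_ else (tp * tn - fp * fn) / denom,
    auc = auc,
    counts = counts), class = "metrics_report")
}

#' Round half away from zero
#'
#' Display rounding used in comparison tables (R's `round()` rounds half
#' to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 4L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

fmt_metric <- function(x, digits = 4L) {
  ifelse(is.na(x), "undefined",
         formatC(round_half_up(x, digits), format = "f", digits = digits))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (f in c("ccr", "sensitivity", "specificity", "ppv", "npv", "mcc")) {
    cat(sprintf("  %-12s %s\n", f, fmt_metric(x[[f]])))
  }
  if (!is.na(x$auc)) cat(sprintf("  %-12s %s\n", "auc", fmt_metric(x$auc)))
  invisible(x)
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve (sensitivity against 1 - specificity across
#' all thresholds), computed as the Mann-Whitney rank statistic: the
#' probability that a randomly chosen cleaved site outscores a randomly
#' chosen non-cleaved site, ties counted 1/2. Values below about 0.7 are
#' conventionally read as poor discrimination.
#'
#' @param labels Observed labels (logical or `"cleaved"`/`"not_cleaved"`);
#'   both classes must be present.
#' @param scores Numeric scores, higher = more likely cleaved.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as_cleaved_logical(labels)
  if (length(labels) != length(scores)) {
    stop("labels and scores differ in length", call. = FALSE)
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC AUC requires both classes", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a cleavage model on labelled sites
#'
#' Scores the sites, thresholds, counts the confusion cells and derives
#' the metric suite. ROC AUC is included for probabilistic models
#' (logistic/ANN); for the binary known-motif rule the full ROC is
#' degenerate and AUC is omitted.
#'
#' @param model A `cleavage_model`.
#' @param sites Labelled candidate-site data frame.
#' @param threshold Decision cutoff (default: the model's own).
#' @return A `metrics_report` (its `counts` field holds the confusion
#'   quadruple).
#' @export
evaluate_model <- function(model, sites, threshold = NULL) {
  stopifnot(is.data.frame(sites))
  if (nrow(sites) == 0L || !"cleaved" %in% names(sites)) {
    stop("evaluation requires labelled sites", call. = FALSE)
  }
  if (is.null(threshold)) threshold <- model$threshold
  scores <- predict_scores(model, sites)
  preds <- apply_threshold(scores, threshold)
  counts <- count_confusion(sites$cleaved, preds)
  auc <- if (model$kind == "known_motif" ||
             length(unique(sites$cleaved)) < 2L) {
    NA_real_
  } else {
    roc_auc(sites$cleaved, scores)
  }
  compute_metrics(counts, auc = auc)
}

COMPARISON_ROWS <- c("True Positives", "True Negatives", "False Positives",
                     "False Negatives", "Correct Classification",
                     "Sensitivity", "Specificity",
                     "Positive predictive power",
                     "Negative predictive power", "Correlation", "AUC")

#' Side-by-side model comparison table
#'
#' Lays out confusion counts and derived statistics as a criteria-by-model
#' matrix (counts, then the six derived statistics, then AUC), statistics
#' formatted to 4 decimals (half away from zero), undefined cells marked.
#' Models are also ranked by correct classification rate.
#'
#' @param results Named list (>= 2 entries) of `metrics_report` objects,
#'   e.g. from [evaluate_model()].
#' @return An object of class `model_comparison`: `$table` (character
#'   matrix, 11 criteria rows x models), `$ranking` (model names by
#'   decreasing CCR).
#' @export
compare_models <- function(results) {
  if (!is.list(results) || length(results) < 2L || is.null(names(results))) {
    stop("compare_models() needs a named list of at least two reports",
         call. = FALSE)
  }
  stopifnot(all(vapply(results, inherits, logical(1), "metrics_report")))
  cols <- lapply(results, function(r) {
    c(as.character(c(r$counts$tp, r$counts$tn, r$counts$fp, r$counts$fn)),
      fmt_metric(c(r$ccr, r$sensitivity, r$specificity, r$ppv, r$npv,
                   r$mcc)),
      if (is.na(r$auc)) "-" else fmt_metric(r$auc))
  })
  tab <- do.call(cbind, cols)
  rownames(tab) <- COMPARISON_ROWS
  colnames(tab) <- names(results)
  ccrs <- vapply(results, `[[`, numeric(1), "ccr")
  structure(list(table = tab,
                 ranking = names(sort(ccrs, decreasing = TRUE))),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, quote = FALSE)
  cat("\nRanking by correct classification rate: ",
      paste(x$ranking, collapse = " > "), "\n", sep = "")
  invisible(x)
}
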