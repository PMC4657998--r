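#' Partition samples into cross-validation folds
#'
#' Returns a fold id per sample, with fold sizes differing by at most one.
#' Stratified mode balances the per-class counts across folds (each class's
#' surplus samples are placed in the currently smallest folds, so overall
#' fold sizes still differ by at most one); if any class is smaller than the
#' number of folds, stratification degrades to a plain partition with a
#' warning.
#'
#' @param n number of samples.
#' @param k number of folds, `2 <= k <= n`.
#' @param labels class labels (required for `stratified = TRUE`).
#' @param stratified balance class counts per fold.
#' @param seed optional seed; the assignment is deterministic given it.
#' @return integer vector of fold ids in `1:k`, with attribute `"k"`.
#' @export
make_folds <- function(n, k, labels = NULL, stratified = FALSE, seed = NULL) {
  if (k < 2 || k > n)
    .arg_error(sprintf("need 2 <= k <= n (k = %d, n = %d)", k, n))
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(n)
  if (stratified) {
    if (is.null(labels) || length(labels) != n)
      .arg_error("stratified folds require one label per sample")
    cls_sizes <- sort(table(labels), decreasing = TRUE)
    if (min(cls_sizes) < k) {
      warning("a class has fewer samples than folds; using plain partition")
      stratified <- FALSE
    } else {
      totals <- integer(k)
      for (cl in names(cls_sizes)) {
        idx <- which(labels == cl)
        nc <- length(idx)
        base <- nc %/% k
        r <- nc %% k
        # extras go to the currently smallest folds, ties broken at random
        ord <- sample.int(k)
        ord <- ord[order(totals[ord])]
        counts <- rep(base, k)
        if (r > 0) counts[ord[seq_len(r)]] <- base + 1
        folds[sample(idx)] <- rep(seq_len(k), counts)
        totals <- totals + counts
      }
    }
  }
  if (!stratified)
    folds <- sample(rep_len(seq_len(k), n))
  attr(folds, "k") <- k
  folds
}

#' Confusion-matrix metrics for a two-class prediction
#'
#' Exact rational arithmetic: `accuracy = (TP + TN) / n`,
#' `sensitivity = TP / (TP + FN)` (true-positive rate among cancer cases),
#' `specificity = TN / (TN + FP)`.  A rate with an empty denominator is
#' returned as `NA` and flagged.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive the positive (cancer) class.
#' @return a list with `tp`, `fp`, `tn`, `fn`, `n`, `accuracy`,
#'   `sensitivity`, `specificity` and the flags
#'   `sensitivity_defined` / `specificity_defined`.
#' @export
confusion_metrics <- function(y_true, y_pred, positive) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 1)
    .arg_error("y_true and y_pred must have equal length >= 1")
  seen <- unique(c(y_true, y_pred))
  other <- setdiff(seen, positive)
  if (length(other) > 1)
    .contract_error(sprintf("unknown label value(s): %s",
                            paste(setdiff(other, other[1]), collapse = ", ")))
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  n <- length(y_true)
  list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
       accuracy = (tp + tn) / n,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       sensitivity_defined = tp + fn > 0,
       specificity_defined = tn + fp > 0)
}

#' Six-number summary (Min, 1st Qu., Median, Mean, 3rd Qu., Max)
#'
#' The accuracy-table format of the study design this package implements.
#' Quartiles use linear interpolation of order statistics at position
#' `(n - 1) p + 1` (type-7 quantiles, R's default).
#'
#' @param values numeric vector, length >= 1, no missing values.
#' @return named numeric vector
#'   `c(min, q1, median, mean, q3, max)`, classed `summary_row`.
#' @export
six_number_summary <- function(values) {
  if (length(values) < 1) .arg_error("need at least one value")
  if (anyNA(values)) .arg_error("missing values in summary input")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(c(min = min(values), q1 = q[1], median = q[2],
              mean = mean(values), q3 = q[3], max = max(values)),
            class = c("summary_row", "numeric"))
}

#' @export
print.summary_row <- function(x, digits = 4, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}

#' Chance agreement with fixed marginal frequencies
#'
#' Expected accuracy of a random classifier whose predicted class
#' frequencies match the true ones: `p^2 + q^2` with `p = n_pos / n`.
#' For 59 cancer / 43 control this is 0.5123 — the reference level against
#' which permutation-null accuracies are judged.
#'
#' @param n_pos,n_neg positive/negative class sizes, both > 0.
#' @return the expected agreement as a fraction.
#' @export
chance_agreement <- function(n_pos, n_neg) {
  if (n_pos <= 0 || n_neg <= 0)
    .arg_error("both class sizes must be positive")
  p <- n_pos / (n_pos + n_neg)
  p^2 + (1 - p)^2
}

#' Pooled receiver operating characteristic curve
#'
#' Sweeps thresholds over the distinct scores (a sample is called positive
#' when its score is >= the threshold) and computes the trapezoidal AUC.
#' For cross-validation results (see [pooled_roc.voc_cv]) the per-sample
#' score is the mean predicted positive-class probability over all repeats
#' in which the sample sat in a test fold.  Constant scores yield a
#' single-point curve with AUC 0.5.
#'
#' @param x numeric scores (higher = more positive), or a `voc_cv` result.
#' @param ... passed to methods.
#' @return an object of class `roc_data` with `thresholds`, `tpr`, `fpr`
#'   and `auc`.
#' @export
pooled_roc <- function(x, ...) UseMethod("pooled_roc")

#' @rdname pooled_roc
#' @param labels true labels aligned with the scores.
#' @param positive positive-class name.
#' @export
pooled_roc.default <- function(x, labels, positive, ...) {
  scores <- as.numeric(x)
  truth <- as.character(labels) == positive
  if (length(scores) != length(truth))
    .arg_error("scores and labels must be aligned")
  P <- sum(truth); N <- sum(!truth)
  if (P < 1 || N < 1)
    .arg_error("need at least one positive and one negative case")
  if (length(unique(scores)) == 1) {
    return(structure(list(thresholds = scores[1], tpr = 1, fpr = 1, auc = 0.5),
                     class = "roc_data"))
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(truth & scores >= t) / P, numeric(1))
  fpr <- vapply(thr, function(t) sum(!truth & scores >= t) / N, numeric(1))
  thr <- c(Inf, thr); tpr <- c(0, tpr); fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_data")
}

#' @export
print.roc_data <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
plot.roc_data <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate (1 - specificity)",
       ylab = "True positive rate (sensitivity)",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}
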