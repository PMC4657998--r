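# Validation engines: repeated k-fold cross-validation, repeated double
# (nested) cross-validation, and their Monte-Carlo label-permutation
# variants.  All randomness flows from a single master seed through a seed
# cascade (master -> per-repeat -> per-fold), so any repeat is reproducible
# in isolation and identical master seeds give bit-identical results.

#' Specify a classifier for the validation engines
#'
#' @param model `"forest"` or `"lda"`.
#' @param n_trees forest size (default 500).
#' @param mtry fixed forest mtry; `NULL` = `floor(sqrt(p))`.
#' @param ridge fixed LDA ridge multiplier (default `1e-6`).
#' @param priors LDA priors, `"empirical"` or `"uniform"`.
#' @param tune in repeated double CV, let the inner loop choose the forest
#'   `mtry` over the grid `floor(seq(sqrt(p), p, length.out = 3))` or the
#'   LDA ridge over `ridge_grid` (default `TRUE`; ignored by plain repeated
#'   k-fold CV, which has no tuning loop).
#' @param ridge_grid candidate LDA ridge multipliers for the inner loop.
#' @param log_scale_covariates for LDA, log-transform and z-score continuous
#'   covariate columns (e.g. PSA) on the training portion (default `TRUE`;
#'   the forest always receives raw values).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(model = c("forest", "lda"), n_trees = 500,
                       mtry = NULL, ridge = 1e-6,
                       priors = c("empirical", "uniform"), tune = TRUE,
                       ridge_grid = c(1e-6, 1e-3),
                       log_scale_covariates = TRUE) {
  model <- match.arg(model)
  priors <- match.arg(priors)
  structure(list(model = model, n_trees = n_trees, mtry = mtry,
                 ridge = ridge, priors = priors, tune = tune,
                 ridge_grid = ridge_grid,
                 log_scale_covariates = log_scale_covariates),
            class = "model_spec")
}

#' Specify a resampling plan
#'
#' @param kind `"repeated_kfold"` (flat: `repeats` x `k` folds, one metric
#'   record per fold) or `"repeated_double"` (nested: `repeats` outer
#'   repeats of `k_outer` folds, an inner tuning loop of
#'   `inner_repeats` x `inner_k`, one pooled metric record per outer
#'   repeat).
#' @param repeats outer repeats (default 30).
#' @param k folds of the flat scheme (default 10).
#' @param k_outer outer folds of the nested scheme (default 3).
#' @param inner_repeats,inner_k inner tuning loop of the nested scheme
#'   (defaults 30 and 10).
#' @param permute_labels Monte-Carlo variant: randomly permute the class
#'   labels (class sizes preserved) at the start of each repeat.
#' @param selection_mode `"full_data"` (feature panel fixed before CV) or
#'   `"nested"` (panel re-selected inside each outer calibration set).
#' @param stratified stratify folds by class (default `TRUE`).
#' @param seed master seed of the scheme.
#' @return an object of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("repeated_kfold", "repeated_double"),
                      repeats = 30, k = 10, k_outer = 3,
                      inner_repeats = 30, inner_k = 10,
                      permute_labels = FALSE,
                      selection_mode = c("full_data", "nested"),
                      stratified = TRUE, seed = 1) {
  kind <- match.arg(kind)
  selection_mode <- match.arg(selection_mode)
  if (kind == "repeated_double" && (k_outer < 2 || inner_k < 2))
    .arg_error("repeated_double requires k_outer >= 2 and inner_k >= 2")
  if (repeats < 1) .arg_error("repeats must be >= 1")
  structure(list(kind = kind, repeats = repeats, k = k, k_outer = k_outer,
                 inner_repeats = inner_repeats, inner_k = inner_k,
                 permute_labels = permute_labels,
                 selection_mode = selection_mode,
                 stratified = stratified, seed = as.integer(seed)),
            class = "cv_scheme")
}

# internal: design matrix for a feature set that may mix VOC features and
# covariate columns; returns the matrix plus which columns are covariates
.assemble_design <- function(table, feature_set) {
  if (!length(feature_set)) .arg_error("feature_set must be non-empty")
  feats <- intersect(feature_set, colnames(table$values))
  covs <- intersect(feature_set, names(table$covariates))
  unknown <- setdiff(feature_set, c(feats, covs))
  if (length(unknown))
    .contract_error(sprintf("unknown feature(s): %s",
                            paste(unknown, collapse = ", ")))
  parts <- list()
  if (length(feats)) parts$f <- table$values[, feats, drop = FALSE]
  if (length(covs)) parts$c <- as.matrix(table$covariates[covs])
  x <- do.call(cbind, unname(parts))
  rownames(x) <- rownames(table$values)
  list(x = x[, feature_set, drop = FALSE], covariate_cols = covs)
}

# internal: fit the specified model with fixed hyperparameters
.fit_model <- function(spec, x, y, positive, covariate_cols, seed,
                       mtry = spec$mtry, ridge = spec$ridge) {
  if (spec$model == "forest") {
    fit_forest(x, y, n_trees = spec$n_trees, mtry = mtry, seed = seed,
               positive = positive)
  } else {
    fit_lda(x, y, priors = spec$priors, ridge = ridge, positive = positive,
            log_scale = if (spec$log_scale_covariates) covariate_cols
                        else character())
  }
}

# internal: mean fold accuracy of a candidate hyperparameter on the
# calibration data, over inner_repeats x inner_k folds
.inner_cv_accuracy <- function(spec, x, y, positive, covariate_cols,
                               inner_repeats, inner_k, stratified, seed,
                               mtry = spec$mtry, ridge = spec$ridge) {
  accs <- c()
  for (ir in seq_len(inner_repeats)) {
    folds <- make_folds(nrow(x), min(inner_k, nrow(x)), labels = y,
                        stratified = stratified,
                        seed = derive_seed(seed, ir))
    k <- attr(folds, "k")
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) next
      fit <- tryCatch(
        .fit_model(spec, x[tr, , drop = FALSE], y[tr], positive,
                   covariate_cols, seed = derive_seed(seed, ir, f),
                   mtry = mtry, ridge = ridge),
        error = function(e) NULL)
      if (is.null(fit)) next
      pred <- predict(fit, x[!tr, , drop = FALSE])
      accs <- c(accs, mean(as.character(pred) == as.character(y[!tr])))
    }
  }
  if (!length(accs)) NA_real_ else mean(accs)
}

# internal: choose hyperparameters on the calibration data (model tuning
# loop of the nested scheme); returns list(mtry=, ridge=)
.tune_model <- function(spec, x, y, positive, covariate_cols, scheme, seed) {
  p <- ncol(x)
  if (spec$model == "forest") {
    # caret-style mtry grid from floor(sqrt(p)) up to p; mtry = 1 is
    # excluded deliberately: single-feature splits dilute the vote toward
    # the training majority and an accuracy-driven tuner would select that
    # degenerate setting under label permutation, inflating the null
    grid <- unique(pmax(1L, pmin(p, floor(seq(max(sqrt(p), 2), p,
                                              length.out = 3)))))
    if (!spec$tune || !is.null(spec$mtry) || length(grid) == 1)
      return(list(mtry = if (is.null(spec$mtry)) max(1L, floor(sqrt(p)))
                         else spec$mtry,
                  ridge = spec$ridge, grid = grid, inner_accuracy = NA_real_))
    accs <- vapply(grid, function(m)
      .inner_cv_accuracy(spec, x, y, positive, covariate_cols,
                         scheme$inner_repeats, scheme$inner_k,
                         scheme$stratified, seed = derive_seed(seed, m),
                         mtry = m),
      numeric(1))
    best <- which.max(accs)       # ties -> first candidate
    list(mtry = grid[best], ridge = spec$ridge, grid = grid,
         inner_accuracy = accs[best])
  } else {
    grid <- spec$ridge_grid
    if (!spec$tune || length(grid) <= 1)
      return(list(mtry = NULL, ridge = spec$ridge, grid = grid,
                  inner_accuracy = NA_real_))
    accs <- vapply(seq_along(grid), function(i)
      .inner_cv_accuracy(spec, x, y, positive, covariate_cols,
                         scheme$inner_repeats, scheme$inner_k,
                         scheme$stratified, seed = derive_seed(seed, i),
                         ridge = grid[i]),
      numeric(1))
    best <- which.max(accs)
    list(mtry = NULL, ridge = grid[best], grid = grid,
         inner_accuracy = accs[best])
  }
}

.metric_row <- function(unit, r, f, cm) {
  data.frame(unit = unit, repeat_index = r,
             fold_index = if (is.na(f)) NA_integer_ else f,
             accuracy = cm$accuracy, sensitivity = cm$sensitivity,
             specificity = cm$specificity, n_test = cm$n,
             tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn)
}

#' Repeated k-fold cross-validation
#'
#' For each of `repeats` x `k` folds, fits the model on the training portion
#' (restricted to `feature_set`) and predicts the held-out fold, emitting
#' one fold-level metric record (30 repeats x 10 folds = 300 records at the
#' defaults).  With `permute_labels` the class labels are randomly permuted
#' (class sizes preserved) at the start of each repeat, giving the
#' Monte-Carlo chance reference.
#'
#' @param table a `feature_table`.
#' @param spec a [model_spec()].
#' @param feature_set non-empty character vector of feature and/or covariate
#'   column names.
#' @param scheme a [cv_scheme()] with `kind = "repeated_kfold"`.
#' @return an object of class `voc_cv`: metric records (`$records`), the
#'   per-sample x per-repeat score matrix (`$scores`), labels and scheme.
#' @export
repeated_kfold_cv <- function(table, spec, feature_set, scheme) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "model_spec"),
            inherits(scheme, "cv_scheme"))
  if (scheme$kind != "repeated_kfold")
    .arg_error("scheme$kind must be 'repeated_kfold'")
  d <- .assemble_design(table, feature_set)
  y0 <- table$labels
  n <- nrow(d$x)
  pos <- table$positive
  records <- vector("list", scheme$repeats * scheme$k)
  scores <- matrix(NA_real_, n, scheme$repeats,
                   dimnames = list(rownames(d$x), NULL))
  skipped <- 0L
  ri <- 0L
  for (r in seq_len(scheme$repeats)) {
    rs <- derive_seed(scheme$seed, r)
    y <- y0
    if (scheme$permute_labels) {
      set.seed(derive_seed(rs, 991))
      y <- y0[sample.int(n)]
    }
    folds <- make_folds(n, scheme$k, labels = y,
                        stratified = scheme$stratified,
                        seed = derive_seed(rs, 992))
    for (f in seq_len(scheme$k)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) { skipped <- skipped + 1L; next }
      fit <- tryCatch(
        .fit_model(spec, d$x[tr, , drop = FALSE], y[tr], pos,
                   d$covariate_cols, seed = derive_seed(rs, f)),
        error = function(e) NULL)
      if (is.null(fit)) { skipped <- skipped + 1L; next }
      te <- d$x[!tr, , drop = FALSE]
      pred <- predict(fit, te)
      cm <- confusion_metrics(y[!tr], pred, pos)
      ri <- ri + 1L
      records[[ri]] <- .metric_row("fold", r, f, cm)
      scores[!tr, r] <- predict(fit, te, type = "prob")
    }
  }
  structure(
    list(records = do.call(rbind, records[seq_len(ri)]),
         scores = scores, labels = y0, positive = pos,
         feature_set = feature_set, spec = spec, scheme = scheme,
         skipped = skipped),
    class = "voc_cv")
}

#' Repeated double (nested) cross-validation
#'
#' Per outer repeat the samples are split into `k_outer` (default 3) folds.
#' For each outer fold the remaining calibration data drives the inner loop
#' (`inner_repeats` x `inner_k`, default 30 x 10) to tune the model — and,
#' with `selection_mode = "nested"`, to select the feature panel — after
#' which the tuned model is refit on the full calibration set and predicts
#' the held-out outer fold.  Predictions from the `k_outer` folds are pooled
#' into one confusion matrix, giving one metric record per outer repeat.
#' With `permute_labels` the labels are permuted at the start of each outer
#' repeat (the feature panel is *not* re-selected from permuted labels).
#'
#' @param table a `feature_table`.
#' @param spec a [model_spec()].
#' @param feature_set feature panel (required for
#'   `selection_mode = "full_data"`).
#' @param scheme a [cv_scheme()] with `kind = "repeated_double"`.
#' @param selector for `selection_mode = "nested"`: a
#'   `function(x, y, seed)` returning a character vector of selected
#'   columns; an empty selection falls back to all columns (logged).
#' @return an object of class `voc_cv` with one record per outer repeat.
#' @export
repeated_double_cv <- function(table, spec, feature_set = NULL, scheme,
                               selector = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "model_spec"),
            inherits(scheme, "cv_scheme"))
  if (scheme$kind != "repeated_double")
    .arg_error("scheme$kind must be 'repeated_double'")
  nested <- scheme$selection_mode == "nested"
  if (nested && !is.function(selector))
    .arg_error("nested selection requires a selector function")
  if (!nested && is.null(feature_set))
    .arg_error("full_data selection requires a feature_set")
  universe <- if (nested)
    c(colnames(table$values), names(table$covariates)) else feature_set
  d <- .assemble_design(table, universe)
  y0 <- table$labels
  n <- nrow(d$x)
  pos <- table$positive
  records <- vector("list", scheme$repeats)
  scores <- matrix(NA_real_, n, scheme$repeats,
                   dimnames = list(rownames(d$x), NULL))
  tuning_log <- vector("list", scheme$repeats)
  empty_selections <- 0L
  for (r in seq_len(scheme$repeats)) {
    rs <- derive_seed(scheme$seed, r)
    y <- y0
    if (scheme$permute_labels) {
      set.seed(derive_seed(rs, 991))
      y <- y0[sample.int(n)]
    }
    outer <- make_folds(n, scheme$k_outer, labels = y,
                        stratified = scheme$stratified,
                        seed = derive_seed(rs, 992))
    pred_all <- rep(NA_character_, n)
    rlog <- vector("list", scheme$k_outer)
    for (f in seq_len(scheme$k_outer)) {
      cal <- outer != f
      feats_f <- universe
      if (nested) {
        feats_f <- selector(d$x[cal, , drop = FALSE], y[cal],
                            derive_seed(rs, f, 7))
        if (!length(feats_f)) {          # empty panel -> all features
          feats_f <- universe
          empty_selections <- empty_selections + 1L
        }
      }
      xcal <- d$x[cal, feats_f, drop = FALSE]
      cov_f <- intersect(d$covariate_cols, feats_f)
      tuned <- .tune_model(spec, xcal, y[cal], pos, cov_f, scheme,
                           seed = derive_seed(rs, f, 8))
      fit <- .fit_model(spec, xcal, y[cal], pos, cov_f,
                        seed = derive_seed(rs, f, 9),
                        mtry = tuned$mtry, ridge = tuned$ridge)
      te <- d$x[!cal, feats_f, drop = FALSE]
      pred_all[!cal] <- as.character(predict(fit, te))
      scores[!cal, r] <- predict(fit, te, type = "prob")
      rlog[[f]] <- list(fold = f, mtry = tuned$mtry, ridge = tuned$ridge,
                        inner_accuracy = tuned$inner_accuracy,
                        n_features = length(feats_f))
    }
    cm <- confusion_metrics(y, pred_all, pos)
    records[[r]] <- .metric_row("outer_repeat", r, NA, cm)
    tuning_log[[r]] <- rlog
  }
  structure(
    list(records = do.call(rbind, records), scores = scores, labels = y0,
         positive = pos, feature_set = feature_set, spec = spec,
         scheme = scheme, tuning = tuning_log,
         empty_selections = empty_selections),
    class = "voc_cv")
}

#' Monte-Carlo permutation null of a validation scheme
#'
#' Re-runs the scheme with class labels randomly permuted at the start of
#' each repeat (class sizes preserved; the feature panel is held fixed).
#' The resulting mean accuracy estimates the agreement achievable by chance
#' for the full modelling process.
#'
#' @inheritParams repeated_double_cv
#' @return a `voc_cv` object from the underlying engine.
#' @export
monte_carlo_null <- function(table, spec, feature_set, scheme,
                             selector = NULL) {
  scheme$permute_labels <- TRUE
  if (scheme$kind == "repeated_kfold")
    repeated_kfold_cv(table, spec, feature_set, scheme)
  else
    repeated_double_cv(table, spec, feature_set, scheme, selector)
}

#' Mean accuracy of a cross-validation result
#' @param cv a `voc_cv`.
#' @return mean of the per-record accuracies.
#' @export
mean_accuracy <- function(cv) mean(cv$records$accuracy)

#' @export
print.voc_cv <- function(x, ...) {
  s <- x$scheme
  cat(sprintf("%s%s: %d records, %s model, %d features\n",
              if (s$permute_labels) "Monte-Carlo " else "",
              if (s$kind == "repeated_kfold")
                sprintf("repeated %d-fold CV (%d repeats)", s$k, s$repeats)
              else
                sprintf("repeated double CV (%d outer repeats, %d/%d folds)",
                        s$repeats, s$k_outer, s$inner_k),
              nrow(x$records), x$spec$model,
              length(x$feature_set %||% character())))
  cat(sprintf("Mean accuracy: %.4f\n", mean_accuracy(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a cross-validation result in the six-number table format
#'
#' Flat repeated k-fold results are summarized at fold level (accuracy
#' only); repeated double CV results at outer-repeat level with
#' mean/min/median/max of accuracy, sensitivity and specificity.
#'
#' @param object a `voc_cv`.
#' @param ... unused.
#' @return for `repeated_kfold`, a `summary_row`; for `repeated_double`, a
#'   data.frame with one row per metric.
#' @export
summary.voc_cv <- function(object, ...) {
  rec <- object$records
  if (object$scheme$kind == "repeated_kfold")
    return(six_number_summary(rec$accuracy))
  metric_tbl <- function(v) {
    v <- v[!is.na(v)]
    data.frame(mean = mean(v), min = min(v), median = stats::median(v),
               max = max(v))
  }
  out <- rbind(accuracy = metric_tbl(rec$accuracy),
               sensitivity = metric_tbl(rec$sensitivity),
               specificity = metric_tbl(rec$specificity))
  out
}

#' @rdname pooled_roc
#' @export
pooled_roc.voc_cv <- function(x, ...) {
  tested <- rowSums(!is.na(x$scores)) > 0
  pooled <- rowMeans(x$scores[tested, , drop = FALSE], na.rm = TRUE)
  pooled_roc.default(pooled, x$labels[tested], x$positive)
}
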