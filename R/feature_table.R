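#' Sample-by-feature table of VOC presence or abundance
#'
#' The universal currency of the pipeline: a numeric sample x feature matrix
#' of non-negative relative abundances or \{0,1\} presence flags, a two-class
#' label per sample (e.g. prostate cancer vs control), and optional
#' continuous per-sample covariates such as serum PSA (ng/mL).
#'
#' @param values numeric matrix (samples x features) with unique row names
#'   (sample ids) and column names (feature names); non-negative, no missing
#'   values (the pipeline has no imputation step).
#' @param labels character or factor of length `nrow(values)` with exactly
#'   two distinct values, both non-empty.
#' @param covariates optional data.frame of numeric per-sample covariates
#'   (one row per sample), e.g. `data.frame(psa = ...)`.
#' @param positive name of the positive class for sensitivity/specificity.
#'   Defaults to `"cancer"` when present among the labels, otherwise the
#'   second factor level.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, labels, covariates = NULL, positive = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    .contract_error("'values' must be a numeric matrix")
  if (anyNA(values))
    .contract_error("missing feature values are not supported (no imputation)")
  if (any(values < 0))
    .contract_error("feature values must be non-negative")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    .contract_error("'values' must have feature names as column names")
  if (anyDuplicated(rownames(values)))
    .contract_error("duplicate sample ids")
  if (anyDuplicated(colnames(values)))
    .contract_error("duplicate feature names")

  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    .contract_error("one label per sample required")
  lev <- sort(unique(labels))
  if (length(lev) != 2)
    .contract_error(sprintf(
      "labels must have exactly two distinct classes (found %d)", length(lev)))
  if (is.null(positive))
    positive <- if ("cancer" %in% lev) "cancer" else lev[2]
  if (!positive %in% lev)
    .arg_error(sprintf("positive class '%s' not among labels", positive))
  negative <- setdiff(lev, positive)
  labels <- factor(labels, levels = c(negative, positive))

  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(values))
      .contract_error("covariates must have one row per sample")
    if (!all(vapply(covariates, is.numeric, logical(1))))
      .contract_error("covariates must be numeric")
    if (anyNA(covariates))
      .contract_error("missing covariate values are not supported")
    if (any(names(covariates) %in% colnames(values)))
      .contract_error("covariate names collide with feature names")
    rownames(covariates) <- rownames(values)
  }

  structure(
    list(values = values, labels = labels, covariates = covariates,
         positive = positive,
         binary = all(values %in% c(0, 1))),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x$values), "samples x", ncol(x$values),
      "features", if (x$binary) "(binary presence/absence)" else "(abundances)",
      "\n")
  tab <- table(x$labels)
  cat("Classes:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "),
      sprintf("(positive: %s)\n", x$positive))
  if (!is.null(x$covariates))
    cat("Covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / features in a feature table
#' @param table a `feature_table`.
#' @return integer count.
#' @export
n_samples <- function(table) nrow(table$values)

#' @rdname n_samples
#' @export
n_features <- function(table) ncol(table$values)

#' Read a cohort CSV into a feature table
#'
#' Expects one sample per row with a header: an id column, a two-class label
#' column, any declared covariate columns (e.g. PSA), and all remaining
#' columns treated as numeric VOC features.
#'
#' @param path CSV file path.
#' @param label_column name of the class column (default `"class"`).
#' @param covariate_columns names of continuous covariate columns.
#' @param id_column name of the sample-id column; if absent from the file,
#'   row numbers are used as ids.
#' @param positive optional positive-class name (see [feature_table()]).
#' @return a validated `feature_table`.
#' @export
read_feature_table <- function(path, label_column = "class",
                               covariate_columns = character(),
                               id_column = "sample_id", positive = NULL) {
  if (!file.exists(path)) .arg_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_column %in% names(df))
    .format_error(sprintf("label column '%s' missing from %s",
                          label_column, path))
  missing_cov <- setdiff(covariate_columns, names(df))
  if (length(missing_cov))
    .format_error(sprintf("covariate column(s) missing: %s",
                          paste(missing_cov, collapse = ", ")))
  labels <- as.character(df[[label_column]])
  if (length(unique(labels)) != 2)
    .contract_error(sprintf(
      "label column '%s' must hold exactly two distinct values (found %d)",
      label_column, length(unique(labels))))

  if (id_column %in% names(df)) {
    ids <- as.character(df[[id_column]])
    if (anyDuplicated(ids))
      .contract_error("duplicate sample id in input file")
  } else {
    ids <- as.character(seq_len(nrow(df)))
  }

  feat_cols <- setdiff(names(df), c(id_column, label_column, covariate_columns))
  vals <- matrix(NA_real_, nrow(df), length(feat_cols),
                 dimnames = list(ids, feat_cols))
  for (cn in feat_cols) {
    col <- df[[cn]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      .format_error(sprintf(
        "non-numeric feature value '%s' at row %d, column '%s'",
        col[bad[1]], bad[1], cn))
    if (anyNA(num))
      .contract_error(sprintf("missing value in feature column '%s'", cn))
    vals[, cn] <- num
  }
  cov <- if (length(covariate_columns)) df[covariate_columns] else NULL
  feature_table(vals, labels, covariates = cov, positive = positive)
}

#' Write a feature table as a cohort CSV
#'
#' Emits the same dialect [read_feature_table()] reads (header row; columns
#' `sample_id`, `class`, covariates, then features).  Numeric values are
#' printed with 17 significant digits so a write/read round trip reproduces
#' the table bit-exactly.
#'
#' @param table a `feature_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  fmt <- function(x) sub("^(-?\\d+)\\.0*$", "\\1", sprintf("%.17g", x))
  df <- data.frame(sample_id = rownames(table$values),
                   class = as.character(table$labels),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(table$covariates))
    for (cn in names(table$covariates)) df[[cn]] <- fmt(table$covariates[[cn]])
  for (cn in colnames(table$values)) df[[cn]] <- fmt(table$values[, cn])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert abundances to presence/absence flags
#'
#' A feature is scored present (1) in a sample when its abundance strictly
#' exceeds `threshold`; detection by the GC-MS pipeline (any positive
#' abundance in a processed table) is equated with presence at the default
#' threshold of 0.  Idempotent on already-binary tables.
#'
#' @param table a `feature_table` of abundances (or already binary).
#' @param threshold non-negative detection threshold (default 0).
#' @return a binary `feature_table`; labels and covariates unchanged.
#' @export
binarize <- function(table, threshold = 0) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0)
    .arg_error("'threshold' must be a single non-negative number")
  vals <- (table$values > threshold) + 0
  dimnames(vals) <- dimnames(table$values)
  feature_table(vals, table$labels, table$covariates, table$positive)
}

#' Dual prevalence filter for binary VOC tables
#'
#' Removes compounds present in fewer than `low` (default 20%) of samples in
#' *both* classes (relatively rare) or in more than `high` (default 90%) of
#' samples in *both* classes (relatively common) before modelling.  Both
#' comparisons are strict, and both are conjunctions over the two classes: a
#' feature rare in one class only is kept.
#'
#' @param table a binary `feature_table` with both classes non-empty.
#' @param low rare-side prevalence bound (fraction).
#' @param high common-side prevalence bound (fraction); `0 <= low < high <= 1`.
#' @return a list with components `table` (the filtered `feature_table`,
#'   original feature order preserved) and `report`, a `filter_report` with
#'   fields `kept`, `removed_rare`, `removed_common` (a disjoint partition of
#'   the original feature names) and `prevalence` (feature x class matrix of
#'   exact per-class presence fractions).
#' @export
prevalence_filter <- function(table, low = 0.20, high = 0.90) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$binary)
    .contract_error("prevalence_filter requires a binary table; run binarize()")
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1 ||
      length(high) != 1 || is.na(low) || is.na(high) ||
      low < 0 || high > 1 || low >= high)
    .arg_error("need 0 <= low < high <= 1")

  cls <- levels(table$labels)
  n_by <- table(table$labels)
  # per-class presence counts -> exact fractions
  counts <- rowsum(table$values, group = table$labels)   # class x feature
  prev <- t(counts / as.vector(n_by[rownames(counts)]))  # feature x class
  colnames(prev) <- rownames(counts)

  rare <- prev[, 1] < low & prev[, 2] < low
  common <- prev[, 1] > high & prev[, 2] > high
  keep <- !(rare | common)

  feats <- colnames(table$values)
  report <- structure(
    list(kept = feats[keep],
         removed_rare = feats[rare],
         removed_common = feats[common],
         prevalence = prev,
         low = low, high = high),
    class = "filter_report")

  filtered <- table
  filtered$values <- table$values[, keep, drop = FALSE]
  filtered$binary <- TRUE
  list(table = filtered, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "Prevalence filter (< %g rare / > %g common, in both classes):\n",
    x$low, x$high))
  cat(sprintf("  kept %d, removed %d rare, removed %d common\n",
              length(x$kept), length(x$removed_rare),
              length(x$removed_common)))
  invisible(x)
}
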