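#' Random-forest classifier for VOC panels
#'
#' A thin, seed-deterministic wrapper around [randomForest::randomForest()]
#' (Breiman's random forest: CART-style trees grown on bootstrap samples
#' with `mtry` random candidate features per split, Gini criterion).  With
#' `mtry = p` every feature is available at each split, which is the bagged
#' decision-tree ensemble used as the second tree-based ranker in recursive
#' feature elimination.
#'
#' @param x numeric matrix or data.frame of predictors (named columns).
#' @param y two-class factor or character vector.
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split; default `floor(sqrt(p))`, capped at
#'   `p`; must be >= 1.
#' @param seed integer seed; the same seed reproduces the forest exactly.
#' @param positive positive-class name (default `"cancer"` when present).
#' @return an object of class `voc_forest` with the fitted ensemble, the
#'   training class priors, and the out-of-bag accuracy estimate.
#' @export
fit_forest <- function(x, y, n_trees = 500, mtry = NULL, seed = NULL,
                       positive = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2)
    .contract_error("fit_forest requires exactly two classes")
  if (nrow(x) < 2) .contract_error("need at least 2 samples")
  if (is.null(positive)) positive <- if ("cancer" %in% lev) "cancer" else lev[2]
  negative <- setdiff(lev, positive)
  yf <- factor(y, levels = c(negative, positive))

  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  if (mtry < 1) .arg_error("mtry must be >= 1")
  mtry <- min(mtry, p)

  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x, yf, ntree = n_trees, mtry = mtry)

  pri <- as.vector(table(yf)) / length(yf)
  names(pri) <- levels(yf)
  structure(
    list(rf = rf, n_trees = n_trees, mtry = mtry,
         feature_names = colnames(x),
         levels = levels(yf), positive = positive, priors = pri,
         oob_estimate = 1 - unname(rf$err.rate[n_trees, "OOB"]),
         seed = seed),
    class = "voc_forest")
}

#' Predict from a fitted forest
#'
#' The score is the fraction of tree votes for the positive class; the label
#' is the majority vote, with exact 50/50 ties broken toward the class with
#' the larger training prior (positive class if priors are equal).
#'
#' @param object a `voc_forest`.
#' @param newdata matrix/data.frame with the training columns, matched by
#'   name.
#' @param type `"class"` or `"prob"` (positive-class vote fraction).
#' @param ... unused.
#' @return factor or numeric vector.
#' @export
predict.voc_forest <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$feature_names))
      .contract_error("newdata has the wrong number of columns")
    colnames(newdata) <- object$feature_names
  }
  if (!all(object$feature_names %in% colnames(newdata)))
    .contract_error(sprintf(
      "newdata lacks feature(s): %s",
      paste(setdiff(object$feature_names, colnames(newdata)), collapse = ", ")))
  newdata <- newdata[, object$feature_names, drop = FALSE]
  votes <- predict(object$rf, newdata, type = "prob")[, object$positive]
  if (type == "prob") return(unname(votes))
  tie_class <- names(object$priors)[which.max(object$priors)]
  if (object$priors[1] == object$priors[2]) tie_class <- object$positive
  lab <- ifelse(votes > 0.5, object$positive,
                ifelse(votes < 0.5, object$levels[1], tie_class))
  factor(lab, levels = object$levels)
}

#' @export
print.voc_forest <- function(x, ...) {
  cat(sprintf(
    "Random forest: %d trees, mtry = %d, %d features (positive: %s)\n",
    x$n_trees, x$mtry, length(x$feature_names), x$positive))
  cat(sprintf("Out-of-bag accuracy: %.3f\n", x$oob_estimate))
  invisible(x)
}
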