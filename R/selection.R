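# Four feature-selection wrappers and their union consensus: a Boruta-style
# shadow-feature scheme, greedy forward stepwise LDA, and recursive feature
# elimination with either a random-forest or a bagged-tree ranker.  The
# panel used for classifier development is the union of the four selections.

.selection_result <- function(method, selected, scores, diagnostics,
                              universe) {
  structure(
    list(method = method, selected = selected, scores = scores,
         diagnostics = diagnostics, universe = universe),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Feature selection [%s]: %d of %d features\n",
              x$method, length(x$selected), length(x$universe)))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Boruta-style all-relevant feature selection
#'
#' Shadow-feature scheme built around a random forest.  Each iteration
#' augments the undecided real features with column-wise permuted ("shadow")
#' copies, fits a forest with permutation importance (normalised to a
#' Z score by its standard error), and scores a *hit* for every undecided
#' real feature whose importance exceeds the maximum shadow importance.  After each iteration a two-sided binomial test of the hit
#' count against p = 0.5 at level `alpha` confirms (upper tail) or rejects
#' (lower tail) features; features still undecided after `max_iter`
#' iterations are reported tentative and excluded from the selection.
#' Constant features are rejected up front.
#'
#' @param x numeric feature matrix (binary presence flags in this pipeline).
#' @param y two-class labels.
#' @param max_iter maximum iterations (>= 10).
#' @param alpha significance level of the binomial decision test.
#' @param n_trees trees per forest fit (default 500).
#' @param seed integer seed.
#' @return a `selection_result` with per-feature hit rates as scores and a
#'   diagnostics log (status per feature, iterations used).
#' @export
boruta_select <- function(x, y, max_iter = 100, alpha = 0.01, n_trees = 500,
                          seed = NULL) {
  x <- as.matrix(x)
  if (ncol(x) < 1) .arg_error("boruta_select needs at least 1 feature")
  if (max_iter < 10) .arg_error("max_iter must be >= 10")
  feats <- colnames(x)
  y <- factor(as.character(y))
  if (nlevels(y) != 2) .contract_error("two classes required")
  if (!is.null(seed)) set.seed(seed)

  status <- stats::setNames(rep("undecided", ncol(x)), feats)
  status[apply(x, 2, function(c) stats::sd(c) == 0)] <- "rejected"
  hits <- stats::setNames(integer(ncol(x)), feats)
  iters <- stats::setNames(integer(ncol(x)), feats)

  k <- 0
  while (k < max_iter && any(status == "undecided")) {
    k <- k + 1
    undec <- names(status)[status == "undecided"]
    live <- names(status)[status != "rejected"]
    shadows <- apply(x[, undec, drop = FALSE], 2, sample)
    colnames(shadows) <- paste0(".shadow.", undec)
    design <- cbind(x[, live, drop = FALSE], shadows)
    rf <- randomForest::randomForest(design, y, ntree = n_trees,
                                     importance = TRUE)
    # permutation importance normalised by its standard error (Z score),
    # the scheme's documented default; raw mean decrease is far less
    # sensitive for weak presence/absence effects
    imp <- rf$importance[, "MeanDecreaseAccuracy"] /
      pmax(rf$importanceSD[, "MeanDecreaseAccuracy"], 1e-12)
    shadow_max <- max(imp[colnames(shadows)])
    hit <- imp[undec] > shadow_max
    hits[undec] <- hits[undec] + hit
    iters[undec] <- k
    # two-sided binomial decision at level alpha (alpha/2 per tail)
    up <- stats::pbinom(hits[undec] - 1, k, 0.5, lower.tail = FALSE)
    lo <- stats::pbinom(hits[undec], k, 0.5)
    status[undec[up < alpha / 2]] <- "confirmed"
    status[undec[lo < alpha / 2 & up >= alpha / 2]] <- "rejected"
  }
  status[status == "undecided"] <- "tentative"

  .selection_result(
    method = "boruta",
    selected = feats[status[feats] == "confirmed"],
    scores = ifelse(iters > 0, hits / pmax(iters, 1), 0),
    diagnostics = list(iterations = k, status = status, hits = hits,
                       tested_iterations = iters, alpha = alpha,
                       n_trees = n_trees),
    universe = feats)
}

# internal: mean fold accuracy of an LDA on a fixed fold plan; NA if any
# fold fails to fit or lacks a class in training
.lda_cv_accuracy <- function(x, y, folds, positive, ridge = 1e-6) {
  k <- attr(folds, "k")
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) return(NA_real_)
    fit <- tryCatch(
      fit_lda(x[tr, , drop = FALSE], y[tr], ridge = ridge,
              positive = positive),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    acc[f] <- mean(as.character(pred) == as.character(y[!tr]))
  }
  mean(acc)
}

#' Greedy forward stepwise LDA feature selection
#'
#' Starting from the empty set, repeatedly adds the feature whose addition
#' maximizes `k_inner`-fold cross-validated LDA accuracy (fold plan fixed up
#' front); stops when no addition strictly improves the accuracy or
#' `max_features` is reached.  Ties are broken by input column order; a
#' candidate whose LDA fit fails (singular within-fold covariance) is
#' skipped and logged.
#'
#' @param x numeric feature matrix.
#' @param y two-class labels.
#' @param k_inner folds of the inner accuracy estimate (default 10).
#' @param max_features optional cap on the panel size.
#' @param seed seed for the fold plan.
#' @param folds optional explicit per-sample fold assignment (overrides
#'   `k_inner`/`seed`); with a fixed fold plan the selection is invariant to
#'   sample order.
#' @return a `selection_result`; scores are the CV accuracies at each
#'   feature's addition.
#' @export
step_lda_select <- function(x, y, k_inner = 10, max_features = NULL,
                            seed = NULL, folds = NULL) {
  x <- as.matrix(x)
  if (ncol(x) < 1) .arg_error("need at least one feature")
  feats <- colnames(x)
  y <- factor(as.character(y))
  positive <- if ("cancer" %in% levels(y)) "cancer" else levels(y)[2]
  if (is.null(max_features)) max_features <- ncol(x)
  if (is.null(folds))
    folds <- make_folds(nrow(x), min(k_inner, nrow(x)), labels = y,
                        stratified = TRUE, seed = seed)

  # baseline: majority-class prediction under the same fold plan
  k <- attr(folds, "k")
  base_acc <- mean(vapply(seq_len(k), function(f) {
    maj <- names(which.max(table(y[folds != f])))
    mean(y[folds == f] == maj)
  }, numeric(1)))

  selected <- character()
  current_acc <- base_acc
  log <- list()
  skipped <- character()
  repeat {
    if (length(selected) >= max_features) break
    cand <- setdiff(feats, selected)
    if (!length(cand)) break
    accs <- vapply(cand, function(f) {
      a <- .lda_cv_accuracy(x[, c(selected, f), drop = FALSE], y, folds,
                            positive)
      if (is.na(a)) skipped <<- c(skipped, f)
      a
    }, numeric(1))
    if (all(is.na(accs))) break
    best <- which.max(accs)          # first max = input-order tie break
    if (accs[best] <= current_acc) break
    selected <- c(selected, cand[best])
    current_acc <- accs[best]
    log[[length(log) + 1]] <- list(feature = cand[best],
                                   cv_accuracy = accs[best])
  }

  .selection_result(
    method = "step_lda",
    selected = selected,
    scores = stats::setNames(vapply(log, `[[`, numeric(1), "cv_accuracy"),
                             selected),
    diagnostics = list(direction = "forward", baseline_accuracy = base_acc,
                       steps = log, skipped = unique(skipped),
                       k_inner = attr(folds, "k")),
    universe = feats)
}

#' Recursive feature elimination with a tree-ensemble ranker
#'
#' Fits the ranker on the full feature set, ranks features by Gini
#' importance, then for each candidate subset size retains the top-ranked
#' subset and records `k_inner`-fold cross-validated accuracy.  The chosen
#' subset is the smallest whose accuracy is within one standard error of the
#' best (the one-SE rule).  `ranker = "forest"` uses random feature subsets
#' per split; `ranker = "bagged_trees"` makes every feature available at
#' each split (`mtry = p`).
#'
#' @param x numeric feature matrix.
#' @param y two-class labels.
#' @param ranker `"forest"` or `"bagged_trees"`.
#' @param subset_sizes decreasing integer vector of candidate panel sizes;
#'   default: the full size followed by descending powers of two.
#' @param k_inner folds of the accuracy estimate (default 10).
#' @param n_trees trees per forest fit (default 500).
#' @param seed integer seed.
#' @return a `selection_result`; scores are the importance ranks, the
#'   diagnostics hold the size/accuracy/SE profile.
#' @export
rfe_select <- function(x, y, ranker = c("forest", "bagged_trees"),
                       subset_sizes = NULL, k_inner = 10, n_trees = 500,
                       seed = NULL) {
  ranker <- match.arg(ranker)
  x <- as.matrix(x)
  p <- ncol(x)
  feats <- colnames(x)
  y <- factor(as.character(y))
  positive <- if ("cancer" %in% levels(y)) "cancer" else levels(y)[2]
  if (is.null(subset_sizes)) {
    pow <- 2^seq(floor(log2(max(p - 1, 1))), 1)
    subset_sizes <- unique(c(p, pow[pow < p]))
  }
  if (!length(subset_sizes)) .arg_error("subset_sizes must be non-empty")
  if (is.unsorted(rev(subset_sizes), strictly = TRUE) ||
      max(subset_sizes) > p || min(subset_sizes) < 1)
    .arg_error("subset_sizes must be strictly decreasing and within 1..p")

  if (!is.null(seed)) set.seed(seed)
  mtry_for <- function(q) if (ranker == "bagged_trees") q else
    max(1L, floor(sqrt(q)))

  full <- randomForest::randomForest(x, y, ntree = n_trees,
                                     mtry = mtry_for(p))
  imp <- full$importance[, "MeanDecreaseGini"]
  ranking <- feats[order(-imp)]        # stable: ties keep input order

  folds <- make_folds(nrow(x), min(k_inner, nrow(x)), labels = y,
                      stratified = TRUE, seed = sample.int(2^31 - 1, 1))
  k <- attr(folds, "k")
  profile <- data.frame(size = subset_sizes, accuracy = NA_real_,
                        se = NA_real_)
  for (i in seq_along(subset_sizes)) {
    s <- subset_sizes[i]
    sub <- ranking[seq_len(s)]
    fold_acc <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- fit_forest(x[tr, sub, drop = FALSE], y[tr], n_trees = n_trees,
                        mtry = mtry_for(s), positive = positive)
      mean(as.character(predict(fit, x[!tr, sub, drop = FALSE])) ==
             as.character(y[!tr]))
    }, numeric(1))
    profile$accuracy[i] <- mean(fold_acc)
    profile$se[i] <- stats::sd(fold_acc) / sqrt(k)
  }
  best <- which.max(profile$accuracy)
  ok <- profile$accuracy >= profile$accuracy[best] - profile$se[best]
  chosen <- profile$size[max(which(ok))]   # sizes descend: last ok = smallest

  .selection_result(
    method = if (ranker == "forest") "rfe_forest" else "rfe_bagtree",
    selected = ranking[seq_len(chosen)],
    scores = stats::setNames(rank(-imp, ties.method = "first"), feats),
    diagnostics = list(profile = profile, chosen_size = chosen,
                       ranking = ranking, ranker = ranker,
                       n_trees = n_trees, one_se = TRUE),
    universe = feats)
}

#' Union consensus of several feature selections
#'
#' The panel used for classifier development: every feature selected by at
#' least one approach, de-duplicated, ordered by first appearance in the
#' input table's column order.
#'
#' @param results list of `selection_result`s over the same feature
#'   universe.
#' @return a `selection_result` with `method = "consensus"`; scores count
#'   how many methods selected each feature.
#' @export
consensus_union <- function(results) {
  if (!length(results)) .arg_error("need at least one selection result")
  if (!all(vapply(results, inherits, logical(1), "selection_result")))
    .contract_error("all inputs must be selection_result objects")
  universe <- results[[1]]$universe
  for (r in results[-1])
    if (!identical(r$universe, universe))
      .contract_error("selection results cover different feature universes")
  all_sel <- unlist(lapply(results, `[[`, "selected"))
  selected <- universe[universe %in% all_sel]
  counts <- vapply(universe, function(f)
    sum(vapply(results, function(r) f %in% r$selected, logical(1))),
    integer(1))
  .selection_result(
    method = "consensus", selected = selected,
    scores = counts[selected],
    diagnostics = list(methods = vapply(results, `[[`, character(1),
                                        "method")),
    universe = universe)
}
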