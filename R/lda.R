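#' Fisher's linear discriminant analysis
#'
#' Two-class Fisher LDA fit from first principles: pooled within-class
#' covariance `S`, discriminant weights `w = (S + lambda I)^-1 (mu1 - mu0)`,
#' and a decision score `s(x) = w'x + b` whose intercept places `s = 0` at
#' the prior-weighted midpoint, i.e.
#' `b = -w'(mu0 + mu1)/2 + log(pi1/pi0)`.  A sample is assigned to the
#' positive class iff `s > 0` (ties at 0 go to the positive class).
#'
#' Binary presence flags in small folds frequently yield a singular pooled
#' covariance, so `S` is ridge-regularized: `lambda = ridge * mean(diag(S))`
#' (falling back to `lambda = ridge` when the mean diagonal is zero).
#' Continuous covariates with long right tails (serum PSA spans orders of
#' magnitude) would otherwise dominate the covariance, so columns named in
#' `log_scale` are log-transformed and z-scored using the *training* mean
#' and standard deviation only; the transform is stored in the model and
#' re-applied at prediction time.
#'
#' @param x numeric matrix or data.frame of predictors (named columns).
#' @param y two-class factor or character vector; both classes need >= 2
#'   samples.
#' @param priors `"empirical"` (class proportions; the default) or
#'   `"uniform"`.
#' @param ridge ridge multiplier applied to the mean diagonal of the pooled
#'   covariance (default `1e-6`).
#' @param positive name of the positive class (default: `"cancer"` when
#'   present, else the second sorted level).
#' @param log_scale character vector of column names to log-transform and
#'   z-score on the training data (e.g. `"psa"`).
#' @return an object of class `fisher_lda` with fields `class_means`,
#'   `pooled_covariance`, `weights`, `intercept`, `priors`, `ridge` (the
#'   effective lambda) and the fitted transform.
#' @examples
#' x <- cbind(v = c(0, 1, 2, 4, 5, 6))
#' y <- rep(c("control", "cancer"), each = 3)
#' fit <- fit_lda(x, y, priors = "uniform")
#' predict(fit, cbind(v = 2.9))   # below the midpoint at 3 -> control
#' @export
fit_lda <- function(x, y, priors = c("empirical", "uniform"), ridge = 1e-6,
                    positive = NULL, log_scale = character()) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2) .contract_error("fit_lda requires exactly two classes")
  if (is.null(positive)) positive <- if ("cancer" %in% lev) "cancer" else lev[2]
  negative <- setdiff(lev, positive)
  if (sum(y == positive) < 2 || sum(y == negative) < 2)
    .contract_error("each class needs at least 2 samples to pool covariance")

  # training-only log + z-score transform for long-tailed covariates
  log_scale <- intersect(log_scale, colnames(x))
  transform <- NULL
  if (length(log_scale)) {
    lx <- log(x[, log_scale, drop = FALSE])
    ctr <- colMeans(lx)
    scl <- apply(lx, 2, stats::sd)
    scl[scl == 0] <- 1
    x[, log_scale] <- sweep(sweep(lx, 2, ctr), 2, scl, "/")
    transform <- list(columns = log_scale, center = ctr, scale = scl)
  }

  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  dropped <- colnames(x)[!keep]
  if (!any(keep)) .contract_error("all features are constant")
  x <- x[, keep, drop = FALSE]

  i1 <- y == positive
  n0 <- sum(!i1); n1 <- sum(i1); n <- n0 + n1
  mu0 <- colMeans(x[!i1, , drop = FALSE])
  mu1 <- colMeans(x[i1, , drop = FALSE])
  s0 <- stats::cov(x[!i1, , drop = FALSE])
  s1 <- stats::cov(x[i1, , drop = FALSE])
  S <- ((n0 - 1) * s0 + (n1 - 1) * s1) / (n - 2)

  md <- mean(diag(S))
  lambda <- if (md > 0) ridge * md else ridge
  w <- tryCatch(
    solve(S + diag(lambda, ncol(S)), mu1 - mu0),
    error = function(e)
      .contract_error(paste0("singular pooled covariance: ", conditionMessage(e))))

  pri <- if (priors == "empirical") c(n0, n1) / n else c(0.5, 0.5)
  names(pri) <- c(negative, positive)
  b <- -sum(w * (mu0 + mu1)) / 2 + log(pri[[positive]] / pri[[negative]])

  class_means <- rbind(mu0, mu1)
  rownames(class_means) <- c(negative, positive)
  structure(
    list(class_means = class_means,
         pooled_covariance = S,
         weights = w, intercept = unname(b),
         priors = pri, ridge = lambda, ridge_mult = ridge,
         levels = c(negative, positive), positive = positive,
         transform = transform, dropped = dropped,
         feature_names = c(colnames(x), dropped)),
    class = "fisher_lda")
}

# internal: apply the stored transform and column selection to new data
.lda_design <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  need <- names(object$weights)
  all_feats <- object$feature_names
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(all_feats))
      .contract_error("newdata has the wrong number of columns")
    colnames(newdata) <- all_feats
  }
  if (!all(all_feats %in% colnames(newdata)))
    .contract_error(sprintf(
      "newdata lacks feature(s): %s",
      paste(setdiff(all_feats, colnames(newdata)), collapse = ", ")))
  tr <- object$transform
  if (!is.null(tr)) {
    lx <- log(newdata[, tr$columns, drop = FALSE])
    newdata[, tr$columns] <-
      sweep(sweep(lx, 2, tr$center), 2, tr$scale, "/")
  }
  newdata[, need, drop = FALSE]
}

#' Predict from a Fisher LDA fit
#'
#' @param object a `fisher_lda`.
#' @param newdata matrix/data.frame with (at least) the training columns,
#'   matched by name.
#' @param type `"class"` (factor), `"prob"` (probability of the positive
#'   class via the two-Gaussian logistic posterior `plogis(s)`), or
#'   `"score"` (the signed discriminant value `s`).
#' @param ... unused.
#' @return factor or numeric vector, one element per row of `newdata`.
#' @export
predict.fisher_lda <- function(object, newdata,
                               type = c("class", "prob", "score"), ...) {
  type <- match.arg(type)
  xm <- .lda_design(object, newdata)
  s <- drop(xm %*% object$weights) + object$intercept
  switch(type,
         score = s,
         prob = stats::plogis(s),
         class = factor(ifelse(s >= 0, object$positive, object$levels[1]),
                        levels = object$levels))
}

#' @export
coef.fisher_lda <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat("Fisher linear discriminant (", length(x$weights), " features, ",
      "positive class: ", x$positive, ")\n", sep = "")
  cat("Priors:", paste(sprintf("%s = %.3f", names(x$priors), x$priors),
                       collapse = ", "),
      sprintf(" ridge lambda = %.3g\n", x$ridge))
  print(coef(x))
  if (length(x$dropped))
    cat("Dropped constant features:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
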