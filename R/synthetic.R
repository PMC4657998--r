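#' Configuration for a synthetic urinary-VOC cohort
#'
#' Describes a cohort with the structure the classification pipeline assumes:
#' two patient groups (default 59 cancer / 43 control), binary VOC presence
#' features with group-wise prevalences spanning rare (< 20% in both groups)
#' to ubiquitous (> 90% in both groups), a small planted discriminative panel
#' (default 4 features: three less frequently present in cancer, one more
#' frequently present), and right-skewed serum PSA drawn log-normally per
#' class with medians near 6.2 (control) and 10.2 (cancer) ng/mL.
#'
#' @param n_cancer,n_control class sizes (default 59 / 43).
#' @param n_features total number of binary VOC features.
#' @param n_planted number of planted discriminative features.
#' @param planted_prevalence numeric matrix `n_planted x 2` with columns
#'   `control`, `cancer`: true presence probability per class.  Default:
#'   three down-regulated features at (0.60, 0.30) and one up-regulated at
#'   (0.30, 0.60).
#' @param background_range range of the shared (class-independent) presence
#'   probability of uninformative background features.
#' @param n_rare,rare_range number and prevalence range of features rare in
#'   both groups (targets of the rare side of the prevalence filter).
#' @param n_common,common_range number and prevalence range of features
#'   ubiquitous in both groups (targets of the common side of the filter).
#' @param psa_median named per-class PSA medians in ng/mL.
#' @param psa_log_sd named per-class log-scale standard deviations of PSA.
#' @param seed integer seed; generation is deterministic given the config.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cancer = 59, n_control = 43,
                             n_features = 150, n_planted = 4,
                             planted_prevalence = NULL,
                             background_range = c(0.25, 0.85),
                             n_rare = 20, rare_range = c(0.02, 0.15),
                             n_common = 20, common_range = c(0.93, 0.99),
                             psa_median = c(control = 6.2, cancer = 10.2),
                             psa_log_sd = c(control = 0.75, cancer = 1.1),
                             seed = 1) {
  if (n_cancer < 2 || n_control < 2)
    .arg_error("both class sizes must be >= 2")
  if (is.null(planted_prevalence)) {
    planted_prevalence <- cbind(
      control = rep(c(0.60, 0.30), c(max(n_planted - 1, 0), min(n_planted, 1))),
      cancer  = rep(c(0.30, 0.60), c(max(n_planted - 1, 0), min(n_planted, 1))))
  }
  planted_prevalence <- as.matrix(planted_prevalence)
  if (n_planted > 0 &&
      (nrow(planted_prevalence) != n_planted || ncol(planted_prevalence) != 2))
    .arg_error("planted_prevalence must be an n_planted x 2 matrix")
  if (any(planted_prevalence < 0 | planted_prevalence > 1))
    .arg_error("planted prevalences must lie in [0, 1]")
  if (n_rare + n_common + n_planted > n_features)
    .arg_error("n_rare + n_common + n_planted exceeds n_features")
  if (any(psa_median <= 0))
    .arg_error("PSA target medians must be positive")
  if (any(psa_log_sd < 0))
    .arg_error("PSA log-sd must be non-negative")
  structure(
    list(n_cancer = n_cancer, n_control = n_control,
         n_features = n_features, n_planted = n_planted,
         planted_prevalence = planted_prevalence,
         background_range = background_range,
         n_rare = n_rare, rare_range = rare_range,
         n_common = n_common, common_range = common_range,
         psa_median = psa_median, psa_log_sd = psa_log_sd,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Draw per-class serum PSA values
#'
#' PSA is drawn log-normally per class with the log-median equal to the log
#' of the target median, so sample medians converge to the configured
#' targets as n grows; `psa_log_sd = 0` degenerates to all values exactly at
#' the median.
#'
#' @param config a `synthetic_config`.
#' @param n_control,n_cancer arm sizes (default: the config's class sizes).
#' @param seed seed (default: derived from the config seed).
#' @return a list with numeric vectors `control` and `cancer` (ng/mL).
#' @export
generate_psa <- function(config, n_control = config$n_control,
                         n_cancer = config$n_cancer,
                         seed = derive_seed(config$seed, 2)) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  list(
    control = stats::rlnorm(n_control, log(config$psa_median[["control"]]),
                            config$psa_log_sd[["control"]]),
    cancer = stats::rlnorm(n_cancer, log(config$psa_median[["cancer"]]),
                           config$psa_log_sd[["cancer"]]))
}

#' Generate a synthetic cohort and its ground truth
#'
#' Each binary feature is drawn independently per sample as a Bernoulli flag
#' with its class-specific prevalence: planted features use
#' `planted_prevalence`; background features share one prevalence across
#' classes drawn uniformly from `background_range`; rare/common blocks sit
#' below/above the prevalence-filter bounds in both classes so the filter
#' removes them (in expectation).  Feature positions are shuffled so column
#' order carries no information.  PSA is drawn via [generate_psa()],
#' independent of the VOC flags within class.
#'
#' @param config a `synthetic_config`.
#' @return a list with `table` (a binary `feature_table` with a `psa`
#'   covariate) and `truth` (a `synthetic_truth`: planted feature names,
#'   per-class true prevalences, PSA parameters, seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, 1))
  n_bg <- config$n_features - config$n_planted - config$n_rare - config$n_common
  runif2 <- function(n, range) stats::runif(n, range[1], range[2])

  # feature x class true prevalence matrix, built block-wise then shuffled
  bg <- runif2(n_bg, config$background_range)
  rare <- runif2(config$n_rare, config$rare_range)
  common <- runif2(config$n_common, config$common_range)
  prev <- rbind(config$planted_prevalence[seq_len(config$n_planted), ,
                                          drop = FALSE],
                cbind(control = bg, cancer = bg),
                cbind(control = rare, cancer = rare),
                cbind(control = common, cancer = common))
  role <- rep(c("planted", "background", "rare", "common"),
              c(config$n_planted, n_bg, config$n_rare, config$n_common))

  pos <- sample.int(config$n_features)          # shuffle feature positions
  prev <- prev[pos, , drop = FALSE]
  role <- role[pos]
  feat_names <- sprintf("VOC%03d", seq_len(config$n_features))
  rownames(prev) <- feat_names

  n <- config$n_cancer + config$n_control
  labels <- rep(c("cancer", "control"), c(config$n_cancer, config$n_control))
  vals <- matrix(0, n, config$n_features,
                 dimnames = list(sprintf("S%03d", seq_len(n)), feat_names))
  is_cancer <- labels == "cancer"
  for (j in seq_len(config$n_features)) {
    vals[is_cancer, j] <- stats::rbinom(config$n_cancer, 1, prev[j, "cancer"])
    vals[!is_cancer, j] <- stats::rbinom(config$n_control, 1,
                                         prev[j, "control"])
  }

  psa <- generate_psa(config)
  psa_vec <- numeric(n)
  psa_vec[is_cancer] <- psa$cancer
  psa_vec[!is_cancer] <- psa$control

  table <- feature_table(vals, labels,
                         covariates = data.frame(psa = psa_vec),
                         positive = "cancer")
  truth <- structure(
    list(planted_features = feat_names[role == "planted"],
         background_features = feat_names[role == "background"],
         rare_features = feat_names[role == "rare"],
         common_features = feat_names[role == "common"],
         prevalence = prev,
         psa_median = config$psa_median, psa_log_sd = config$psa_log_sd,
         seed = config$seed),
    class = "synthetic_truth")
  list(table = table, truth = truth)
}

#' Write a synthetic cohort plus its truth sidecar
#'
#' @param cohort result of [generate_cohort()].
#' @param path cohort CSV path.
#' @param truth_path optional JSON sidecar path for the ground truth.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  write_feature_table(cohort$table, path)
  if (!is.null(truth_path)) {
    tr <- cohort$truth
    tr$prevalence <- as.data.frame(tr$prevalence)
    jsonlite::write_json(unclass(tr), truth_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
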