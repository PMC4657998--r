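#' Configure an end-to-end pipeline run
#'
#' Mirrors the structure of the study's result tables: each requested model
#' (`lda`, `forest`) is evaluated on each requested feature source (`psa`
#' alone, the `voc` panel alone, or `voc_psa` combined) under each
#' requested validation scheme, optionally with the Monte-Carlo permutation
#' variant alongside.
#'
#' @param input path to a cohort CSV (see [read_feature_table()]), or `NULL`
#'   to simulate a cohort from `synthetic`.
#' @param synthetic a [synthetic_config()] used when `input` is `NULL`.
#' @param models subset of `c("forest", "lda")`.
#' @param features subset of `c("psa", "voc", "voc_psa")`.
#' @param schemes subset of `c("rkf", "rdcv")` (repeated 10-fold /
#'   repeated double CV).
#' @param selection `"consensus"` to select the VOC panel with the four-way
#'   consensus on the full (filtered) data, or `"none"` to use `panel`.
#' @param panel explicit VOC panel (required when `selection = "none"` and a
#'   VOC feature source is requested).
#' @param with_null also run the Monte-Carlo permutation variant of each
#'   scheme.
#' @param repeats,n_trees scheme repeats and forest size.
#' @param covariate name of the continuous covariate column (default
#'   `"psa"`).
#' @param out_dir output directory (created if needed).
#' @param seed master seed for every source of randomness in the run.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = NULL,
                       models = c("forest", "lda"),
                       features = c("psa", "voc", "voc_psa"),
                       schemes = c("rkf", "rdcv"),
                       selection = c("consensus", "none"), panel = NULL,
                       with_null = TRUE, repeats = 30, n_trees = 500,
                       covariate = "psa", out_dir = ".", seed = 1) {
  selection <- match.arg(selection)
  models <- match.arg(models, several.ok = TRUE)
  features <- match.arg(features, several.ok = TRUE)
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (is.null(input) && is.null(synthetic))
    .arg_error("provide an input CSV path or a synthetic_config")
  if (selection == "none" && is.null(panel) &&
      any(features %in% c("voc", "voc_psa")))
    .arg_error("selection = 'none' requires an explicit VOC panel")
  structure(list(input = input, synthetic = synthetic, models = models,
                 features = features, schemes = schemes,
                 selection = selection, panel = panel,
                 with_null = with_null, repeats = repeats,
                 n_trees = n_trees, covariate = covariate,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full classification pipeline and write a report bundle
#'
#' Executes binarization, the dual prevalence filter, (optionally) the
#' four-way consensus feature selection, and every requested
#' model x feature-source x scheme combination, writing per-record metric
#' CSVs, six-number summary CSVs (as fractions and percentages), pooled ROC
#' curves for the nested scheme, the selected panel, and a machine-readable
#' JSON manifest (configuration, seeds, package version).  Every number in
#' a summary table is recomputable from the emitted metric records.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the filtered table, filter report,
#'   selection panel, all `voc_cv` results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, paste0(...))

  if (!is.null(config$input)) {
    table <- read_feature_table(config$input,
                                covariate_columns = config$covariate)
  } else {
    table <- generate_cohort(config$synthetic)$table
  }
  table <- binarize(table)
  filt <- prevalence_filter(table)
  table <- filt$table

  panel <- config$panel
  sel_results <- NULL
  if (config$selection == "consensus" &&
      any(config$features %in% c("voc", "voc_psa"))) {
    x <- table$values
    y <- table$labels
    sel_results <- list(
      boruta_select(x, y, seed = derive_seed(config$seed, 11)),
      step_lda_select(x, y, seed = derive_seed(config$seed, 12)),
      rfe_select(x, y, "forest", seed = derive_seed(config$seed, 13)),
      rfe_select(x, y, "bagged_trees", seed = derive_seed(config$seed, 14)))
    consensus <- consensus_union(sel_results)
    panel <- consensus$selected
    flags <- vapply(consensus$universe, function(f)
      sum(2^(which(vapply(sel_results, function(r) f %in% r$selected,
                          logical(1))) - 1)), numeric(1))
    utils::write.csv(
      data.frame(feature = consensus$universe, method_flags = flags),
      out("selection_panel.csv"), row.names = FALSE)
  }
  if (is.null(panel)) panel <- character()

  feature_sets <- list()
  if ("psa" %in% config$features)
    feature_sets$psa <- config$covariate
  if ("voc" %in% config$features)
    feature_sets$voc <- panel
  if ("voc_psa" %in% config$features)
    feature_sets$voc_psa <- c(panel, config$covariate)

  results <- list()
  scheme_of <- function(kind, permute, seed)
    cv_scheme(kind = if (kind == "rkf") "repeated_kfold"
                     else "repeated_double",
              repeats = config$repeats, permute_labels = permute,
              seed = seed)
  i <- 0
  for (mod in config$models) {
    spec <- model_spec(mod, n_trees = config$n_trees)
    for (fs in names(feature_sets)) {
      if (!length(feature_sets[[fs]])) next
      for (sk in config$schemes) {
        for (permute in unique(c(FALSE, config$with_null))) {
          i <- i + 1
          tag <- paste(mod, fs, sk, if (permute) "null" else "obs",
                       sep = "_")
          sch <- scheme_of(sk, permute, derive_seed(config$seed, 20 + i))
          cv <- if (sk == "rkf")
            repeated_kfold_cv(table, spec, feature_sets[[fs]], sch)
          else
            repeated_double_cv(table, spec, feature_sets[[fs]], sch)
          results[[tag]] <- cv
          utils::write.csv(cv$records, out("records_", tag, ".csv"),
                           row.names = FALSE)
          sm <- summary(cv)
          if (is.data.frame(sm)) {
            utils::write.csv(data.frame(metric = rownames(sm), sm,
                                        row.names = NULL,
                                        check.names = FALSE),
                             out("summary_", tag, ".csv"),
                             row.names = FALSE)
          } else {
            df <- as.data.frame(t(unclass(sm)))
            utils::write.csv(rbind(df, 100 * df),
                             out("summary_", tag, ".csv"),
                             row.names = FALSE)
          }
          if (sk == "rdcv" && !permute) {
            roc <- pooled_roc(cv)
            utils::write.csv(data.frame(fpr = roc$fpr, tpr = roc$tpr),
                             out("roc_", tag, ".csv"), row.names = FALSE)
          }
        }
      }
    }
  }

  manifest <- list(
    package = "vocclass",
    version = as.character(utils::packageVersion("vocclass")),
    seed = config$seed,
    input = config$input %||% "synthetic",
    models = config$models, features = config$features,
    schemes = config$schemes, repeats = config$repeats,
    n_trees = config$n_trees, panel = panel,
    n_samples = n_samples(table), n_features_after_filter = n_features(table),
    removed_rare = length(filt$report$removed_rare),
    removed_common = length(filt$report$removed_common),
    outputs = i)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(table = table, filter_report = filt$report,
                 panel = panel, selection = sel_results,
                 results = results, manifest = manifest))
}
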