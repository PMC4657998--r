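# smaller repeat counts than the production defaults keep the suite quick;
# the engines are size-agnostic and the full-scale runs live in the
# acceptance checks

make_separable_table <- function(seed = 1) {
  set.seed(seed)
  labels <- rep(c("cancer", "control"), c(30, 24))
  vals <- cbind(sep = as.numeric(labels == "cancer"),
                noise1 = rbinom(54, 1, 0.5), noise2 = rbinom(54, 1, 0.5))
  rownames(vals) <- NULL
  feature_table(vals, labels)
}

test_that("perfectly separable data is classified perfectly by both engines
          and both models", {
  tab <- make_separable_table()
  rkf <- cv_scheme("repeated_kfold", repeats = 2, k = 10, seed = 4)
  rd <- cv_scheme("repeated_double", repeats = 2, inner_repeats = 2,
                  seed = 4)
  for (mod in c("lda", "forest")) {
    spec <- model_spec(mod, n_trees = 50)
    a <- repeated_kfold_cv(tab, spec, c("sep", "noise1"), rkf)
    expect_equal(nrow(a$records), 20)
    expect_true(all(a$records$accuracy == 1))
    expect_true(all(unclass(summary(a)) == 1))
    b <- repeated_double_cv(tab, spec, c("sep", "noise1"), rd)
    expect_equal(nrow(b$records), 2)
    expect_true(all(b$records$accuracy == 1))
  }
})

test_that("fold-level accuracies on a 102-sample cohort are multiples of
          1/10 or 1/11", {
  coh <- generate_cohort(synthetic_config(seed = 21))
  sch <- cv_scheme("repeated_kfold", repeats = 1, k = 10, seed = 2)
  cv <- repeated_kfold_cv(coh$table, model_spec("lda"),
                          coh$truth$planted_features, sch)
  expect_equal(sort(unique(cv$records$n_test)), c(10, 11))
  ok <- with(cv$records, abs(accuracy * n_test - round(accuracy * n_test)))
  expect_true(all(ok < 1e-9))
})

test_that("identical master seeds give bit-identical metric streams and
          different seeds differ", {
  tab <- make_binary_table(25, 20, prev_cancer = runif(6), seed = 31)
  sch <- cv_scheme("repeated_kfold", repeats = 3, k = 5, seed = 77)
  s1 <- repeated_kfold_cv(tab, model_spec("forest", n_trees = 40),
                          colnames(tab$values)[1:4], sch)
  s2 <- repeated_kfold_cv(tab, model_spec("forest", n_trees = 40),
                          colnames(tab$values)[1:4], sch)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$scores, s2$scores)
  sch$seed <- 78L
  s3 <- repeated_kfold_cv(tab, model_spec("forest", n_trees = 40),
                          colnames(tab$values)[1:4], sch)
  expect_false(identical(s1$records, s3$records))

  rd <- cv_scheme("repeated_double", repeats = 2, inner_repeats = 2,
                  permute_labels = TRUE, seed = 5)
  d1 <- repeated_double_cv(tab, model_spec("lda"),
                           colnames(tab$values)[1:4], rd)
  d2 <- repeated_double_cv(tab, model_spec("lda"),
                           colnames(tab$values)[1:4], rd)
  expect_identical(d1$records, d2$records)
})

test_that("label permutation preserves class sizes and collapses planted
          signal toward chance", {
  coh <- generate_cohort(synthetic_config(seed = 41))
  panel <- coh$truth$planted_features
  spec <- model_spec("forest", n_trees = 60)
  obs <- repeated_kfold_cv(coh$table, spec, panel,
                           cv_scheme("repeated_kfold", repeats = 3,
                                     seed = 6))
  nul <- monte_carlo_null(coh$table, spec, panel,
                          cv_scheme("repeated_kfold", repeats = 3,
                                    seed = 6))
  # permutation preserves the 59/43 marginals: per-repeat test counts add
  # up to the full cohort either way
  expect_equal(sum(nul$records$tp + nul$records$fn),
               sum(obs$records$tp + obs$records$fn))
  # planted signal is real: observed accuracy clearly above the null
  expect_gt(mean_accuracy(obs), mean_accuracy(nul) + 0.05)
  # and the null is near the fixed-marginal chance agreement
  expect_lt(abs(mean_accuracy(nul) - chance_agreement(59, 43)), 0.08)
})

test_that("a training fold that loses a class is skipped and logged", {
  # 3 cancer cases in 20 samples with k = 2: a permuted repeat can place
  # all cancer in one fold; force it via unstratified folds
  set.seed(8)
  labels <- rep(c("cancer", "control"), c(3, 17))
  vals <- cbind(v1 = rbinom(20, 1, 0.5), v2 = rbinom(20, 1, 0.5))
  tab <- feature_table(vals, labels)
  sch <- cv_scheme("repeated_kfold", repeats = 10, k = 2,
                   stratified = FALSE, seed = 3)
  suppressWarnings(cv <- repeated_kfold_cv(tab, model_spec("lda"),
                                           c("v1", "v2"), sch))
  expect_equal(nrow(cv$records) + cv$skipped, 20)
})

test_that("full-data selection before CV on pure noise is optimistic while
          nested selection is honest (leakage contrast)", {
  sel <- function(x, y, seed)
    step_lda_select(x, y, k_inner = 5, max_features = 3,
                    seed = seed)$selected
  full_acc <- nested_acc <- numeric()
  for (s in 1:6) {
    d <- make_noise_xy(n = 60, p = 20, seed = 500 + s)
    tab <- feature_table(d$x, d$y)
    panel <- sel(tab$values, tab$labels, derive_seed(500 + s, 1))
    if (!length(panel)) panel <- colnames(tab$values)[1]
    fa <- repeated_kfold_cv(tab, model_spec("lda"), panel,
                            cv_scheme("repeated_kfold", repeats = 2, k = 5,
                                      seed = s))
    na <- repeated_double_cv(tab, model_spec("lda"), scheme =
                               cv_scheme("repeated_double", repeats = 2,
                                         inner_repeats = 2,
                                         selection_mode = "nested",
                                         seed = s),
                             selector = sel)
    full_acc <- c(full_acc, mean_accuracy(fa))
    nested_acc <- c(nested_acc, mean_accuracy(na))
  }
  # selecting on the full data then cross-validating looks better than
  # chance; the nested scheme does not inherit that optimism
  expect_gt(mean(full_acc), mean(nested_acc))
  expect_gt(mean(full_acc), 0.5)
})

test_that("rdCV is not more optimistic than flat repeated k-fold CV on the
          same signal data (paired seeds)", {
  diffs <- numeric()
  for (s in 1:4) {
    coh <- generate_cohort(synthetic_config(seed = 600 + s))
    panel <- coh$truth$planted_features
    spec <- model_spec("lda")
    flat <- repeated_kfold_cv(coh$table, spec, panel,
                              cv_scheme("repeated_kfold", repeats = 3,
                                        seed = s))
    nested <- repeated_double_cv(coh$table, spec, panel,
                                 cv_scheme("repeated_double", repeats = 3,
                                           inner_repeats = 3, seed = s))
    diffs <- c(diffs, mean_accuracy(flat) - mean_accuracy(nested))
  }
  # Monte-Carlo standard error of the paired difference
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_gt(mean(diffs), -2 * mc_se - 0.02)
})

test_that("pooled ROC from a cross-validation result behaves like a real
          curve", {
  coh <- generate_cohort(synthetic_config(seed = 51))
  cv <- repeated_double_cv(coh$table, model_spec("forest", n_trees = 60),
                           coh$truth$planted_features,
                           cv_scheme("repeated_double", repeats = 3,
                                     inner_repeats = 2, seed = 9))
  roc <- pooled_roc(cv)
  expect_s3_class(roc, "roc_data")
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  # planted signal: discriminates better than chance
  expect_gt(roc$auc, 0.5)
})

test_that("scheme contracts are enforced", {
  tab <- make_separable_table()
  expect_error(cv_scheme("repeated_double", k_outer = 1), "k_outer")
  sch <- cv_scheme("repeated_kfold", repeats = 1)
  expect_error(repeated_double_cv(tab, model_spec("lda"), "sep", sch),
               "repeated_double")
  expect_error(repeated_kfold_cv(tab, model_spec("lda"), character(),
                                 cv_scheme("repeated_kfold", repeats = 1)),
               "non-empty")
  expect_error(repeated_kfold_cv(tab, model_spec("lda"), "nope",
                                 cv_scheme("repeated_kfold", repeats = 1)),
               "unknown feature")
})
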