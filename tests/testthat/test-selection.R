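test_that("a perfect separator is confirmed by the shadow-feature scheme", {
  set.seed(1)
  y <- rep(c("cancer", "control"), each = 30)
  x <- cbind(sep = as.numeric(y == "cancer"),
             noise = rbinom(60, 1, 0.5))
  res <- boruta_select(x, y, max_iter = 30, n_trees = 100, seed = 5)
  expect_true("sep" %in% res$selected)
  expect_s3_class(res, "selection_result")
  expect_true(all(res$selected %in% colnames(x)))
})

test_that("a strongly planted feature is confirmed in nearly every run,
          noise almost never (simulation oracle)", {
  hits <- 0; false_pos <- 0; n_noise_tested <- 0
  for (s in 1:10) {
    set.seed(s)
    y <- rep(c("cancer", "control"), each = 50)
    planted <- c(rbinom(50, 1, 0.9), rbinom(50, 1, 0.1))
    noise <- matrix(rbinom(100 * 20, 1, 0.5), 100, 20,
                    dimnames = list(NULL, sprintf("n%02d", 1:20)))
    x <- cbind(planted = planted, noise)
    res <- boruta_select(x, y, max_iter = 50, n_trees = 100, seed = s)
    hits <- hits + ("planted" %in% res$selected)
    false_pos <- false_pos + sum(res$selected != "planted")
    n_noise_tested <- n_noise_tested + 20
  }
  expect_gte(hits, 9)                       # >= 90% recovery
  # per-feature confirmation on noise controlled near alpha = 0.01
  expect_lte(false_pos / n_noise_tested, 0.05)
})

test_that("constant features are auto-rejected and an all-noise panel can
          come back empty", {
  set.seed(2)
  y <- rep(c("cancer", "control"), each = 20)
  x <- cbind(const = rep(1, 40), a = rbinom(40, 1, 0.5),
             b = rbinom(40, 1, 0.5))
  res <- boruta_select(x, y, max_iter = 20, n_trees = 80, seed = 3)
  expect_equal(unname(res$diagnostics$status["const"]), "rejected")
  expect_false("const" %in% res$selected)
})

test_that("stepwise LDA picks the perfect separator first and respects
          max_features", {
  set.seed(4)
  y <- rep(c("cancer", "control"), each = 25)
  x <- cbind(matrix(rbinom(50 * 6, 1, 0.5), 50, 6,
                    dimnames = list(NULL, sprintf("n%d", 1:6))),
             sep = as.numeric(y == "cancer"))
  folds <- make_folds(50, 10, labels = y, stratified = TRUE, seed = 9)
  res <- step_lda_select(x, y, folds = folds)
  expect_equal(res$selected[1], "sep")

  # exhaustive oracle for the first greedy step: best single-feature CV acc
  accs <- vapply(colnames(x), function(f) {
    k <- attr(folds, "k")
    mean(vapply(seq_len(k), function(fd) {
      fit <- fit_lda(x[folds != fd, f, drop = FALSE], y[folds != fd])
      mean(as.character(predict(fit, x[folds == fd, f, drop = FALSE])) ==
             y[folds == fd])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(res$selected[1], names(which.max(accs)))

  res1 <- step_lda_select(x, y, folds = folds, max_features = 1)
  expect_length(res1$selected, 1)
  expect_equal(res1$selected, names(which.max(accs)))
})

test_that("stepwise LDA on pure noise stays at (or near) the empty panel
          with chance-level accuracy", {
  sizes <- integer(); accs <- numeric()
  for (s in 1:5) {
    d <- make_noise_xy(n = 60, p = 8, seed = s)
    res <- step_lda_select(d$x, d$y, k_inner = 10, seed = s)
    sizes <- c(sizes, length(res$selected))
    last <- if (length(res$scores)) res$scores[length(res$scores)] else
      res$diagnostics$baseline_accuracy
    accs <- c(accs, last)
  }
  # greedy forward selection with a strict-improvement stop stays small
  expect_lte(median(sizes), 3)
  # and its apparent accuracy is not far above chance (0.5)
  expect_lt(mean(accs), 0.5 + 3 * sqrt(0.25 / 60) / sqrt(5) + 0.15)
})

test_that("stepwise LDA with an explicit fold plan is invariant to sample
          order", {
  set.seed(6)
  y <- rep(c("cancer", "control"), each = 20)
  x <- cbind(good = rbinom(40, 1, ifelse(y == "cancer", 0.8, 0.2)),
             matrix(rbinom(40 * 4, 1, 0.5), 40, 4,
                    dimnames = list(NULL, sprintf("n%d", 1:4))))
  folds <- make_folds(40, 5, labels = y, stratified = TRUE, seed = 1)
  r1 <- step_lda_select(x, y, folds = folds)
  perm <- sample(40)
  f2 <- folds[perm]; attr(f2, "k") <- attr(folds, "k")
  r2 <- step_lda_select(x[perm, ], y[perm], folds = f2)
  expect_identical(r1$selected, r2$selected)
})

test_that("RFE recovers planted features and collapses to the smallest
          subset on noise (one-SE rule)", {
  rec <- 0
  for (s in 1:6) {
    set.seed(s)
    y <- rep(c("cancer", "control"), each = 50)
    x <- cbind(p1 = rbinom(100, 1, ifelse(y == "cancer", 0.85, 0.15)),
               p2 = rbinom(100, 1, ifelse(y == "cancer", 0.2, 0.8)),
               matrix(rbinom(100 * 30, 1, 0.5), 100, 30,
                      dimnames = list(NULL, sprintf("n%02d", 1:30))))
    res <- rfe_select(x, y, "forest", subset_sizes = c(32, 16, 8, 4, 2),
                      n_trees = 100, seed = s)
    rec <- rec + all(c("p1", "p2") %in% res$selected)
  }
  expect_gte(rec, 5)   # both planted recovered in >= ~90% of runs

  # pure noise: one-SE rule prefers the most parsimonious subset offered
  chosen <- vapply(1:5, function(s) {
    d <- make_noise_xy(n = 60, p = 16, seed = s + 100)
    r <- rfe_select(d$x, d$y, "forest", subset_sizes = c(16, 8, 4, 2),
                    n_trees = 100, seed = s)
    r$diagnostics$chosen_size
  }, numeric(1))
  expect_lte(median(chosen), 4)

  # full set only: nothing can be eliminated
  d <- make_noise_xy(n = 30, p = 5, seed = 1)
  r <- rfe_select(d$x, d$y, "forest", subset_sizes = 5, n_trees = 50,
                  seed = 1)
  expect_setequal(r$selected, colnames(d$x))
  expect_error(rfe_select(d$x, d$y, "forest", subset_sizes = integer()),
               "non-empty")
})

test_that("bagged-tree RFE uses every feature per split and is seed
          deterministic (as are the other forest-based selectors)", {
  d <- make_noise_xy(n = 50, p = 6, seed = 2)
  r1 <- rfe_select(d$x, d$y, "bagged_trees", n_trees = 60, seed = 7)
  r2 <- rfe_select(d$x, d$y, "bagged_trees", n_trees = 60, seed = 7)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$diagnostics$profile, r2$diagnostics$profile)
  b1 <- boruta_select(d$x, d$y, max_iter = 15, n_trees = 60, seed = 8)
  b2 <- boruta_select(d$x, d$y, max_iter = 15, n_trees = 60, seed = 8)
  expect_identical(b1$diagnostics$hits, b2$diagnostics$hits)
})

test_that("consensus union de-duplicates, preserves column order, and
          rejects mismatched universes", {
  uni <- c("a", "b", "c", "d")
  mk <- function(sel) vocclass:::.selection_result("m", sel, NULL, NULL, uni)
  got <- consensus_union(list(mk(c("a", "b")), mk(c("b", "c")), mk(character()),
                              mk("c")))
  expect_equal(got$selected, c("a", "b", "c"))
  expect_equal(got$method, "consensus")
  expect_equal(consensus_union(list(mk(character()), mk(character())))$selected,
               character())
  expect_equal(consensus_union(list(mk("a"), mk("a"), mk("a"),
                                    mk("a")))$selected, "a")
  bad <- vocclass:::.selection_result("m", "z", NULL, NULL, c("z", "q"))
  expect_error(consensus_union(list(mk("a"), bad)), "universe")
})
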