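# fixtures built in code: small binary tables and noise matrices

# binary table with given per-class prevalence vectors (one per feature)
make_binary_table <- function(n_cancer = 20, n_control = 20,
                              prev_cancer, prev_control = prev_cancer,
                              seed = 1, psa = FALSE) {
  set.seed(seed)
  p <- length(prev_cancer)
  labels <- rep(c("cancer", "control"), c(n_cancer, n_control))
  vals <- sapply(seq_len(p), function(j)
    c(rbinom(n_cancer, 1, prev_cancer[j]), rbinom(n_control, 1,
                                                  prev_control[j])))
  vals <- matrix(vals, ncol = p,
                 dimnames = list(NULL, sprintf("v%02d", seq_len(p))))
  cov <- if (psa)
    data.frame(psa = c(rlnorm(n_cancer, log(10.2), 1.1),
                       rlnorm(n_control, log(6.2), 0.75)))
  feature_table(vals, labels, covariates = cov)
}

# pure-noise labels/features: no label-feature association
make_noise_xy <- function(n = 100, p = 20, seed = 1, balance = c(0.5, 0.5)) {
  set.seed(seed)
  x <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(NULL, sprintf("v%02d", seq_len(p))))
  y <- rep(c("cancer", "control"),
           c(round(n * balance[1]), n - round(n * balance[1])))
  list(x = x, y = y)
}
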