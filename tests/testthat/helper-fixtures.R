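# Small synthetic specs and matrices shared across test files.

small_spec <- function(seed = 7L, ...) {
  synthetic_spec(n_compounds = 120L, n_informative = 6L, p_true = 6L,
                 n_constant = 8L, n_quasi_constant = 8L, n_low_rsd = 10L,
                 n_corr_blocks = 3L, corr_block_size = 5L,
                 n_mc_groups = 2L, n_families = 4L, family_size = 20L,
                 n_noise = 10L, k_true = 4L, seed = seed, ...)
}

# Named random matrix helper.
rand_matrix <- function(n, p, seed = 1L, prefix = "d") {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("c%03d", seq_len(n)),
                         sprintf("%s%03d", prefix, seq_len(p))))
}

# Independent brute-force metric oracle: direct summation formulas only.
oracle_metrics <- function(obs, pred, n_pred = 0L) {
  n <- length(obs)
  ss <- sum((obs - sum(obs) / n)^2)
  rss <- sum((pred - obs)^2)
  r2 <- 1 - rss / ss
  list(ss = ss, rss = rss, press = rss, r2 = r2,
       r2_adj = 1 - (1 - r2) * (n - 1) / (n - n_pred - 1),
       r = sum((obs - mean(obs)) * (pred - mean(pred))) /
         sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2)),
       q2 = 1 - rss / ss, mse = rss / n, rmse = sqrt(rss / n),
       mae = sum(abs(pred - obs)) / n)
}

# Independent VIF oracle: one ordinary least-squares fit per column.
oracle_vif <- function(x) {
  vapply(seq_len(ncol(x)), function(i) {
    fit <- lm(x[, i] ~ x[, -i, drop = FALSE])
    1 / (1 - summary(fit)$r.squared)
  }, numeric(1))
}
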