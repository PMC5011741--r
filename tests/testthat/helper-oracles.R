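# Independent oracles and small fixture builders shared across test files.

# Brute-force Benjamini-Hochberg step-up: adj_i = min_{j >= rank(i)} (m/j) p_(j)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min((m / i:m) * p[o][i:m]))
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Brute-force per-pair regression oracle via stats::lm: Models 2 and 3 on
# identical samples, two-sided t-tests of the interaction (Model 2) and the
# lncRNA slope (Model 3).
lm_pair_oracle <- function(y, x, st) {
  df <- data.frame(y = y, x = x, tissue = st$tissue_type,
                   batch = factor(st$batch), age = st$age)
  has_batch <- nlevels(df$batch) > 1
  has_age <- stats::var(df$age) > 0
  covs <- paste(c(if (has_batch) "batch", if (has_age) "age"),
                collapse = " + ")
  f2 <- stats::as.formula(paste("y ~ x + tissue + x:tissue",
                                if (nzchar(covs)) paste("+", covs) else ""))
  f3 <- stats::as.formula(paste("y ~ x + tissue",
                                if (nzchar(covs)) paste("+", covs) else ""))
  m2 <- stats::lm(f2, data = df)
  m3 <- stats::lm(f3, data = df)
  s2 <- summary(m2)$coefficients
  s3 <- summary(m3)$coefficients
  list(b1 = unname(stats::coef(m2)["x"]),
       b3 = unname(stats::coef(m2)["x:tissue"]),
       p_interaction = unname(s2["x:tissue", 4]),
       b1_m3 = unname(stats::coef(m3)["x"]),
       p_b1_m3 = unname(s3["x", 4]))
}

# Brute-force hypergeometric upper tail P(X >= k).
hyper_brute <- function(N, K, n, k) {
  i <- k:min(K, n)
  if (k <= max(0, n - (N - K))) return(1)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Random small two-group sample table; batch alternates within tissue so the
# two factors are never confounded.
rand_sample_table <- function(n = 12, n_batches = 2) {
  sample_table(data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    tissue_type = rep(0:1, each = ceiling(n / 2))[seq_len(n)],
    age = stats::runif(n, 30, 80),
    batch = rep(paste0("B", seq_len(n_batches)), length.out = n)))
}

# Random CountMatrix with given dims.
rand_count_matrix <- function(n_genes = 10, n_samples = 4, max_count = 1000) {
  m <- matrix(sample.int(max_count, n_genes * n_samples, replace = TRUE),
              n_genes, n_samples,
              dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  count_matrix(m)
}

# Key for pair identity.
pair_key <- function(d) paste(d$lncRNA, d$mRNA)

# Small simulation configuration for fast end-to-end tests; `...` overrides
# the downsized defaults.
small_sim_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_lncRNA = 100, n_mRNA = 300, n_de_lncRNA = 15, n_de_mRNA = 30,
         n_diff_pairs = 10, n_dose_pairs = 10, seed = seed),
    list(...))
  do.call(sim_config, args)
}
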