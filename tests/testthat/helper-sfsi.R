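# Random genotype-mean tables with a guaranteed positive stress intensity.
random_means_table <- function(n_genotypes, seed) {
  set.seed(seed)
  repeat {
    x_hf <- runif(n_genotypes, 800, 3000)
    frac <- runif(n_genotypes, -0.2, 0.8)
    x_lf <- (1 - frac) * x_hf
    if (mean(x_lf) < mean(x_hf)) break
  }
  tibble::tibble(
    genotype = sprintf("G%02d", seq_len(n_genotypes)),
    x_lf = x_lf, x_hf = x_hf, n_lf = 12L, n_hf = 12L
  )
}

# Independent scalar oracle for the index pipeline: explicit loops, no
# shared code with sfsi_table().
sfsi_oracle <- function(x_lf, x_hf) {
  n <- length(x_lf)
  sum_lf <- 0
  sum_hf <- 0
  for (i in seq_len(n)) {
    sum_lf <- sum_lf + x_lf[i]
    sum_hf <- sum_hf + x_hf[i]
  }
  si <- 1 - (sum_lf / n) / (sum_hf / n)
  pr <- numeric(n)
  sfsi <- numeric(n)
  for (i in seq_len(n)) {
    pr[i] <- (x_hf[i] - x_lf[i]) / x_hf[i] * 100
    sfsi[i] <- (1 - x_lf[i] / x_hf[i]) / si
  }
  list(si = si, pr = pr, sfsi = sfsi)
}

# Exhaustive two-sided permutation p-value for the Welch statistic.
perm_welch_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  splits <- utils::combn(length(pooled), nx)
  t_obs <- abs(stats::t.test(x, y)$statistic)
  t_perm <- apply(splits, 2, function(i) {
    abs(stats::t.test(pooled[i], pooled[-i])$statistic)
  })
  mean(t_perm >= t_obs - 1e-12)
}

# Pearson r and t-distribution p computed from first principles.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Minimal balanced plot-level records for io tests.
balanced_records <- function(n_genotypes = 3, n_years = 2, n_reps = 2,
                             trait = "tuber_yield", seed = 1) {
  set.seed(seed)
  grid <- expand.grid(
    genotype = sprintf("G%02d", seq_len(n_genotypes)),
    year = 2017L + seq_len(n_years),
    treatment = c("LF", "HF"),
    rep = seq_len(n_reps),
    stringsAsFactors = FALSE
  )
  grid[[trait]] <- round(runif(nrow(grid), 300, 2500), 1)
  tibble::as_tibble(grid)
}
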