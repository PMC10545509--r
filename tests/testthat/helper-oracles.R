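# Independent oracles used across the suite. Each re-derives its quantity
# from first principles (brute force, closed form, or direct enumeration),
# never by calling the implementation under test.

# Kruskal-Wallis H from the rank-sum definition, with tie correction.
kw_oracle <- function(groups) {
  vals <- unlist(groups)
  N <- length(vals)
  r <- rank(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(vals)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Dunn z for pair (i, j), direct formula on jointly ranked data.
dunn_oracle <- function(groups, i, j) {
  vals <- unlist(groups)
  N <- length(vals)
  r <- rank(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  rb <- tapply(r, idx, mean)
  ties <- table(vals)
  v0 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  (rb[[i]] - rb[[j]]) /
    sqrt(v0 * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
}

# AUC by exhaustive case/control pair counting, ties worth one half.
auc_pair_oracle <- function(cases, controls) {
  s <- 0
  for (a in cases) for (b in controls) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(cases) * length(controls))
}

# Binomial negative log-likelihood by direct log-mass summation.
binom_nll_oracle <- function(k, n, p) {
  -sum(log(choose(n, k)) + k * log(p) + (n - k) * log(1 - p))
}

# Chi-square dispersion statistic for replicate counts k ~ Bin(n, p),
# pooled over levels with informative p-hat; returns the statistic and df.
dispersion_stat <- function(k_mat, n) {
  stat <- 0; df <- 0
  for (lev in seq_len(ncol(k_mat))) {
    k <- k_mat[, lev]
    phat <- mean(k) / n
    if (phat < 0.05 || phat > 0.95) next
    stat <- stat + sum((k - n * phat)^2) / (n * phat * (1 - phat))
    df <- df + length(k) - 1
  }
  list(stat = stat, df = df)
}

# A custom design with a given number of trials per vocoded channel level
# (no clear trials), for high-precision recovery runs.
make_flat_design <- function(trials_per_level, levels = 24:1, seed = 99) {
  n <- trials_per_level * length(levels)
  digits <- sprintf("%03d", withr::with_seed(seed, sample(100:999, n, replace = (n > 900))))
  data.frame(stimulus_id = seq_len(n),
             digits = digits,
             level = rep(as.character(levels), each = trials_per_level),
             stringsAsFactors = FALSE)
}
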