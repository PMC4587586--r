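# Explicit loop-summation oracles, kept deliberately independent of the
# vectorized implementations they check.

mse_loop <- function(t, o) {
  s <- 0
  for (j in seq_along(t)) s <- s + (t[j] - o[j])^2
  s / length(t)
}

mape_loop <- function(t, o) {
  s <- 0
  for (j in seq_along(t)) s <- s + abs((t[j] - o[j]) / t[j])
  100 * s / length(t)
}

theil_loop <- function(t, o) {
  num <- 0; den <- 0
  for (j in seq_along(t)) num <- num + (t[j] - o[j])^2
  for (j in seq_len(length(o) - 1)) den <- den + (o[j] - o[j + 1])^2
  num / den
}

arv_loop <- function(t, o) {
  tbar <- sum(t) / length(t)
  num <- 0; den <- 0
  for (j in seq_along(t)) {
    num <- num + (o[j] - t[j])^2
    den <- den + (o[j] - tbar)^2
  }
  num / den
}

pocid_loop <- function(t, o) {
  hits <- 0
  for (j in 2:length(t))
    if ((t[j] - t[j - 1]) * (o[j] - o[j - 1]) > 0) hits <- hits + 1
  100 * hits / (length(t) - 1)
}

ia_loop <- function(t, o) {
  tbar <- sum(t) / length(t)
  num <- 0; den <- 0
  for (j in seq_along(t)) {
    num <- num + abs(o[j] - t[j])^2
    den <- den + (abs(o[j] - tbar) + abs(t[j] - tbar))^2
  }
  1 - num / den
}

# Brute-force autocorrelation with the biased (divisor N) covariance
# estimator: a literal double loop.
acf_loop <- function(x, max_lag) {
  n <- length(x)
  xbar <- sum(x) / n
  g0 <- 0
  for (t in seq_len(n)) g0 <- g0 + (x[t] - xbar)^2
  g0 <- g0 / n
  rho <- numeric(max_lag)
  for (k in seq_len(max_lag)) {
    g <- 0
    for (t in seq_len(n - k)) g <- g + (x[t] - xbar) * (x[t + k] - xbar)
    rho[k] <- (g / n) / g0
  }
  rho
}

# A small trained chain on composite data, reused by several tests.
small_chain <- function(seed = 2, n = 400, max_corrections = 2) {
  x <- normalize_minmax(gen_composite(n, seed = seed)$series)$series
  fit_correction_chain(
    x,
    base_factory = mlp_factory(1, 1, "lm", train_options(max_iterations = 80)),
    correction_factory = ann_correction_factory(
      hidden_grid = 1:2, opts = train_options(max_iterations = 80)),
    split = split_spec(0.8, 0.1, 0.1),
    policy = stop_policy(max_corrections = max_corrections),
    seed = seed)
}
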