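test_that("autocorrelations match the brute-force double-loop oracle", {
  a <- acf_series(c(1, 2, 3, 4), max_lag = 2)
  expect_equal(a$rho, c(0.25, -0.3), tolerance = 1e-12)
  w <- gen_white_noise(500, 1, seed = 31)
  a2 <- acf_series(w, max_lag = 20)
  expect_equal(a2$rho, acf_loop(w$values, 20), tolerance = 1e-12)
  expect_true(all(abs(a2$rho) <= 1))
  expect_equal(a2$bound, 2 / sqrt(500))
  expect_error(acf_series(rep(3, 50), 5), "constant")
  # the literal two-standard-deviations band remains available
  a3 <- acf_series(w, max_lag = 10, bound = "two_s")
  expect_equal(a3$bound, 2 * sd(w$values))
})

test_that("white-noise verdicts follow the exceedance rule", {
  a <- acf_series(gen_white_noise(500, 1, seed = 31), max_lag = 20)
  fake <- a; fake$rho <- rep(0, 20); fake$n_exceeding <- 0L
  expect_true(white_noise_test(fake, 0))
  strong <- acf_series(gen_ar(500, 0.9, seed = 12), max_lag = 20)
  expect_gt(strong$rho[1], 0.8)
  expect_false(white_noise_test(strong, 0.05))
  # on i.i.d. noise with a 5% tolerance (one lag of twenty allowed out), the
  # binomial oracle gives P(pass) = P(X <= 1 | 20, ~0.05) ~ 0.74, so a clear
  # majority of seeds must pass
  cnt <- 0
  for (s in 1:50)
    if (white_noise_test(acf_series(gen_white_noise(1000, 1, seed = s), 20),
                         0.05)) cnt <- cnt + 1
  expect_gte(cnt, 30)
})

test_that("a white-noise input stops the chain at the base model", {
  x <- normalize_minmax(gen_white_noise(400, 1, seed = 6))$series
  ch <- fit_correction_chain(
    x, base_factory = mlp_factory(1, 1, "lm", train_options(max_iterations = 80)),
    correction_factory = ann_correction_factory(
      hidden_grid = 1, opts = train_options(max_iterations = 80)),
    split = split_spec(0.8, 0.1, 0.1),
    policy = stop_policy(max_corrections = 2), seed = 6)
  expect_length(ch$models, 1L)
  expect_equal(ch$stop_reason, "white_noise")
  expect_equal(ch$selected_depth, 0L)
})

test_that("a zero correction cap returns exactly the base model", {
  x <- normalize_minmax(gen_composite(300, seed = 2)$series)$series
  ch <- fit_correction_chain(
    x, base_factory = mlp_factory(1, 1, "lm", train_options(max_iterations = 60)),
    correction_factory = ann_correction_factory(
      hidden_grid = 1, opts = train_options(max_iterations = 60)),
    split = split_spec(0.8, 0.1, 0.1),
    policy = stop_policy(max_corrections = 0), seed = 2)
  expect_length(ch$models, 1L)
  expect_equal(ch$stop_reason, "max_corrections")
})

test_that("stored residual series reconstruct from the persisted models", {
  ch <- small_chain(seed = 2)
  expect_gte(length(ch$models), 2L)
  vals <- ch$series$values
  s <- vals; start <- 1L
  for (i in seq_along(ch$residual_series)) {
    fs <- forecast_steps(ch$models[[i]], s)
    e <- s[fs$target_index] - fs$outputs
    stored <- ch$residual_series[[i]]
    expect_equal(stored$values, e, tolerance = 1e-10)
    expect_equal(stored$start, fs$target_index[1] + start - 1L)
    start <- stored$start
    s <- e
  }
})

test_that("the chain forecast is exactly the sum of stage predictions", {
  ch <- small_chain(seed = 2)
  d <- length(ch$models) - 1L
  vals <- ch$series$values
  co <- chain_outputs(ch, vals, depth = d)
  # oracle: recompute each stage in isolation and sum elementwise
  s <- vals
  stage_preds <- list()
  idx0 <- NULL
  for (i in 0:d) {
    fs <- forecast_steps(ch$models[[i + 1]], s)
    gl <- if (i == 0) fs$target_index else idx0[fs$target_index]
    stage_preds[[i + 1]] <- list(out = fs$outputs, gidx = gl)
    idx0 <- gl
    s <- s[fs$target_index] - fs$outputs
  }
  common <- stage_preds[[d + 1]]$gidx
  total <- rep(0, length(common))
  for (i in 0:d) {
    pos <- match(common, stage_preds[[i + 1]]$gidx)
    total <- total + stage_preds[[i + 1]]$out[pos]
  }
  pos <- match(common, co$combined$gindex)
  expect_equal(co$combined$outputs[pos], total, tolerance = 1e-12)
  # one-step forecast over a history prefix agrees with the stagewise sum
  n <- length(vals)
  manual <- 0; s <- vals[1:(n - 1)]
  for (i in 0:ch$selected_depth) {
    manual <- manual + forecast_next(ch$models[[i + 1]], s)
    if (i < ch$selected_depth) {
      fs <- forecast_steps(ch$models[[i + 1]], s)
      s <- s[fs$target_index] - fs$outputs
    }
  }
  expect_equal(chain_forecast(ch, vals[1:(n - 1)]), manual, tolerance = 1e-12)
  # depth-0 forecast is the base model's prediction alone
  expect_equal(chain_forecast(ch, vals[1:(n - 1)], depth = 0),
               forecast_next(ch$models[[1]], vals[1:(n - 1)]),
               tolerance = 1e-12)
})

test_that("a persisted chain restores and forecasts identically", {
  ch <- small_chain(seed = 3)
  js <- chain_to_json(ch)
  ch2 <- chain_from_json(js)
  expect_equal(ch2$selected_depth, ch$selected_depth)
  vals <- ch$series$values
  n <- length(vals)
  expect_equal(chain_forecast(ch2, vals[1:(n - 1)]),
               chain_forecast(ch, vals[1:(n - 1)]), tolerance = 1e-12)
  co1 <- chain_outputs(ch, vals)
  co2 <- chain_outputs(ch2, vals, depth = ch$selected_depth)
  expect_equal(co1$combined$outputs, co2$combined$outputs, tolerance = 1e-12)
})

test_that("selected depth never has worse validation fitness than the base", {
  for (s in c(2, 3, 5)) {
    ch <- small_chain(seed = s)
    f <- vapply(ch$iteration_records, function(r)
      if (is.null(r$validation)) NA_real_ else r$validation$fitness, numeric(1))
    expect_gte(f[ch$selected_depth + 1], f[1] - 1e-12)
  }
})

test_that("significant residual lags do not increase along the chain", {
  trend_ok <- 0; usable <- 0
  for (s in 1:6) {
    x <- normalize_minmax(gen_composite(500, seed = s)$series)$series
    ch <- fit_correction_chain(
      x, base_factory = mlp_factory(1, 1, "lm", train_options(max_iterations = 80)),
      correction_factory = ann_correction_factory(
        hidden_grid = 1:3, opts = train_options(max_iterations = 80)),
      split = split_spec(0.8, 0.1, 0.1),
      policy = stop_policy(max_corrections = 3), seed = s)
    ne <- vapply(ch$iteration_records, function(r)
      if (is.null(r$acf)) NA_real_ else r$acf$n_exceeding, numeric(1))
    ne <- ne[!is.na(ne)]
    if (length(ne) >= 2) {
      usable <- usable + 1
      if (all(diff(ne) <= 0)) trend_ok <- trend_ok + 1
    }
  }
  expect_gte(usable, 3)
  expect_gt(trend_ok / usable, 0.5)
})
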