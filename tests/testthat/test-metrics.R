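test_that("metric worked examples match hand computation", {
  expect_equal(mse(c(0, 1), c(1, 1)), 0.5)
  expect_equal(mse(1:5, 1:5), 0)
  expect_equal(as.numeric(mape(c(1, 2), c(1.1, 1.8))), 10)
  expect_equal(theil_u(c(1, 1, 2), c(1, 2, 2)), 1)
  expect_equal(arv(c(0, 1), c(0, 0)), 2)
  expect_equal(pocid(c(1, 2, 3), c(1.1, 2.2, 3.3)), 100)
  expect_equal(pocid(c(1, 2, 1), c(1, 1.5, 1.8)), 50)
  expect_equal(pocid(c(1, 1, 1), c(0, 5, 2)), 0)
  expect_equal(ia(c(0, 1), c(0, 0)), 0.5)
})

test_that("metric guards: zero targets, constant outputs, mismatches", {
  m <- mape(c(0, 1), c(0, 1))
  expect_equal(as.numeric(m), 0)
  expect_equal(attr(m, "n_excluded"), 1L)
  expect_error(mape(c(0, 0), c(1, 1)), "eps")
  expect_error(theil_u(c(1, 2, 3), c(2, 2, 2)), "denominator")
  expect_error(arv(c(0, 2), c(1, 1)), "denominator")
  expect_error(mse(1:3, 1:4), "length")
  expect_error(pocid(1, 1), "at least 2")
})

test_that("all metrics agree with loop oracles to 1e-12 on random vectors", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(2:200, 1)
    t <- runif(n, 0.5, 2)
    o <- t + rnorm(n, sd = 0.3)
    if (sum(diff(o)^2) == 0) next
    expect_equal(mse(t, o), mse_loop(t, o), tolerance = 1e-12)
    expect_equal(as.numeric(mape(t, o)), mape_loop(t, o), tolerance = 1e-12)
    expect_equal(theil_u(t, o), theil_loop(t, o), tolerance = 1e-12)
    expect_equal(arv(t, o), arv_loop(t, o), tolerance = 1e-12)
    expect_equal(pocid(t, o), pocid_loop(t, o), tolerance = 1e-12)
    expect_equal(ia(t, o), ia_loop(t, o), tolerance = 1e-12)
    expect_true(pocid(t, o) >= 0 && pocid(t, o) <= 100)
    expect_true(ia(t, o) <= 1)
  }
})

test_that("fitness is monotone in its components", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(1, 1, 100); m <- runif(1, 0, 0.1); a <- runif(1, 5, 40)
    u <- runif(1, 0, 1); v <- runif(1, 0, 1)
    f0 <- fitness_score(p, m, a, u, v)
    eps <- 0.01
    expect_gt(fitness_score(p + eps, m, a, u, v), f0)
    expect_lt(fitness_score(p, m + eps, a, u, v), f0)
    expect_lt(fitness_score(p, m, a + eps, u, v), f0)
    expect_lt(fitness_score(p, m, a, u + eps, v), f0)
    expect_lt(fitness_score(p, m, a, u, v + eps), f0)
  }
  expect_equal(fitness_score(0, 1, 2, 3, 4), 0)
})

test_that("evaluate_forecast bundles components consistently", {
  set.seed(9)
  t <- runif(50, 0.5, 2); o <- t + rnorm(50, sd = 0.2)
  r <- evaluate_forecast(t, o)
  expect_equal(r$mse, mse(t, o))
  expect_equal(r$mape, as.numeric(mape(t, o)))
  expect_equal(r$theil_u, theil_u(t, o))
  expect_equal(r$arv, arv(t, o))
  expect_equal(r$pocid, pocid(t, o))
  expect_equal(r$ia, ia(t, o))
  # stored fitness always recomputable from stored fields
  expect_equal(r$fitness,
               r$pocid / (1 + r$mse + r$mape + r$theil_u + r$arv),
               tolerance = 1e-12)
  # perfect non-constant forecast
  rp <- evaluate_forecast(t, t)
  expect_equal(rp$mse, 0); expect_equal(rp$mape, 0)
  expect_equal(rp$theil_u, 0); expect_equal(rp$arv, 0)
  expect_equal(rp$pocid, 100); expect_equal(rp$ia, 1)
  expect_equal(rp$fitness, 100)
  # undefined components become flags, not errors
  rf <- evaluate_forecast(c(1, 1, 1), c(2, 2, 2))
  expect_true(is.na(rf$theil_u))
  expect_true(length(rf$flags) > 0)
})

test_that("metric ratios: identity, multiplicativity, zero guard", {
  set.seed(3)
  mk <- function() {
    t <- runif(30, 0.5, 2); o <- t + rnorm(30, sd = 0.2)
    evaluate_forecast(t, o)
  }
  a <- mk(); b <- mk(); c <- mk()
  rii <- metric_ratio(a, a)
  for (f in c("mse", "pocid", "theil_u", "mape", "arv", "ia", "fitness"))
    expect_equal(rii[[f]], 1, tolerance = 1e-12)
  rab <- metric_ratio(a, b); rbc <- metric_ratio(b, c); rac <- metric_ratio(a, c)
  for (f in c("mse", "pocid", "theil_u", "mape", "arv", "ia", "fitness"))
    expect_equal(rab[[f]] * rbc[[f]], rac[[f]], tolerance = 1e-9)
  z <- a; z$mse <- 0
  rz <- metric_ratio(b, z)
  expect_true(is.na(rz$mse))
  expect_match(paste(rz$flags, collapse = " "), "mse")
})
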