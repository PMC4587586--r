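test_that("time_series validates its invariants", {
  expect_error(time_series(numeric(0)), "at least one")
  expect_error(time_series(c(1, NA, 3)), "finite")
  expect_error(time_series(c(1, Inf)), "finite")
  expect_error(time_series(1:3, timestamps = c("2001-01-01", "2001-01-01",
                                               "2001-01-02")),
               "strictly increasing")
  ts <- time_series(1:3, timestamps = c("2001-01-01", "2001-01-02",
                                        "2001-01-03"))
  expect_s3_class(ts, "time_series")
  expect_length(ts, 3L)
})

test_that("min-max normalization maps endpoints to 0 and 1", {
  nm <- normalize_minmax(time_series(c(10, 20, 30)))
  expect_equal(nm$series$values, c(0, 0.5, 1))
  expect_equal(nm$params$low, 10)
  expect_equal(nm$params$high, 30)
  # supplied params apply the same affine map
  again <- normalize_minmax(c(15, 25), nm$params)
  expect_equal(again$series$values, c(0.25, 0.75))
})

test_that("normalization round-trips within 1e-12 and rejects constants", {
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(sample(5:200, 1), sd = runif(1, 0.1, 50))
    if (max(x) == min(x)) next
    nm <- normalize_minmax(x)
    back <- denormalize(nm$series, nm$params)
    expect_equal(back$values, x, tolerance = 1e-12)
    expect_true(all(nm$series$values >= 0 & nm$series$values <= 1))
  }
  expect_error(normalize_minmax(c(5, 5, 5)), "degenerate")
  expect_length(denormalize(numeric(0), norm_params(0, 1))$values, 0L)
  expect_equal(denormalize(0.25, norm_params(0, 4))$values, 1)
})

test_that("chronological split uses floor boundaries and concatenates back", {
  s <- chronological_split(1:100, split_spec(0.8, 0.1, 0.1))
  expect_equal(sapply(s[c("train", "val", "test")], length), c(train = 80, val = 10, test = 10))
  s2 <- chronological_split(1:10, split_spec(0.8, 0.1, 0.1))
  expect_equal(sapply(s2[c("train", "val", "test")], length), c(train = 8, val = 1, test = 1))
  s3 <- chronological_split(1:100, split_spec(0.5, 0.2, 0.3))
  expect_equal(sapply(s3[c("train", "val", "test")], length), c(train = 50, val = 20, test = 30))
  # segments are contiguous, ordered, and cover the series
  x <- rnorm(137)
  sp <- chronological_split(x, split_spec(0.5, 0.3, 0.2))
  expect_identical(c(sp$train$values, sp$val$values, sp$test$values), x)
  expect_error(chronological_split(1:5, split_spec(0.8, 0.1, 0.1)), "empty")
  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
})

test_that("lag matrix windows the series as documented", {
  ls <- make_lag_matrix(1:5, 2)
  expect_equal(unname(ls$inputs), cbind(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(ls$targets, c(3, 4, 5))
  # explicit lag set {1,3}: columns oldest-to-newest (lag 3 then lag 1)
  ls2 <- make_lag_matrix(1:5, c(1, 3))
  expect_equal(unname(ls2$inputs), cbind(c(1, 2), c(3, 4)))
  expect_equal(ls2$targets, c(4, 5))
  expect_equal(colnames(ls2$inputs), c("lag_3", "lag_1"))
  expect_error(make_lag_matrix(1:5, 5), "too short")
})

test_that("every lag-set row reconstructs from the source by index arithmetic", {
  set.seed(7)
  for (i in 1:15) {
    n <- sample(10:80, 1)
    x <- rnorm(n)
    # a scalar lag_spec means "count of consecutive lags", so explicit sets
    # here always have >= 2 elements; counts are covered below
    lags <- sort(sample.int(min(8, n - 2), sample(2:3, 1)))
    ls <- make_lag_matrix(x, lags)
    dec <- sort(lags, decreasing = TRUE)
    for (r in seq_along(ls$targets)) {
      ti <- ls$target_index[r]
      expect_identical(ls$targets[r], x[ti])
      expect_identical(unname(ls$inputs[r, ]), x[ti - dec])
    }
    # lag-count semantics: count L behaves as the set {1..L}
    L <- sample(2:4, 1)
    expect_identical(make_lag_matrix(x, L)$inputs,
                     make_lag_matrix(x, seq_len(L))$inputs)
  }
})
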