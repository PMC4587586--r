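#' Univariate time-series container
#'
#' A light container for an ordered sequence of real-valued observations,
#' optionally carrying date labels. Every stage of the forecasting pipeline
#' (base model, residual models, metrics) consumes and produces this class.
#'
#' @param values numeric vector of observations; all values must be finite.
#' @param name label for the series.
#' @param timestamps optional character or Date vector, same length as
#'   `values`, strictly increasing. Carried through for reporting; never used
#'   by the numerics.
#' @return An object of class `time_series`.
#' @examples
#' ts <- time_series(c(12.1, 15.3, 9.8), name = "pm10")
#' length(ts$values)
#' @export
time_series <- function(values, name = "series", timestamps = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("time_series: need at least one observation", call. = FALSE)
  if (!all(is.finite(values)))
    stop("time_series: all values must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (!is.null(timestamps)) {
    if (length(timestamps) != length(values))
      stop("time_series: timestamps and values must have the same length",
           call. = FALSE)
    ord <- if (inherits(timestamps, "Date")) as.numeric(timestamps)
           else as.numeric(as.Date(as.character(timestamps)))
    if (anyNA(ord) || any(diff(ord) <= 0))
      stop("time_series: timestamps must parse as dates and be strictly increasing",
           call. = FALSE)
  }
  structure(list(values = values, name = name, timestamps = timestamps),
            class = "time_series")
}

#' Coerce to a time series
#' @param x numeric vector or `time_series`.
#' @param ... passed on to [time_series()].
#' @return A `time_series`.
#' @export
as_time_series <- function(x, ...) {
  if (inherits(x, "time_series")) return(x)
  time_series(x, ...)
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s: n = %d, range [%.4g, %.4g]%s\n",
              x$name, length(x$values), min(x$values), max(x$values),
              if (is.null(x$timestamps)) "" else ", dated"))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$values)

# Internal: accept either a time_series or a bare numeric vector.
series_values <- function(x) {
  if (inherits(x, "time_series")) x$values else as.numeric(x)
}

#' Min-max normalization to [0, 1]
#'
#' Rescales a series linearly so the fitting range maps onto the unit
#' interval. When `params` is omitted the minimum and maximum are taken from
#' the series itself; supplying previously fitted parameters applies the same
#' affine map (values outside the fitted range then fall outside [0, 1]).
#'
#' @param series a `time_series` or numeric vector.
#' @param params optional `norm_params` from an earlier fit.
#' @return A list with elements `series` (the rescaled `time_series`) and
#'   `params` (a `norm_params` object with fields `low`, `high`).
#' @seealso [denormalize()]
#' @examples
#' nm <- normalize_minmax(time_series(c(10, 20, 30)))
#' nm$series$values  # 0, 0.5, 1
#' @export
normalize_minmax <- function(series, params = NULL) {
  ts <- as_time_series(series)
  if (is.null(params)) {
    if (length(ts$values) < 2L)
      stop("normalize_minmax: need at least two observations to fit a scale",
           call. = FALSE)
    lo <- min(ts$values); hi <- max(ts$values)
    if (hi <= lo)
      stop("normalize_minmax: degenerate scale (constant series); supply params",
           call. = FALSE)
    params <- norm_params(lo, hi)
  }
  out <- (ts$values - params$low) / (params$high - params$low)
  list(series = time_series(out, name = ts$name, timestamps = ts$timestamps),
       params = params)
}

#' Normalization parameters
#' @param low series minimum used for scaling.
#' @param high series maximum; must exceed `low`.
#' @return A `norm_params` object.
#' @export
norm_params <- function(low, high) {
  if (!is.finite(low) || !is.finite(high) || high <= low)
    stop("norm_params: need finite high > low", call. = FALSE)
  structure(list(low = low, high = high), class = "norm_params")
}

#' Invert min-max normalization
#' @param series normalized `time_series` or numeric vector.
#' @param params the `norm_params` used for normalization.
#' @return A `time_series` on the original scale.
#' @export
denormalize <- function(series, params) {
  stopifnot(inherits(params, "norm_params"))
  vals <- series_values(series)
  out <- vals * (params$high - params$low) + params$low
  if (length(out) == 0L) return(structure(list(values = numeric(0),
                                               name = "series",
                                               timestamps = NULL),
                                          class = "time_series"))
  if (inherits(series, "time_series"))
    time_series(out, name = series$name, timestamps = series$timestamps)
  else time_series(out)
}

#' Chronological split proportions
#'
#' @param train_frac,val_frac,test_frac proportions in (0, 1) summing to 1.
#' @return A `split_spec` object.
#' @export
split_spec <- function(train_frac = 0.8, val_frac = 0.1, test_frac = 0.1) {
  fr <- c(train_frac, val_frac, test_frac)
  if (any(fr <= 0) || any(fr >= 1))
    stop("split_spec: fractions must lie strictly in (0, 1)", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("split_spec: fractions must sum to 1", call. = FALSE)
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac), class = "split_spec")
}

#' Chronological train/validation/test split
#'
#' Splits a series into three contiguous, order-preserving segments. The
#' boundaries are floor(N * train_frac) and floor(N * (train_frac + val_frac));
#' rounding remainder is absorbed by the test segment.
#'
#' @param series a `time_series` or numeric vector.
#' @param spec a [split_spec()].
#' @return A list with `time_series` elements `train`, `val`, `test` and an
#'   integer vector `boundaries` (last index of train, last index of val).
#' @export
chronological_split <- function(series, spec = split_spec()) {
  ts <- as_time_series(series)
  n <- length(ts$values)
  b1 <- floor(n * spec$train_frac)
  b2 <- floor(n * (spec$train_frac + spec$val_frac))
  if (b1 < 1 || b2 <= b1 || b2 >= n)
    stop("chronological_split: a segment would be empty at this length",
         call. = FALSE)
  seg <- function(i, j, suffix) {
    tsub <- if (is.null(ts$timestamps)) NULL else ts$timestamps[i:j]
    time_series(ts$values[i:j], name = paste0(ts$name, suffix),
                timestamps = tsub)
  }
  list(train = seg(1, b1, "_train"),
       val = seg(b1 + 1, b2, "_val"),
       test = seg(b2 + 1, n, "_test"),
       boundaries = c(b1, b2))
}

#' Lagged supervised windows for one-step-ahead learning
#'
#' Builds the design matrix for a lag-input forecaster: each row holds the
#' lagged values that precede one target observation. `lag_spec` is either a
#' single count L (meaning lags 1..L) or an explicit set of lag distances.
#' Columns are ordered oldest to newest, i.e. the largest lag first, so a lag
#' count of 2 gives rows (x[t-2], x[t-1]) with target x[t].
#'
#' @param series a `time_series` or numeric vector.
#' @param lag_spec integer count of consecutive lags, or an integer vector of
#'   lag distances (e.g. `c(1, 3)` uses x[t-1] and x[t-3]).
#' @return A `lag_set` list: `inputs` (matrix, one row per target), `targets`
#'   (numeric vector), `lags` (the lag distances, decreasing), and
#'   `target_index` (index of each target in the source series).
#' @examples
#' make_lag_matrix(1:5, 2)$targets  # 3 4 5
#' @export
make_lag_matrix <- function(series, lag_spec) {
  vals <- series_values(series)
  lags <- as.integer(lag_spec)
  if (length(lags) == 1L) lags <- seq_len(lags)
  if (any(lags < 1L) || anyDuplicated(lags))
    stop("make_lag_matrix: lags must be distinct positive integers",
         call. = FALSE)
  lags <- sort(lags, decreasing = TRUE)  # oldest-to-newest column order
  maxlag <- lags[1L]
  n <- length(vals)
  if (maxlag >= n)
    stop("make_lag_matrix: series too short for the requested lags",
         call. = FALSE)
  tidx <- (maxlag + 1L):n
  inputs <- vapply(lags, function(l) vals[tidx - l], numeric(length(tidx)))
  inputs <- matrix(inputs, nrow = length(tidx),
                   dimnames = list(NULL, paste0("lag_", lags)))
  structure(list(inputs = inputs, targets = vals[tidx], lags = lags,
                 target_index = tidx), class = "lag_set")
}

# Internal: training windows from the train segment alone, validation windows
# built causally from the concatenated train+val history so every validation
# target has a full lag window.
supervised_sets <- function(train_vals, val_vals, lag_spec) {
  tr <- make_lag_matrix(train_vals, lag_spec)
  joint <- make_lag_matrix(c(train_vals, val_vals), lag_spec)
  keep <- joint$target_index > length(train_vals)
  va <- structure(list(inputs = joint$inputs[keep, , drop = FALSE],
                       targets = joint$targets[keep],
                       lags = joint$lags,
                       target_index = joint$target_index[keep]),
                  class = "lag_set")
  list(train = tr, val = va)
}
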