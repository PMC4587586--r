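#' Autocorrelation function with white-noise bounds
#'
#' Sample autocorrelations rho_k = gamma_k / gamma_0 for lags 1..`max_lag`,
#' using the biased autocovariance estimator (divisor N), together with a
#' two-sided band for judging whiteness. The default band is the standard
#' large-sample bound 2/sqrt(N) for the autocorrelation of white noise; the
#' `"two_s"` option takes the band literally as twice the sample standard
#' deviation of the series, which is statistically meaningless for values
#' bounded in [-1, 1] but retained for fidelity to sources that state it.
#'
#' @param series `time_series` or numeric vector.
#' @param max_lag number of lags; default min(20, floor(N/4)).
#' @param bound `"two_over_sqrt_n"` (default) or `"two_s"`.
#' @param tolerance_fraction fraction of lags allowed outside the band while
#'   still calling the series white (default 0: every lag must be inside).
#' @return An `acf_result`: `rho` (per-lag values), `bound` (scalar band
#'   half-width), `n`, `n_exceeding`, `is_white_noise`, `max_lag`.
#' @export
acf_series <- function(series, max_lag = NULL,
                       bound = c("two_over_sqrt_n", "two_s"),
                       tolerance_fraction = 0) {
  vals <- series_values(series)
  bound <- match.arg(bound)
  n <- length(vals)
  if (is.null(max_lag)) max_lag <- min(20L, n %/% 4L)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= n)
    stop("acf_series: need 1 <= max_lag < series length", call. = FALSE)
  if (stats::var(vals) == 0)
    stop("acf_series: constant series has no autocorrelation", call. = FALSE)
  rho <- as.numeric(stats::acf(vals, lag.max = max_lag, plot = FALSE,
                               demean = TRUE)$acf)[-1L]
  b <- if (bound == "two_over_sqrt_n") 2 / sqrt(n)
       else 2 * stats::sd(vals)
  n_exc <- sum(abs(rho) > b)
  structure(list(rho = rho, bound = b, bound_type = bound, n = n,
                 max_lag = max_lag, n_exceeding = n_exc,
                 is_white_noise = (n_exc / max_lag) <= tolerance_fraction,
                 tolerance_fraction = tolerance_fraction),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("<acf_result> n = %d, %d lags, band +/-%.4g, %d exceeding -> %s\n",
              x$n, x$max_lag, x$bound, x$n_exceeding,
              if (x$is_white_noise) "white noise" else "correlated"))
  invisible(x)
}

#' White-noise verdict from an ACF
#'
#' TRUE when the fraction of lags whose autocorrelation magnitude exceeds
#' the band is at most `tolerance_fraction`. The default 0 is the literal
#' rule "all lags inside the band"; 0.05 tolerates the ~5% of band crossings
#' expected from genuine white noise under the 2/sqrt(N) band.
#'
#' @param acf_result an [acf_series()] result.
#' @param tolerance_fraction maximum allowed exceedance fraction.
#' @return Logical verdict.
#' @export
white_noise_test <- function(acf_result, tolerance_fraction = 0) {
  stopifnot(inherits(acf_result, "acf_result"))
  (acf_result$n_exceeding / acf_result$max_lag) <= tolerance_fraction
}

#' Stop policy for the correction loop
#'
#' The recursion over residual models stops when (i) the current residual
#' series behaves as white noise, (ii) adding a correction increases the
#' validation MAPE by at least `mape_increase_threshold` (relative) for
#' `patience` consecutive additions — the offending stages are then excluded
#' from the selected depth — or (iii) `max_corrections` stages have been
#' fitted.
#'
#' @param mape_increase_threshold relative MAPE increase that counts as a
#'   degradation (default 0.05, i.e. 5 percent).
#' @param patience consecutive degradations required to stop (default 1;
#'   2 tolerates a single bad stage before giving up).
#' @param max_corrections cap on the number of correction stages.
#' @return A `stop_policy` object.
#' @export
stop_policy <- function(mape_increase_threshold = 0.05, patience = 1L,
                        max_corrections = 5L) {
  stopifnot(mape_increase_threshold > 0, patience >= 1, max_corrections >= 0)
  structure(list(mape_increase_threshold = mape_increase_threshold,
                 patience = as.integer(patience),
                 max_corrections = as.integer(max_corrections)),
            class = "stop_policy")
}

#' Forecaster factories for chain stages
#'
#' A factory is a function `(train, val, seed)` returning a fitted
#' forecaster that supports [forecast_steps()] / [forecast_next()].
#' `mlp_factory` builds a fixed-structure MLP; `hs_factory` runs the GA
#' structure search plus phase adjustment; `ann_correction_factory` builds
#' the residual-correction network whose input lags are the ACF-significant
#' lags of the residual series (capped at `max_acf_lags`) and whose
#' hidden-layer size is swept over `hidden_grid` by validation error, with
#' the Levenberg-Marquardt trainer.
#'
#' @param n_lags,n_hidden,trainer fixed MLP structure for `mlp_factory`.
#' @param opts a [train_options()].
#' @param params a [ga_params()] for `hs_factory`.
#' @param adjust_phase whether `hs_factory` runs [phase_adjust()].
#' @param hidden_grid hidden-unit candidates for the correction network.
#' @param max_acf_lags cap on ACF-chosen input lags.
#' @param acf_bound band rule passed to [acf_series()].
#' @return A factory function.
#' @name stage-factories
NULL

#' @rdname stage-factories
#' @export
mlp_factory <- function(n_lags, n_hidden, trainer = "lm",
                        opts = train_options()) {
  force(n_lags); force(n_hidden); force(trainer); force(opts)
  function(train, val, seed) {
    sets <- supervised_sets(series_values(train), series_values(val), n_lags)
    cfg <- mlp_config(n_inputs = n_lags, n_hidden = n_hidden,
                      trainer = trainer, seed = seed)
    mlp_train(mlp_init(cfg), sets$train, sets$val, opts)
  }
}

#' @rdname stage-factories
#' @export
hs_factory <- function(params = ga_params(), adjust_phase = TRUE) {
  force(params); force(adjust_phase)
  function(train, val, seed) {
    p <- params; p$seed <- as.integer(seed)
    m <- ga_search(train, val, p)
    if (adjust_phase) m <- phase_adjust(m, train, val)
    m
  }
}

#' @rdname stage-factories
#' @export
ann_correction_factory <- function(hidden_grid = 1:20,
                                   max_acf_lags = 10L,
                                   opts = train_options(),
                                   acf_bound = "two_over_sqrt_n") {
  force(hidden_grid); force(max_acf_lags); force(opts); force(acf_bound)
  function(train, val, seed) {
    tr <- series_values(train); va <- series_values(val)
    ac <- tryCatch(acf_series(tr, bound = acf_bound), error = function(e) NULL)
    lags <- if (is.null(ac)) integer(0)
            else which(abs(ac$rho) > ac$bound)
    if (length(lags) == 0L) lags <- 1L
    if (length(lags) > max_acf_lags)
      lags <- lags[order(abs(ac$rho[lags]), decreasing = TRUE)[seq_len(max_acf_lags)]]
    lags <- sort(lags)
    if (max(lags) >= length(tr)) lags <- 1L
    sets <- supervised_sets(tr, va, lags)
    best <- NULL; best_val <- Inf
    for (h in hidden_grid) {
      cfg <- mlp_config(n_inputs = lags, n_hidden = h, trainer = "lm",
                        seed = as.integer(seed) + h)
      m <- tryCatch(mlp_train(mlp_init(cfg), sets$train, sets$val, opts),
                    error = function(e) NULL)
      if (is.null(m)) next
      vm <- mean((mlp_forward(m, sets$val$inputs) - sets$val$targets)^2)
      if (is.finite(vm) && vm < best_val) { best_val <- vm; best <- m }
    }
    if (is.null(best))
      stop("ann_correction_factory: every hidden-layer candidate failed",
           call. = FALSE)
    best
  }
}

#' Fit a recursive residual-correction chain
#'
#' Trains the base model M0 on the training segment, then repeatedly: takes
#' the in-sample one-step residuals of the current stage on the training
#' segment, applies the ACF white-noise gate, and — if structure remains —
#' trains the next correction model on the residual series. The combined
#' forecast at depth d is the sum of stage outputs
#' \deqn{\hat{x}_{t+1} = M_0(x) + M_1(e_0) + \dots + M_d(e_{d-1}),}
#' each stage predicting the previous stage's error. The validation MAPE of
#' the combined forecast drives the degradation stop rule; degrading stages
#' are excluded from `selected_depth`.
#'
#' @param series `time_series` or numeric vector (typically already
#'   normalized to [0, 1]).
#' @param base_factory,correction_factory stage factories (see
#'   [stage-factories]); the base factory fits M0, the correction factory
#'   fits every Mi for i >= 1 on a residual series.
#' @param split a [split_spec()].
#' @param policy a [stop_policy()].
#' @param seed integer; stage i trains with seed `seed + 101 * i`.
#' @param acf_bound,acf_tolerance white-noise gate settings (see
#'   [acf_series()]).
#' @param selection `"best_val_fitness"` (default) picks, among the depths
#'   the stop policy did not exclude, the one with the highest validation
#'   fitness — which guarantees the selected depth never has a worse
#'   validation fitness than the uncorrected model; `"policy"` keeps the
#'   deepest non-degrading stage set (the "last model found" reading).
#' @return A `correction_chain`: `models`, `residual_series` (e_0..e_{n-1}
#'   over the full series, aligned by `stage_start`), `iteration_records`
#'   (per-depth validation/test `metrics_report`s and per-stage
#'   `acf_result`), `stop_reason`, `selected_depth`, `stage_start`,
#'   `boundaries`.
#' @export
fit_correction_chain <- function(series, base_factory, correction_factory,
                                 split = split_spec(), policy = stop_policy(),
                                 seed = 1L, acf_bound = "two_over_sqrt_n",
                                 acf_tolerance = 0,
                                 selection = c("best_val_fitness", "policy")) {
  selection <- match.arg(selection)
  ts <- as_time_series(series)
  vals <- ts$values
  n <- length(vals)
  segs <- chronological_split(ts, split)
  b1 <- segs$boundaries[1]; b2 <- segs$boundaries[2]

  models <- list()
  stage_start <- integer(0)   # global index of stage input series' first value
  stage_out <- list()         # outputs aligned: names target_index global
  residuals <- list()
  records <- list()
  stop_reason <- NULL
  mape_trace <- numeric(0)
  degrade_run <- 0L
  selected_depth <- 0L

  cur_vals <- vals
  cur_start <- 1L

  depth <- -1L
  repeat {
    depth <- depth + 1L
    stage_seed <- as.integer(seed) + 101L * depth
    # segment the current stage series at the global boundaries
    tr_keep <- seq_along(cur_vals) + cur_start - 1L <= b1
    va_keep <- (seq_along(cur_vals) + cur_start - 1L > b1) &
               (seq_along(cur_vals) + cur_start - 1L <= b2)
    tr_vals <- cur_vals[tr_keep]
    va_vals <- cur_vals[va_keep]
    factory <- if (depth == 0L) base_factory else correction_factory
    model <- tryCatch(factory(tr_vals, va_vals, stage_seed),
                      error = function(e) e)
    if (inherits(model, "error")) {
      if (depth == 0L)
        stop("fit_correction_chain: base model training failed: ",
             conditionMessage(model), call. = FALSE)
      stop_reason <- "stage_failure"
      depth <- depth - 1L
      break
    }
    models[[depth + 1L]] <- model
    stage_start[depth + 1L] <- cur_start

    fs <- forecast_steps(model, cur_vals)
    gidx <- fs$target_index + cur_start - 1L   # global indices of outputs
    stage_out[[depth + 1L]] <- list(outputs = fs$outputs, gindex = gidx)

    # combined forecast at this depth on validation and test segments
    comb <- combined_outputs(stage_out, depth)
    rec <- list(depth = depth)
    vsel <- comb$gindex > b1 & comb$gindex <= b2
    tsel <- comb$gindex > b2
    rec$validation <- if (sum(vsel) >= 2L)
      tryCatch(evaluate_forecast(vals[comb$gindex[vsel]], comb$outputs[vsel]),
               error = function(e) NULL) else NULL
    rec$test <- if (sum(tsel) >= 2L)
      tryCatch(evaluate_forecast(vals[comb$gindex[tsel]], comb$outputs[tsel]),
               error = function(e) NULL) else NULL

    # residual series of this stage over its full range
    e_vals <- cur_vals[fs$target_index] - fs$outputs
    e_start <- gidx[1L]

    # white-noise gate on the training-segment portion of the residuals
    e_tr <- e_vals[gidx <= b1]
    ac <- tryCatch(acf_series(e_tr, bound = acf_bound,
                              tolerance_fraction = acf_tolerance),
                   error = function(e) NULL)
    rec$acf <- ac
    records[[depth + 1L]] <- rec

    # stop-policy bookkeeping on validation MAPE
    cur_mape <- if (!is.null(rec$validation)) rec$validation$mape else NA_real_
    mape_trace <- c(mape_trace, cur_mape)
    if (depth > 0L) {
      prev <- mape_trace[depth]
      degraded <- is.na(cur_mape) || (!is.na(prev) && prev > 0 &&
        (cur_mape - prev) / prev >= policy$mape_increase_threshold)
      if (degraded) {
        degrade_run <- degrade_run + 1L
        if (degrade_run >= policy$patience) {
          stop_reason <- "mape_increase"
          selected_depth <- depth - degrade_run
          break
        }
      } else {
        degrade_run <- 0L
        selected_depth <- depth
      }
    }

    if (depth >= policy$max_corrections) {
      stop_reason <- "max_corrections"
      break
    }
    if (!is.null(ac) && white_noise_test(ac, acf_tolerance)) {
      stop_reason <- "white_noise"
      break
    }
    if (is.null(ac)) {  # degenerate residuals: nothing left to model
      stop_reason <- "white_noise"
      break
    }
    residuals[[depth + 1L]] <- list(values = e_vals, start = e_start)
    cur_vals <- e_vals
    cur_start <- e_start
  }

  n_stages <- depth + 1L
  models <- models[seq_len(max(n_stages, 1L))]
  if (selection == "best_val_fitness") {
    fits <- vapply(seq_len(n_stages), function(i) {
      r <- records[[i]]$validation
      if (is.null(r) || is.na(r$fitness)) -Inf else r$fitness
    }, numeric(1))
    cand <- seq_len(min(selected_depth + 1L, n_stages))
    selected_depth <- cand[which.max(fits[cand])] - 1L
  }
  structure(list(models = models,
                 residual_series = residuals[seq_len(min(length(residuals),
                                                         n_stages))],
                 iteration_records = records,
                 stop_reason = stop_reason,
                 selected_depth = selected_depth,
                 stage_start = stage_start,
                 boundaries = c(b1, b2),
                 series = ts,
                 seed = as.integer(seed)),
            class = "correction_chain")
}

# Sum stage outputs 0..depth on the intersection of their index ranges.
combined_outputs <- function(stage_out, depth) {
  from <- max(vapply(stage_out[seq_len(depth + 1L)],
                     function(s) s$gindex[1L], numeric(1)))
  last <- stage_out[[1L]]$gindex[length(stage_out[[1L]]$gindex)]
  gindex <- from:last
  total <- numeric(length(gindex))
  for (i in seq_len(depth + 1L)) {
    s <- stage_out[[i]]
    pos <- match(gindex, s$gindex)
    total <- total + s$outputs[pos]
  }
  list(gindex = gindex, outputs = total)
}

#' @export
print.correction_chain <- function(x, ...) {
  cat(sprintf("<correction_chain> %d stage(s), selected depth %d, stop: %s\n",
              length(x$models), x$selected_depth, x$stop_reason))
  for (i in seq_along(x$iteration_records)) {
    r <- x$iteration_records[[i]]
    v <- if (!is.null(r$validation)) sprintf("val MAPE %.2f", r$validation$mape)
         else "val n/a"
    a <- if (!is.null(r$acf))
      sprintf("ACF %d/%d lags out", r$acf$n_exceeding, r$acf$max_lag)
    else "ACF n/a"
    cat(sprintf("  stage %d: %s, %s\n", i - 1L, v, a))
  }
  invisible(x)
}

#' Additive chain forecast of the next value
#'
#' Applies the test-time architecture: the base model predicts the next
#' value from the lagged history, each correction model predicts the next
#' residual of the stage before it from the causally reconstructed residual
#' history, and the final forecast is the sum of stage predictions up to the
#' selected depth. Uses no information beyond the supplied history.
#'
#' @param chain a `correction_chain`.
#' @param history `time_series` or numeric vector of past observations.
#' @param depth stage count to use; defaults to the chain's selected depth.
#' @return A single numeric forecast.
#' @export
chain_forecast <- function(chain, history, depth = chain$selected_depth) {
  stopifnot(inherits(chain, "correction_chain"))
  vals <- series_values(history)
  if (depth > length(chain$models) - 1L)
    stop("chain_forecast: depth exceeds the fitted chain", call. = FALSE)
  total <- 0
  s <- vals
  for (i in 0:depth) {
    model <- chain$models[[i + 1L]]
    total <- total + forecast_next(model, s)
    if (i == depth) break
    fs <- forecast_steps(model, s)
    s <- s[fs$target_index] - fs$outputs
  }
  total
}

#' Stage-wise one-step outputs of a chain over a series
#'
#' Recomputes, causally, the per-stage outputs and the combined forecasts of
#' a fitted chain over a full series (the training-time alignment). Used by
#' the report renderer and for verifying the additive structure.
#'
#' @param chain a `correction_chain`.
#' @param values numeric vector; defaults to the series the chain was fitted
#'   on.
#' @param depth maximum stage index to include.
#' @return A list with `stage` (per-stage list of `outputs` and global
#'   `gindex`) and `combined` (summed outputs on the common index range).
#' @export
chain_outputs <- function(chain, values = chain$series$values,
                          depth = chain$selected_depth) {
  s <- series_values(values)
  stage <- list()
  start <- 1L
  for (i in 0:depth) {
    fs <- forecast_steps(chain$models[[i + 1L]], s)
    gidx <- fs$target_index + start - 1L
    stage[[i + 1L]] <- list(outputs = fs$outputs, gindex = gidx)
    if (i < depth) {
      e <- s[fs$target_index] - fs$outputs
      start <- gidx[1L]
      s <- e
    }
  }
  list(stage = stage, combined = combined_outputs(stage, depth))
}
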