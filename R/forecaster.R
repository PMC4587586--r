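# Common one-step-ahead forecasting surface shared by the plain MLP and the
# GA-optimized hybrid model. `forecast_steps` produces the in-sample /
# causal one-step outputs for every position of a series that has a complete
# lag window; `forecast_next` predicts the single value following the series.

#' One-step-ahead outputs over a whole series
#'
#' @param model a fitted forecaster (`mlp_model` or `hybrid_model`).
#' @param values numeric vector (or `time_series`) of actual observations.
#' @return A list: `outputs` (one prediction per predictable position),
#'   `target_index` (position in `values` each prediction targets) and
#'   `warmup` (number of leading positions without a prediction).
#' @export
forecast_steps <- function(model, values) UseMethod("forecast_steps")

#' Predict the value following a series
#'
#' @inheritParams forecast_steps
#' @return A single numeric prediction for the next time step.
#' @export
forecast_next <- function(model, values) UseMethod("forecast_next")

#' Leading positions a model cannot predict
#' @inheritParams forecast_steps
#' @return Integer warmup length (max lag, plus any phase shift).
#' @export
model_warmup <- function(model) UseMethod("model_warmup")

#' @export
model_warmup.mlp_model <- function(model) model$config$lags[1L]

#' @export
forecast_steps.mlp_model <- function(model, values) {
  vals <- series_values(values)
  ls <- make_lag_matrix(vals, model$config$lags)
  list(outputs = mlp_forward(model, ls$inputs),
       target_index = ls$target_index,
       warmup = model$config$lags[1L])
}

#' @export
forecast_next.mlp_model <- function(model, values) {
  vals <- series_values(values)
  lags <- model$config$lags
  n <- length(vals)
  if (n < lags[1L])
    stop("forecast_next: history shorter than the model's largest lag",
         call. = FALSE)
  row <- matrix(vals[n + 1L - lags], nrow = 1L)
  mlp_forward(model, row)
}

#' @export
model_warmup.hybrid_model <- function(model) {
  sh <- if (is.null(model$phase) || !model$phase$applied) 0L else model$phase$shift
  model_warmup(model$model) + sh
}

#' @export
forecast_steps.hybrid_model <- function(model, values) {
  raw <- forecast_steps(model$model, values)
  ph <- model$phase
  if (is.null(ph) || !ph$applied) return(raw)
  sh <- ph$shift
  m <- length(raw$outputs)
  if (sh == 0L) {
    raw$outputs <- ph$a * raw$outputs + ph$b
    return(raw)
  }
  if (m <= sh)
    stop("forecast_steps: series too short for the phase shift", call. = FALSE)
  list(outputs = ph$a * raw$outputs[seq_len(m - sh)] + ph$b,
       target_index = raw$target_index[(sh + 1L):m],
       warmup = raw$warmup + sh)
}

#' @export
forecast_next.hybrid_model <- function(model, values) {
  vals <- series_values(values)
  ph <- model$phase
  if (is.null(ph) || !ph$applied) return(forecast_next(model$model, vals))
  if (ph$shift == 0L) return(ph$a * forecast_next(model$model, vals) + ph$b)
  # shift 1: the adjusted next-step prediction reuses the raw output for the
  # current last observation, computed from history up to the step before it
  n <- length(vals)
  raw_prev <- forecast_next(model$model, vals[seq_len(n - 1L)])
  ph$a * raw_prev + ph$b
}
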