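#' @name forecast-metrics
#' @title Forecast evaluation metrics
#'
#' @description
#' The six metrics used to score one-step-ahead forecasts — mean squared
#' error (MSE), mean absolute percentage error (MAPE), Theil's U statistic,
#' average relative variance (ARV), prediction of change in direction
#' (POCID) and index of agreement (IA) — plus the composite fitness
#'
#' \deqn{Fitness = POCID / (1 + MSE + MAPE + U + ARV)}
#'
#' that serves as the genetic-algorithm objective and model-selection score.
#' MAPE and POCID enter the fitness on the percent scale.
#'
#' Two of the printed formulas are deliberately nonstandard and are
#' implemented as printed: Theil's U divides by summed squared successive
#' differences of the *forecasts* (set `u_denominator = "targets"` for the
#' classical random-walk form), and ARV/IA measure spread of the *forecasts*
#' around the target mean (set `form = "classical"` for textbook variants).
#'
#' @param targets numeric vector of observed values.
#' @param outputs numeric vector of forecasts, same length.
#' @return A single numeric value (POCID and MAPE on the percent scale).
NULL

check_pair <- function(targets, outputs, min_len = 1L) {
  if (length(targets) != length(outputs))
    stop("targets and outputs must have the same length", call. = FALSE)
  if (length(targets) < min_len)
    stop(sprintf("need at least %d aligned points", min_len), call. = FALSE)
  if (!all(is.finite(targets)) || !all(is.finite(outputs)))
    stop("targets and outputs must be finite", call. = FALSE)
}

#' @rdname forecast-metrics
#' @export
mse <- function(targets, outputs) {
  check_pair(targets, outputs)
  mean((targets - outputs)^2)
}

#' @rdname forecast-metrics
#' @param eps targets with absolute value below `eps` are excluded from the
#'   MAPE sum (min-max normalization forces at least one exact zero into the
#'   series); the exclusion count is attached as attribute `n_excluded`.
#' @export
mape <- function(targets, outputs, eps = 1e-8) {
  check_pair(targets, outputs)
  keep <- abs(targets) >= eps
  if (!any(keep))
    stop("mape: undefined, all targets below eps", call. = FALSE)
  val <- 100 * mean(abs((targets[keep] - outputs[keep]) / targets[keep]))
  attr(val, "n_excluded") <- sum(!keep)
  val
}

#' @rdname forecast-metrics
#' @param u_denominator `"outputs"` (as printed: squared successive forecast
#'   differences) or `"targets"` (classical random-walk denominator).
#' @export
theil_u <- function(targets, outputs, u_denominator = c("outputs", "targets")) {
  check_pair(targets, outputs, min_len = 2L)
  u_denominator <- match.arg(u_denominator)
  ref <- if (u_denominator == "outputs") outputs else targets
  den <- sum(diff(ref)^2)
  if (den == 0)
    stop("theil_u: zero denominator (constant successive differences)",
         call. = FALSE)
  sum((targets - outputs)^2) / den
}

#' @rdname forecast-metrics
#' @param form `"printed"` (forecast spread around the target mean in the
#'   denominator) or `"classical"` (target spread around the target mean).
#' @export
arv <- function(targets, outputs, form = c("printed", "classical")) {
  check_pair(targets, outputs)
  form <- match.arg(form)
  tbar <- mean(targets)
  den <- if (form == "printed") sum((outputs - tbar)^2)
         else sum((targets - tbar)^2)
  if (den == 0)
    stop("arv: zero denominator (no spread around the target mean)",
         call. = FALSE)
  sum((outputs - targets)^2) / den
}

#' @rdname forecast-metrics
#' @details POCID counts steps j = 2..N whose target change and forecast
#'   change have the same strict sign, as a percentage of N - 1 steps; a zero
#'   change on either side never counts as a hit.
#' @export
pocid <- function(targets, outputs) {
  check_pair(targets, outputs, min_len = 2L)
  d <- diff(targets) * diff(outputs)
  100 * sum(d > 0) / (length(targets) - 1L)
}

#' @rdname forecast-metrics
#' @export
ia <- function(targets, outputs, form = c("printed", "classical")) {
  check_pair(targets, outputs)
  form <- match.arg(form)  # printed form coincides with Willmott's classical IA
  tbar <- mean(targets)
  num <- sum(abs(outputs - targets)^2)
  den <- sum((abs(outputs - tbar) + abs(targets - tbar))^2)
  if (den == 0)
    stop("ia: zero denominator (all points at the target mean)", call. = FALSE)
  1 - num / den
}

#' Composite fitness of a forecast
#'
#' `Fitness = POCID / (1 + MSE + MAPE + U + ARV)`, with MAPE and POCID on the
#' percent scale. Higher is better; a value approaches 100 only when POCID is
#' near 100 and the four error terms are near zero. The denominator is always
#' at least 1, so the score is defined for any valid metric combination.
#'
#' @param pocid,mse,mape,theil_u,arv the component metric values
#'   (non-negative; POCID and MAPE in percent).
#' @return The fitness score (numeric scalar).
#' @examples
#' fitness_score(pocid = 97.16, mse = 6.00e-4, mape = 35.93,
#'               theil_u = 0.0969, arv = 0.3077)  # ~2.60
#' @export
fitness_score <- function(pocid, mse, mape, theil_u, arv) {
  vals <- c(pocid, mse, mape, theil_u, arv)
  if (!all(is.finite(vals)) || any(vals < 0))
    stop("fitness_score: all components must be finite and non-negative",
         call. = FALSE)
  pocid / (1 + mse + mape + theil_u + arv)
}

#' Evaluate all metrics for one forecast/target pair
#'
#' Computes the six metrics and the composite fitness on the same aligned
#' pair. Components that are undefined for the pair (e.g. Theil's U with
#' constant forecasts) are recorded as `NA` with an explanatory flag instead
#' of aborting; the fitness is then `NA` too.
#'
#' @param targets,outputs aligned numeric vectors (length >= 2).
#' @param u_denominator,form,eps see [theil_u()], [arv()], [mape()].
#' @return A `metrics_report` list with fields `mse`, `mape`, `theil_u`,
#'   `arv`, `pocid`, `ia`, `fitness`, `n`, `n_mape_excluded` and `flags`.
#' @export
evaluate_forecast <- function(targets, outputs,
                              u_denominator = c("outputs", "targets"),
                              form = c("printed", "classical"),
                              eps = 1e-8) {
  check_pair(targets, outputs, min_len = 2L)
  u_denominator <- match.arg(u_denominator)
  form <- match.arg(form)
  flags <- character(0)
  grab <- function(expr, label) {
    v <- tryCatch(expr, error = function(e) {
      flags <<- c(flags, paste0(label, ": ", conditionMessage(e)))
      NA_real_
    })
    v
  }
  m_mse <- grab(mse(targets, outputs), "mse")
  m_mape <- grab(mape(targets, outputs, eps = eps), "mape")
  n_exc <- if (is.na(m_mape)) NA_integer_ else attr(m_mape, "n_excluded")
  m_u <- grab(theil_u(targets, outputs, u_denominator), "theil_u")
  m_arv <- grab(arv(targets, outputs, form), "arv")
  m_pocid <- grab(pocid(targets, outputs), "pocid")
  m_ia <- grab(ia(targets, outputs, form), "ia")
  fit <- if (anyNA(c(m_pocid, m_mse, m_mape, m_u, m_arv))) NA_real_
         else fitness_score(m_pocid, m_mse, as.numeric(m_mape), m_u, m_arv)
  structure(list(mse = m_mse, mape = as.numeric(m_mape), theil_u = m_u,
                 arv = m_arv, pocid = m_pocid, ia = m_ia, fitness = fit,
                 n = length(targets), n_mape_excluded = n_exc, flags = flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> n = %d\n",
                     "  MSE %.4g  POCID %.2f  U %.4g  MAPE %.2f  ARV %.4g",
                     "  IA %.3f  Fitness %.2f\n"),
              x$n, x$mse, x$pocid, x$theil_u, x$mape, x$arv, x$ia, x$fitness))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Per-metric ratio between two forecast evaluations
#'
#' Elementwise ratio corrected / uncorrected for all seven quantities,
#' used to compare a correction stage against the previous stage (or against
#' the uncorrected base model). For MSE, U, MAPE and ARV a ratio below 1
#' means the correction improved the forecast; for POCID, IA and fitness a
#' ratio above 1 does.
#'
#' @param corrected,uncorrected `metrics_report` objects.
#' @return A `ratio_report` with one ratio per metric; metrics whose
#'   uncorrected value is zero or undefined get `NA` and a flag.
#' @export
metric_ratio <- function(corrected, uncorrected) {
  stopifnot(inherits(corrected, "metrics_report"),
            inherits(uncorrected, "metrics_report"))
  fields <- c("mse", "pocid", "theil_u", "mape", "arv", "ia", "fitness")
  flags <- character(0)
  out <- lapply(fields, function(f) {
    a <- corrected[[f]]; b <- uncorrected[[f]]
    if (is.na(a) || is.na(b) || b == 0) {
      flags <<- c(flags, paste0(f, ": undefined ratio"))
      NA_real_
    } else a / b
  })
  names(out) <- fields
  structure(c(out, list(flags = flags)), class = "ratio_report")
}

#' @export
print.ratio_report <- function(x, ...) {
  cat(sprintf(paste0("<ratio_report> MSE %.3f  POCID %.3f  U %.3f",
                     "  MAPE %.3f  ARV %.3f  IA %.3f  Fitness %.3f\n"),
              x$mse, x$pocid, x$theil_u, x$mape, x$arv, x$ia, x$fitness))
  invisible(x)
}
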