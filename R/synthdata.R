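# Seeded generators producing series with the statistical structure the
# method assumes: an autocorrelated linear part, a nonlinear part the linear
# model cannot capture, and white-noise innovations; plus a positive,
# right-skewed, autocorrelated series resembling daily mean particulate-
# matter concentrations.

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Seeded Gaussian white noise
#'
#' @param n series length.
#' @param sigma standard deviation of the i.i.d. innovations.
#' @param seed integer seed; the same seed always reproduces the same draw.
#' @return A `time_series`.
#' @export
gen_white_noise <- function(n, sigma = 1, seed = 1L) {
  stopifnot(n >= 1, sigma > 0)
  with_seed(seed, time_series(stats::rnorm(n, 0, sigma), name = "white_noise"))
}

ar_spectral_radius <- function(coeffs) {
  p <- length(coeffs)
  if (p == 1L) return(abs(coeffs))
  M <- rbind(coeffs, cbind(diag(p - 1L), 0))
  max(Mod(eigen(M, only.values = TRUE)$values))
}

# AR(p) recursion on a given innovation vector, burn-in included in eps.
ar_filter <- function(eps, coeffs) {
  p <- length(coeffs)
  x <- numeric(length(eps))
  for (t in seq_along(eps)) {
    past <- 0
    for (j in seq_len(min(p, t - 1L)))
      past <- past + coeffs[j] * x[t - j]
    x[t] <- past + eps[t]
  }
  x
}

#' Seeded stationary AR(p) series
#'
#' Simulates the autoregressive recursion after a burn-in of 10 * p steps to
#' remove the initialization transient. Coefficients must define a
#' stationary process (companion-matrix spectral radius < 1).
#'
#' @param n series length after burn-in.
#' @param coeffs AR coefficients, lag 1 first.
#' @param sigma innovation standard deviation.
#' @param seed integer seed.
#' @return A `time_series`.
#' @export
gen_ar <- function(n, coeffs, sigma = 1, seed = 1L) {
  stopifnot(n >= 1, sigma > 0, length(coeffs) >= 1)
  if (ar_spectral_radius(coeffs) >= 1)
    stop("gen_ar: non-stationary coefficients (spectral radius >= 1)",
         call. = FALSE)
  burn <- 10L * length(coeffs)
  x <- with_seed(seed, ar_filter(stats::rnorm(n + burn, 0, sigma), coeffs))
  time_series(x[(burn + 1L):(burn + n)], name = "ar")
}

#' Composite series: linear + nonlinear + noise
#'
#' Generates a series as the exact elementwise sum of three components: a
#' stationary AR linear part, a nonlinear transform of the *lagged observed
#' value*, and Gaussian noise. The nonlinear component is built recursively
#' as `amplitude * g(x[t-1])`, a function of the observable history, so it
#' is forecastable by construction — the structure a purely linear one-lag
#' predictor leaves in its residuals. The defaults — AR(2) coefficients
#' (0.6, -0.2), a sinusoid modulation of amplitude 0.5 * sd(linear part)
#' and noise at signal-to-noise ratio 5 — give a series whose one-lag
#' linear predictor demonstrably under-fits.
#'
#' All form functions have bounded slope (the quadratic uses a saturating
#' square, x^2/(1+|x|)), so the feedback recursion is stable for amplitudes
#' below roughly 1/sd(linear part).
#'
#' @param n series length.
#' @param ar_coeffs AR coefficients of the linear part.
#' @param nonlinear list with `form` (one of `"sine_mod"`, `"quadratic"`,
#'   `"threshold"`) and optional `amplitude`; `NULL` amplitude defaults to
#'   0.5 * sd(linear part).
#' @param noise_sigma sd of the additive noise; `NULL` sets it from `snr`
#'   (variance ratio of the linear part to the noise).
#' @param snr signal-to-noise variance ratio used when `noise_sigma` is NULL.
#' @param seed integer seed.
#' @return A `synthetic_bundle`: `series` (`time_series`), `components`
#'   (linear, nonlinear, noise vectors summing exactly to the series) and
#'   `spec` (the generating parameters, sufficient for bitwise regeneration).
#' @export
gen_composite <- function(n, ar_coeffs = c(0.6, -0.2),
                          nonlinear = list(form = "sine_mod", amplitude = NULL),
                          noise_sigma = NULL, snr = 5, seed = 1L) {
  stopifnot(n >= 10)
  form <- match.arg(nonlinear$form, c("sine_mod", "quadratic", "threshold"))
  lin <- gen_ar(n, ar_coeffs, sigma = 1, seed = seed)$values
  amp <- nonlinear$amplitude
  if (is.null(amp)) amp <- 0.5 * stats::sd(lin)
  if (is.null(noise_sigma))
    noise_sigma <- stats::sd(lin) / sqrt(snr)
  noise <- with_seed(seed + 1L, stats::rnorm(n, 0, noise_sigma))
  g <- switch(form,
              sine_mod = function(x) sin(x),
              quadratic = function(x) x^2 / (1 + abs(x)),
              threshold = function(x) x * (x > 0))
  x <- numeric(n); nl <- numeric(n)
  for (t in seq_len(n)) {
    nl[t] <- if (t == 1L) 0 else amp * g(x[t - 1L])
    x[t] <- lin[t] + nl[t] + noise[t]
  }
  structure(list(series = time_series(x, name = "composite"),
                 components = list(linear = lin, nonlinear = nl,
                                   noise = noise),
                 spec = list(n = n, ar_coeffs = ar_coeffs, form = form,
                             amplitude = amp, noise_sigma = noise_sigma,
                             seed = seed)),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle> n = %d, form %s, amplitude %.3f, noise sd %.3f\n",
              x$spec$n, x$spec$form, x$spec$amplitude, x$spec$noise_sigma))
  invisible(x)
}

#' Synthetic daily particulate-matter-like series
#'
#' The exponential of a seasonal AR(1) Gaussian process, scaled to a
#' typical daily-mean concentration range (median around 12 micrograms per
#' cubic meter): strictly positive, right-skewed, autocorrelated, with a
#' mild annual cycle. A stand-in with the qualitative features of urban
#' PM2.5/PM10 monitoring series, not a fit to any real station.
#'
#' @param n series length (>= 30).
#' @param seed integer seed.
#' @param phi AR(1) coefficient of the log-scale process.
#' @param season_amp amplitude of the annual cycle on the log scale.
#' @return A `time_series`.
#' @export
gen_pm_like <- function(n, seed = 1L, phi = 0.8, season_amp = 0.3) {
  stopifnot(n >= 30)
  z <- gen_ar(n, phi, sigma = sqrt(1 - phi^2), seed = seed)$values
  season <- season_amp * sin(2 * pi * seq_len(n) / 365)
  time_series(exp(2.5 + 0.5 * z + season), name = "pm_like")
}
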