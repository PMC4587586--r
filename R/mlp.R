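#' Multilayer-perceptron forecaster configuration
#'
#' One hidden layer of logistic-sigmoid units and (by default) a linear
#' output unit — data are expected on the normalized [0, 1] scale, where a
#' linear output avoids saturation at the range edges. The network maps a
#' window of lagged series values to the one-step-ahead prediction.
#'
#' @param n_inputs integer lag count (lags 1..L) or an explicit integer
#'   vector of lag distances; defines the input layer width.
#' @param n_hidden number of hidden units, between 1 and `max_hidden`.
#' @param trainer one of `"lm"` (Levenberg-Marquardt), `"scg"` (scaled
#'   conjugate gradient), `"rprop"` (resilient backpropagation) or `"oss"`
#'   (one-step secant).
#' @param output_activation `"linear"` (default) or `"logistic"`, which
#'   bounds predictions in (0, 1).
#' @param seed integer seed for weight initialization.
#' @param max_hidden upper bound on hidden-layer size.
#' @return An `mlp_config` object.
#' @export
mlp_config <- function(n_inputs, n_hidden, trainer = c("lm", "scg", "rprop", "oss"),
                       output_activation = c("linear", "logistic"),
                       seed = 1L, max_hidden = 20L) {
  trainer <- match.arg(trainer)
  output_activation <- match.arg(output_activation)
  lags <- as.integer(n_inputs)
  if (length(lags) == 1L) lags <- seq_len(lags)
  if (length(lags) < 1L || any(lags < 1L) || anyDuplicated(lags))
    stop("mlp_config: lags must be distinct positive integers", call. = FALSE)
  lags <- sort(lags, decreasing = TRUE)
  n_hidden <- as.integer(n_hidden)
  if (is.na(n_hidden) || n_hidden < 1L || n_hidden > max_hidden)
    stop(sprintf("mlp_config: n_hidden must be in [1, %d]", max_hidden),
         call. = FALSE)
  structure(list(lags = lags, n_inputs = length(lags), n_hidden = n_hidden,
                 trainer = trainer, output_activation = output_activation,
                 seed = as.integer(seed)), class = "mlp_config")
}

#' Training stop options
#'
#' The three stopping conditions for network training: an iteration cap, a
#' generalization-loss criterion on validation error (stop when the current
#' validation error exceeds the best seen so far by more than
#' `generalization_loss_pct` percent, restoring the best weights), and a
#' minimum training-error progress over a short window.
#'
#' @param max_iterations iteration cap (default 1000).
#' @param generalization_loss_pct validation-loss tolerance in percent
#'   (default 5): stop when 100 * (E_val / min E_val - 1) exceeds it.
#' @param min_progress minimum decrease of training MSE over
#'   `progress_window` monitored strips (default 1e-6).
#' @param progress_window window length, in strips, for the progress check.
#' @param eval_strip iterations per monitoring strip (default 5): training
#'   and validation errors are checked at the end of each strip.
#' @return A `train_options` object.
#' @export
train_options <- function(max_iterations = 1000L, generalization_loss_pct = 5,
                          min_progress = 1e-6, progress_window = 5L,
                          eval_strip = 5L) {
  stopifnot(max_iterations >= 1, generalization_loss_pct > 0,
            min_progress > 0, progress_window >= 1, eval_strip >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 generalization_loss_pct = generalization_loss_pct,
                 min_progress = min_progress,
                 progress_window = as.integer(progress_window),
                 eval_strip = as.integer(eval_strip)),
            class = "train_options")
}

n_params <- function(cfg) cfg$n_hidden * cfg$n_inputs + cfg$n_hidden +
  cfg$n_hidden + 1L

pack_theta <- function(W1, b1, w2, b2) c(as.vector(W1), b1, w2, b2)

unpack_theta <- function(theta, cfg) {
  h <- cfg$n_hidden; p <- cfg$n_inputs
  W1 <- matrix(theta[seq_len(h * p)], nrow = h)
  b1 <- theta[h * p + seq_len(h)]
  w2 <- theta[h * p + h + seq_len(h)]
  b2 <- theta[h * p + 2L * h + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

#' Initialize an MLP with seeded random weights
#'
#' Weights are drawn uniformly in [-0.5, 0.5] scaled by 1/sqrt(fan-in), so
#' the same configuration always yields bitwise-identical weights.
#'
#' @param config an [mlp_config()].
#' @return An `mlp_model` (config, weight vector, empty training log).
#' @export
mlp_init <- function(config) {
  stopifnot(inherits(config, "mlp_config"))
  h <- config$n_hidden; p <- config$n_inputs
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  W1 <- matrix(runif(h * p, -0.5, 0.5) / sqrt(p), nrow = h)
  b1 <- runif(h, -0.5, 0.5) / sqrt(p)
  w2 <- runif(h, -0.5, 0.5) / sqrt(h)
  b2 <- runif(1, -0.5, 0.5)
  structure(list(config = config, theta = pack_theta(W1, b1, w2, b2),
                 training_log = NULL, stop_reason = NULL, flags = character(0)),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mlp_model> lags {%s} -> %d hidden (%s output), trainer %s\n",
              paste(rev(cfg$lags), collapse = ","), cfg$n_hidden,
              cfg$output_activation, toupper(cfg$trainer)))
  if (!is.null(x$training_log))
    cat(sprintf("  trained %d iterations, stop: %s, val MSE %.4g\n",
                nrow(x$training_log), x$stop_reason,
                min(x$training_log$val_mse)))
  invisible(x)
}

# Forward pass on a raw parameter vector; returns predictions and hidden
# activations (needed by backprop and the Jacobian).
net_forward <- function(theta, X, cfg) {
  w <- unpack_theta(theta, cfg)
  A <- X %*% t(w$W1)
  A <- sweep(A, 2L, w$b1, "+")
  H <- plogis(A)
  y <- unname(drop(H %*% w$w2) + w$b2)
  if (cfg$output_activation == "logistic") y <- plogis(y)
  list(y = y, H = H)
}

net_mse <- function(theta, X, t, cfg) {
  y <- net_forward(theta, X, cfg)$y
  mean((y - t)^2)
}

# Gradient of the mean squared error wrt the packed parameter vector.
net_grad <- function(theta, X, t, cfg) {
  w <- unpack_theta(theta, cfg)
  fw <- net_forward(theta, X, cfg)
  n <- length(t)
  dy <- fw$y - t
  if (cfg$output_activation == "logistic") dy <- dy * fw$y * (1 - fw$y)
  dy <- 2 * dy / n
  g_b2 <- sum(dy)
  g_w2 <- drop(crossprod(fw$H, dy))
  dH <- (dy %o% w$w2) * fw$H * (1 - fw$H)
  g_b1 <- colSums(dH)
  g_W1 <- crossprod(dH, X)  # h x p, matches the W1 slot layout
  pack_theta(g_W1, g_b1, g_w2, g_b2)
}

# Jacobian d yhat / d theta (rows = samples), used by Levenberg-Marquardt.
net_jacobian <- function(theta, X, cfg) {
  w <- unpack_theta(theta, cfg)
  fw <- net_forward(theta, X, cfg)
  h <- cfg$n_hidden; p <- cfg$n_inputs
  D <- fw$H * (1 - fw$H)
  Dw <- sweep(D, 2L, w$w2, "*")          # n x h, w2_j * H(1-H)
  J_W1 <- X[, rep(seq_len(p), each = h), drop = FALSE] *
    Dw[, rep(seq_len(h), p), drop = FALSE]
  J <- cbind(J_W1, Dw, fw$H, 1)
  if (cfg$output_activation == "logistic") J <- J * (fw$y * (1 - fw$y))
  J
}

#' Apply a trained (or freshly initialized) MLP to input rows
#'
#' @param model an `mlp_model`.
#' @param input_rows numeric matrix whose column count equals the configured
#'   input width (one lag window per row).
#' @return Numeric vector of one prediction per row.
#' @export
mlp_forward <- function(model, input_rows) {
  stopifnot(inherits(model, "mlp_model"))
  input_rows <- as.matrix(input_rows)
  if (ncol(input_rows) != model$config$n_inputs)
    stop("mlp_forward: input width does not match the configuration",
         call. = FALSE)
  net_forward(model$theta, input_rows, model$config)$y
}
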