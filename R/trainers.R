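# The four batch trainers. Each is a stepper: given (theta, state, problem)
# it performs one outer iteration and returns list(theta, state, ok). A
# shared driver handles logging, the generalization-loss early stop and
# best-validation weight restore.

# --- Levenberg-Marquardt: damped Gauss-Newton on the full-batch Jacobian ----
step_lm <- function(theta, state, pb) {
  if (is.null(state)) state <- list(lambda = 1e-3)
  r <- net_forward(theta, pb$X, pb$cfg)$y - pb$t
  J <- net_jacobian(theta, pb$X, pb$cfg)
  JtJ <- crossprod(J)
  Jtr <- crossprod(J, r)
  sse0 <- sum(r^2)
  for (try in 1:30) {
    A <- JtJ + state$lambda * diag(nrow(JtJ))
    delta <- tryCatch(solve(A, Jtr), error = function(e) NULL)
    if (!is.null(delta)) {
      cand <- unname(theta - drop(delta))
      sse1 <- sum((net_forward(cand, pb$X, pb$cfg)$y - pb$t)^2)
      if (is.finite(sse1) && sse1 < sse0) {
        state$lambda <- max(state$lambda / 10, 1e-12)
        return(list(theta = cand, state = state, ok = TRUE))
      }
    }
    state$lambda <- state$lambda * 10
    if (state$lambda > 1e12) break
  }
  list(theta = theta, state = state, ok = FALSE)  # no acceptable step
}

# --- RPROP (classic): sign-based per-parameter step sizes -------------------
step_rprop <- function(theta, state, pb) {
  if (is.null(state))
    state <- list(delta = rep(0.1, length(theta)),
                  g_prev = rep(0, length(theta)))
  g <- net_grad(theta, pb$X, pb$t, pb$cfg)
  sgn <- state$g_prev * g
  up <- sgn > 0; dn <- sgn < 0
  state$delta[up] <- pmin(state$delta[up] * 1.2, 50)
  state$delta[dn] <- pmax(state$delta[dn] * 0.5, 1e-12)
  g[dn] <- 0  # skip the update where the gradient changed sign
  theta <- theta - sign(g) * state$delta
  state$g_prev <- g
  list(theta = theta, state = state, ok = TRUE)
}

# --- Scaled conjugate gradient (Moller's parameterization) ------------------
step_scg <- function(theta, state, pb) {
  E <- function(w) net_mse(w, pb$X, pb$t, pb$cfg)
  G <- function(w) net_grad(w, pb$X, pb$t, pb$cfg)
  if (is.null(state)) {
    g <- G(theta)
    state <- list(lambda = 1e-6, lambdabar = 0, r = -g, p = -g,
                  success = TRUE, k = 0L)
  }
  s0 <- 1e-4
  for (attempt in 1:20) {  # unsuccessful steps raise lambda and retry
    p <- state$p; r <- state$r
    p2 <- sum(p^2)
    if (p2 < 1e-300) return(list(theta = theta, state = state, ok = FALSE))
    if (state$success) {
      sigma <- s0 / sqrt(p2)
      state$s <- (G(theta + sigma * p) - G(theta)) / sigma
      state$delta <- sum(p * state$s)
    }
    delta <- state$delta + (state$lambda - state$lambdabar) * p2
    if (delta <= 0) {
      state$lambdabar <- 2 * (state$lambda - delta / p2)
      delta <- -delta + state$lambda * p2
      state$lambda <- state$lambdabar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    E0 <- E(theta)
    cand <- theta + alpha * p
    Delta <- 2 * delta * (E0 - E(cand)) / mu^2
    if (is.finite(Delta) && Delta >= 0) {
      theta <- cand
      g_new <- G(theta)
      r_new <- -g_new
      state$lambdabar <- 0
      state$success <- TRUE
      state$k <- state$k + 1L
      if (state$k %% length(theta) == 0L) {
        state$p <- r_new
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        state$p <- r_new + beta * p
      }
      state$r <- r_new
      if (Delta >= 0.75) state$lambda <- state$lambda / 4
      if (Delta < 0.25)
        state$lambda <- min(state$lambda + delta * (1 - Delta) / p2, 1e12)
      return(list(theta = theta, state = state, ok = TRUE))
    }
    state$lambdabar <- state$lambda
    state$success <- FALSE
    state$lambda <- min(state$lambda + delta *
                          (1 - max(if (is.finite(Delta)) Delta else -1, -1)) / p2,
                        1e12)
    if (state$lambda >= 1e12) break
  }
  list(theta = theta, state = state, ok = FALSE)
}

# --- One-step secant quasi-Newton with backtracking line search -------------
step_oss <- function(theta, state, pb) {
  E <- function(w) net_mse(w, pb$X, pb$t, pb$cfg)
  g <- net_grad(theta, pb$X, pb$t, pb$cfg)
  d <- -g
  if (!is.null(state) && !is.null(state$s)) {
    s <- state$s; yv <- g - state$g_prev
    sty <- sum(s * yv)
    if (is.finite(sty) && sty > 1e-12) {
      B <- sum(s * g) / sty
      A <- -(1 + sum(yv * yv) / sty) * B + sum(yv * g) / sty
      d <- -g + A * s + B * yv
      if (sum(d * g) >= 0) d <- -g  # not a descent direction: restart
    }
  }
  E0 <- E(theta); gd <- sum(g * d)
  alpha <- 1
  ok <- FALSE
  for (i in 1:25) {
    cand <- theta + alpha * d
    E1 <- E(cand)
    if (is.finite(E1) && E1 <= E0 + 1e-4 * alpha * gd) { ok <- TRUE; break }
    alpha <- alpha / 2
  }
  if (!ok) return(list(theta = theta, state = state, ok = FALSE))
  state <- list(g_prev = g, s = alpha * d)
  list(theta = cand, state = state, ok = TRUE)
}

#' Train an MLP with validation-based early stopping
#'
#' Runs the configured batch trainer (Levenberg-Marquardt, scaled conjugate
#' gradient, RPROP or one-step secant) and returns the weight snapshot with
#' the lowest validation error seen along the trajectory. Training stops at
#' the iteration cap, when the generalization loss
#' 100 * (E_val / min E_val - 1) exceeds its tolerance, when training-error
#' progress over a short window falls below `min_progress`, or when the
#' trainer can make no further acceptable step. Divergence (non-finite loss)
#' reverts to the best snapshot and sets a flag.
#'
#' @param model an `mlp_model` from [mlp_init()].
#' @param train_set,val_set `lag_set` objects (see [make_lag_matrix()]) with
#'   matching input width.
#' @param opts a [train_options()]; errors are monitored at the end of every
#'   strip of `eval_strip` iterations.
#' @return The trained `mlp_model` with `training_log` (iteration, train and
#'   validation MSE at each monitored point) and `stop_reason` filled in.
#' @export
mlp_train <- function(model, train_set, val_set, opts = train_options()) {
  stopifnot(inherits(model, "mlp_model"))
  cfg <- model$config
  X <- as.matrix(train_set$inputs); t <- train_set$targets
  Xv <- as.matrix(val_set$inputs); tv <- val_set$targets
  if (ncol(X) != cfg$n_inputs || ncol(Xv) != cfg$n_inputs)
    stop("mlp_train: lag-set width does not match the model configuration",
         call. = FALSE)
  if (length(t) == 0L || length(tv) == 0L)
    stop("mlp_train: empty training or validation set", call. = FALSE)
  pb <- list(X = X, t = t, cfg = cfg)
  stepper <- switch(cfg$trainer, lm = step_lm, scg = step_scg,
                    rprop = step_rprop, oss = step_oss)
  theta <- model$theta
  state <- NULL
  e_tr <- net_mse(theta, X, t, cfg)
  e_va <- net_mse(theta, Xv, tv, cfg)
  log_it <- numeric(opts$max_iterations + 1L)
  log_tr <- numeric(opts$max_iterations + 1L)
  log_va <- numeric(opts$max_iterations + 1L)
  log_it[1] <- 0; log_tr[1] <- e_tr; log_va[1] <- e_va
  best_va <- e_va; best_theta <- theta
  stop_reason <- "max_iterations"
  flags <- character(0)
  n_logged <- 1L
  strip <- opts$eval_strip
  log_state <- function(it) {
    # evaluate and snapshot the current weights (used at strip ends and
    # before any early exit, so unlogged progress is never lost)
    e_tr <<- net_mse(theta, X, t, cfg)
    e_va <<- net_mse(theta, Xv, tv, cfg)
    if (!is.finite(e_tr) || !is.finite(e_va)) return(FALSE)
    n_logged <<- n_logged + 1L
    log_it[n_logged] <<- it; log_tr[n_logged] <<- e_tr; log_va[n_logged] <<- e_va
    if (e_va < best_va) { best_va <<- e_va; best_theta <<- theta }
    TRUE
  }
  for (it in seq_len(opts$max_iterations)) {
    res <- stepper(theta, state, pb)
    state <- res$state
    if (!res$ok) {
      stop_reason <- "no_progress_step"
      log_state(it)
      break
    }
    theta <- res$theta
    # validation is monitored at the end of every strip of iterations, as in
    # the GL_alpha early-stopping criterion
    if (it %% strip != 0L && it != opts$max_iterations) next
    if (!log_state(it)) {
      flags <- c(flags, "diverged")
      stop_reason <- "diverged"
      theta <- best_theta
      break
    }
    gl <- if (best_va == 0) { if (e_va == 0) 0 else Inf }
          else 100 * (e_va / best_va - 1)
    if (gl > opts$generalization_loss_pct) {
      stop_reason <- "generalization_loss"
      break
    }
    w <- opts$progress_window
    if (n_logged > w &&
        (log_tr[n_logged - w] - log_tr[n_logged]) < opts$min_progress) {
      stop_reason <- "min_progress"
      break
    }
  }
  model$theta <- best_theta
  model$training_log <- data.frame(iteration = log_it[seq_len(n_logged)],
                                   train_mse = log_tr[seq_len(n_logged)],
                                   val_mse = log_va[seq_len(n_logged)])
  model$stop_reason <- stop_reason
  model$flags <- flags
  model$val_mse <- best_va
  model
}
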