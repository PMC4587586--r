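#' Genetic-algorithm parameters for the hybrid system
#'
#' The hybrid system searches the MLP structure — number of relevant time
#' lags, hidden-layer size and training algorithm among four candidates —
#' with a small-population genetic algorithm scored by the composite fitness
#' on the validation segment, then optionally applies a phase adjustment.
#'
#' @param mutation_prob per-gene mutation probability (default 0.10).
#' @param pop_size population size (default 10).
#' @param max_generations generation cap (default 1000).
#' @param min_fitness_progress minimum improvement of the best validation
#'   fitness over `progress_patience` generations before the search stops
#'   (default 1e-4).
#' @param acceptable_fitness_error early exit when the best model's
#'   validation RMSE (normalized scale) drops to this level, read as "1% of
#'   error" (default 0.01).
#' @param max_lags upper bound on the lag count gene (default 10).
#' @param max_hidden upper bound on the hidden-unit gene (default 20).
#' @param max_outer_iterations outer restarts of the GA+training cycle,
#'   keeping the best-ever model (default 10; set to 1 for speed).
#' @param crossover_prob uniform-crossover probability (default 0.9).
#' @param tournament_size selection tournament size (default 2).
#' @param elitism number of elites copied unchanged (default 1).
#' @param progress_patience generations without sufficient progress before
#'   stopping (default 5).
#' @param trainers candidate training algorithms (gene alphabet).
#' @param train_opts a [train_options()] shared by all evaluations.
#' @param seed master seed of the search.
#' @return A `ga_params` object.
#' @export
ga_params <- function(mutation_prob = 0.10, pop_size = 10L,
                      max_generations = 1000L, min_fitness_progress = 1e-4,
                      acceptable_fitness_error = 0.01, max_lags = 10L,
                      max_hidden = 20L, max_outer_iterations = 10L,
                      crossover_prob = 0.9, tournament_size = 2L,
                      elitism = 1L, progress_patience = 5L,
                      trainers = c("lm", "scg", "rprop", "oss"),
                      train_opts = train_options(), seed = 1L) {
  stopifnot(mutation_prob >= 0, mutation_prob <= 1, pop_size >= 2,
            max_generations >= 1, min_fitness_progress > 0,
            acceptable_fitness_error > 0, max_lags >= 1, max_hidden >= 1,
            max_outer_iterations >= 1, crossover_prob >= 0,
            crossover_prob <= 1, tournament_size >= 1, elitism >= 0,
            progress_patience >= 1, length(trainers) >= 1)
  structure(list(mutation_prob = mutation_prob, pop_size = as.integer(pop_size),
                 max_generations = as.integer(max_generations),
                 min_fitness_progress = min_fitness_progress,
                 acceptable_fitness_error = acceptable_fitness_error,
                 max_lags = as.integer(max_lags),
                 max_hidden = as.integer(max_hidden),
                 max_outer_iterations = as.integer(max_outer_iterations),
                 crossover_prob = crossover_prob,
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 progress_patience = as.integer(progress_patience),
                 trainers = trainers, train_opts = train_opts,
                 seed = as.integer(seed)),
            class = "ga_params")
}

# Deterministic per-chromosome seed so cached evaluations and reruns agree.
chromosome_seed <- function(base_seed, ch) {
  as.integer((as.double(base_seed) * 7 + ch$n_lags * 131 +
                ch$n_hidden * 17 + ch$trainer_id * 3) %% 2147483629) + 1L
}

# Decode, train and score one chromosome on the validation segment.
eval_chromosome <- function(ch, train_vals, val_vals, params) {
  if (ch$n_lags >= length(train_vals)) return(NULL)
  sets <- supervised_sets(train_vals, val_vals, ch$n_lags)
  cfg <- mlp_config(n_inputs = ch$n_lags, n_hidden = ch$n_hidden,
                    trainer = params$trainers[ch$trainer_id],
                    seed = chromosome_seed(params$seed, ch),
                    max_hidden = params$max_hidden)
  model <- tryCatch(
    mlp_train(mlp_init(cfg), sets$train, sets$val, params$train_opts),
    error = function(e) NULL)
  if (is.null(model)) return(NULL)
  preds <- mlp_forward(model, sets$val$inputs)
  report <- tryCatch(evaluate_forecast(sets$val$targets, preds),
                     error = function(e) NULL)
  if (is.null(report)) return(NULL)
  fit <- report$fitness
  list(model = model, report = report,
       fitness = if (is.na(fit)) -Inf else fit,
       val_mse = mean((sets$val$targets - preds)^2))
}

random_chromosome <- function(params) {
  list(n_lags = sample.int(params$max_lags, 1L),
       n_hidden = sample.int(params$max_hidden, 1L),
       trainer_id = sample.int(length(params$trainers), 1L))
}

mutate_chromosome <- function(ch, params) {
  if (runif(1) < params$mutation_prob)
    ch$n_lags <- sample.int(params$max_lags, 1L)
  if (runif(1) < params$mutation_prob)
    ch$n_hidden <- sample.int(params$max_hidden, 1L)
  if (runif(1) < params$mutation_prob)
    ch$trainer_id <- sample.int(length(params$trainers), 1L)
  ch
}

crossover_chromosomes <- function(a, b) {
  pick <- runif(3) < 0.5
  list(n_lags = if (pick[1]) a$n_lags else b$n_lags,
       n_hidden = if (pick[2]) a$n_hidden else b$n_hidden,
       trainer_id = if (pick[3]) a$trainer_id else b$trainer_id)
}

#' GA structure search for the hybrid forecaster
#'
#' Evolves a population of (lag count, hidden units, trainer) chromosomes.
#' Each evaluation decodes the chromosome to an MLP, trains it on the
#' training segment with validation-based early stopping, and scores the
#' composite fitness of its one-step forecasts on the validation segment.
#' The search keeps the best-ever individual across generations and outer
#' restarts; with elitism the best fitness never decreases.
#'
#' @param train,val `time_series` or numeric vectors: the chronological
#'   training and validation segments (validation windows are built causally
#'   from the concatenated history).
#' @param params a [ga_params()].
#' @return A `hybrid_model`: `chromosome`, trained `model` (`mlp_model`),
#'   `phase` (NULL until [phase_adjust()]), `validation_report`
#'   (`metrics_report`) and `search_log` (generation, best, mean fitness).
#' @export
ga_search <- function(train, val, params = ga_params()) {
  train_vals <- series_values(train); val_vals <- series_values(val)
  if (params$max_lags >= length(train_vals))
    stop("ga_search: training segment shorter than max_lags windows",
         call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  cache <- new.env(parent = emptyenv())
  cached_eval <- function(ch) {
    key <- paste(ch$n_lags, ch$n_hidden, ch$trainer_id, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- eval_chromosome(ch, train_vals, val_vals, params)
    cache[[key]] <- if (is.null(v)) list(fitness = -Inf) else v
    cache[[key]]
  }
  best <- NULL; best_ch <- NULL
  logs <- list()
  for (outer in seq_len(params$max_outer_iterations)) {
    set.seed(params$seed + (outer - 1L) * 1009L)
    pop <- replicate(params$pop_size, random_chromosome(params),
                     simplify = FALSE)
    evals <- lapply(pop, cached_eval)
    fits <- vapply(evals, function(e) e$fitness, numeric(1))
    stale <- 0L; ref_best <- max(fits)
    for (gen in seq_len(params$max_generations)) {
      ord <- order(fits, decreasing = TRUE)
      if (is.null(best) || fits[ord[1]] > best$fitness) {
        best <- evals[[ord[1]]]; best_ch <- pop[[ord[1]]]
      }
      logs[[length(logs) + 1L]] <-
        data.frame(outer = outer, generation = gen,
                   best_fitness = fits[ord[1]],
                   mean_fitness = mean(fits[is.finite(fits)]))
      if (is.finite(best$fitness) && !is.null(best$val_mse) &&
          sqrt(best$val_mse) <= params$acceptable_fitness_error) {
        stale <- -1L; break
      }
      if (fits[ord[1]] - ref_best < params$min_fitness_progress) {
        stale <- stale + 1L
        if (stale >= params$progress_patience) break
      } else {
        stale <- 0L; ref_best <- fits[ord[1]]
      }
      if (gen == params$max_generations) break
      newpop <- pop[ord[seq_len(min(params$elitism, params$pop_size))]]
      while (length(newpop) < params$pop_size) {
        tour <- function() {
          idx <- sample.int(length(pop), params$tournament_size, replace = TRUE)
          pop[[idx[which.max(fits[idx])]]]
        }
        child <- if (runif(1) < params$crossover_prob)
          crossover_chromosomes(tour(), tour()) else tour()
        newpop[[length(newpop) + 1L]] <- mutate_chromosome(child, params)
      }
      pop <- newpop
      evals <- lapply(pop, cached_eval)
      fits <- vapply(evals, function(e) e$fitness, numeric(1))
    }
    if (identical(stale, -1L)) break  # acceptable error reached
  }
  if (is.null(best) || !is.finite(best$fitness))
    stop("ga_search: every chromosome evaluation failed", call. = FALSE)
  structure(list(chromosome = best_ch, model = best$model, phase = NULL,
                 validation_report = best$report,
                 search_log = do.call(rbind, logs)),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  ch <- x$chromosome
  cat(sprintf("<hybrid_model> lags %d, hidden %d, trainer %s%s\n",
              ch$n_lags, ch$n_hidden, toupper(x$model$config$trainer),
              if (!is.null(x$phase) && x$phase$applied)
                sprintf(", phase adjust (a=%.3f, b=%.3f, shift=%d)",
                        x$phase$a, x$phase$b, x$phase$shift) else ""))
  if (!is.null(x$validation_report))
    cat(sprintf("  validation fitness %.3f\n", x$validation_report$fitness))
  invisible(x)
}

# Validation metrics of a model's causal one-step forecasts on val, with
# history taken from train.
validate_model <- function(model, train_vals, val_vals) {
  joint <- c(train_vals, val_vals)
  fs <- forecast_steps(model, joint)
  keep <- fs$target_index > length(train_vals)
  if (sum(keep) < 2L) return(NULL)
  evaluate_forecast(joint[fs$target_index[keep]], fs$outputs[keep])
}

#' Phase adjustment of a trained hybrid forecaster
#'
#' Fits an affine realignment y'(t) = a * y(t - shift) + b, with candidate
#' integer shifts 0 and 1 and (a, b) by least squares on the validation
#' segment, to counter the one-step phase lag neural forecasters often show.
#' The adjustment is kept only if it improves the validation fitness;
#' otherwise the model is returned unchanged with `phase$applied = FALSE`.
#'
#' @param model a `hybrid_model` from [ga_search()].
#' @param train,val the chronological segments used during the search.
#' @return The `hybrid_model`, with `phase` and `validation_report` updated
#'   when the adjustment is accepted.
#' @export
phase_adjust <- function(model, train, val) {
  stopifnot(inherits(model, "hybrid_model"))
  train_vals <- series_values(train); val_vals <- series_values(val)
  model$phase <- list(applied = FALSE, a = 1, b = 0, shift = 0L)
  if (length(val_vals) < 2L) {
    model$phase$skipped <- "validation segment too short"
    return(model)
  }
  joint <- c(train_vals, val_vals)
  raw <- forecast_steps(model$model, joint)
  keep <- raw$target_index > length(train_vals)
  if (sum(keep) < 3L) {
    model$phase$skipped <- "too few validation predictions"
    return(model)
  }
  base_report <- validate_model(model$model, train_vals, val_vals)
  if (is.null(base_report) || is.na(base_report$fitness)) {
    model$phase$skipped <- "baseline fitness undefined"
    return(model)
  }
  best_fit <- base_report$fitness
  best_phase <- NULL; best_report <- NULL
  out_at <- function(idx) {  # raw output for global target position idx
    pos <- match(idx, raw$target_index)
    raw$outputs[pos]
  }
  val_idx <- raw$target_index[keep]
  targets <- joint[val_idx]
  for (shift in 0:1) {
    src <- val_idx - shift
    ok <- src %in% raw$target_index
    if (sum(ok) < 3L) next
    x <- out_at(src[ok]); y <- targets[ok]
    if (stats::sd(x) == 0) next
    co <- stats::coef(stats::lm(y ~ x))
    adj <- co[2] * x + co[1]
    rpt <- tryCatch(evaluate_forecast(y, adj), error = function(e) NULL)
    if (is.null(rpt) || is.na(rpt$fitness)) next
    if (rpt$fitness > best_fit) {
      best_fit <- rpt$fitness
      best_phase <- list(applied = TRUE, a = unname(co[2]), b = unname(co[1]),
                         shift = as.integer(shift))
      best_report <- rpt
    }
  }
  if (!is.null(best_phase)) {
    model$phase <- best_phase
    model$validation_report <- best_report
  }
  model
}
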