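#' Default run configuration
#'
#' Assembles the configuration tree consumed by [run_experiment()] and the
#' command-line interface. Defaults follow the study protocol: min-max
#' normalization of the full series, 80/10/10 chronological split, a
#' GA-optimized base model, correction via ANN, ten repetitions selected by
#' validation fitness, and the 5 percent MAPE-increase stop rule. The
#' 50/20/30 and 50/30/20 splits used for sensitivity analysis are ordinary
#' values of `split`.
#'
#' @param split numeric length-3 vector of train/validation/test fractions.
#' @param normalization list: `enabled` and `fit_on` (`"full"` fits the
#'   min-max scale on the whole series; `"train"` on the training segment
#'   only, for leak-free operation).
#' @param base list: `method` (`"hs"` or `"mlp"`); for `"hs"` a `ga` sublist
#'   of [ga_params()] overrides and `adjust_phase`; for `"mlp"` the fixed
#'   `n_lags`, `n_hidden`, `trainer`.
#' @param correction list: `method` (`"ann"` or `"hs"`), `hidden_grid`,
#'   `max_acf_lags`, and a `ga` sublist for the `"hs"` method.
#' @param policy list of [stop_policy()] fields.
#' @param acf list: `bound`, `tolerance`.
#' @param train list of [train_options()] fields.
#' @param repetitions number of seeded repetitions (default 10).
#' @param selection `"policy"` or `"best_val_fitness"`.
#' @param seed master seed; fans out deterministically to the repetitions.
#' @return A validated `run_config` list.
#' @export
run_config <- function(split = c(0.8, 0.1, 0.1),
                       normalization = list(),
                       base = list(),
                       correction = list(),
                       policy = list(),
                       acf = list(),
                       train = list(),
                       repetitions = 10L,
                       selection = "best_val_fitness",
                       seed = 1L) {
  merge_defaults <- function(user, defaults, where) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop(sprintf("run_config: unknown key(s) in %s: %s", where,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    split = as.numeric(split),
    normalization = merge_defaults(normalization,
                                   list(enabled = TRUE, fit_on = "full"),
                                   "normalization"),
    base = merge_defaults(base,
                          list(method = "hs", ga = list(),
                               adjust_phase = TRUE,
                               n_lags = 3L, n_hidden = 4L, trainer = "lm"),
                          "base"),
    correction = merge_defaults(correction,
                                list(method = "ann", hidden_grid = 1:20,
                                     max_acf_lags = 10L, ga = list()),
                                "correction"),
    policy = merge_defaults(policy,
                            list(mape_increase_threshold = 0.05,
                                 patience = 1L, max_corrections = 5L),
                            "policy"),
    acf = merge_defaults(acf, list(bound = "two_over_sqrt_n", tolerance = 0),
                         "acf"),
    train = merge_defaults(train,
                           list(max_iterations = 1000L,
                                generalization_loss_pct = 5,
                                min_progress = 1e-6, progress_window = 5L,
                                eval_strip = 5L),
                           "train"),
    repetitions = as.integer(repetitions),
    selection = match.arg(selection, c("best_val_fitness", "policy")),
    seed = as.integer(seed))
  if (length(cfg$split) != 3L)
    stop("run_config: split must have three fractions", call. = FALSE)
  stopifnot(cfg$repetitions >= 1)
  if (!cfg$normalization$fit_on %in% c("full", "train"))
    stop("run_config: normalization$fit_on must be 'full' or 'train'",
         call. = FALSE)
  if (!cfg$base$method %in% c("hs", "mlp"))
    stop("run_config: base$method must be 'hs' or 'mlp'", call. = FALSE)
  if (!cfg$correction$method %in% c("ann", "hs"))
    stop("run_config: correction$method must be 'ann' or 'hs'", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level and nested keys mirror [run_config()];
#' unknown keys are rejected with an error naming them.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("split", "normalization", "base", "correction", "policy",
             "acf", "train", "repetitions", "selection", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("read_run_config: unknown top-level key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(run_config, y)
}

config_factories <- function(cfg) {
  topts <- do.call(train_options, cfg$train)
  base_factory <- if (cfg$base$method == "hs") {
    gp <- do.call(ga_params, utils::modifyList(list(train_opts = topts),
                                               cfg$base$ga))
    hs_factory(gp, adjust_phase = isTRUE(cfg$base$adjust_phase))
  } else {
    mlp_factory(cfg$base$n_lags, cfg$base$n_hidden, cfg$base$trainer, topts)
  }
  correction_factory <- if (cfg$correction$method == "ann") {
    ann_correction_factory(hidden_grid = cfg$correction$hidden_grid,
                           max_acf_lags = cfg$correction$max_acf_lags,
                           opts = topts, acf_bound = cfg$acf$bound)
  } else {
    gp <- do.call(ga_params, utils::modifyList(list(train_opts = topts),
                                               cfg$correction$ga))
    hs_factory(gp, adjust_phase = FALSE)
  }
  list(base = base_factory, correction = correction_factory)
}

#' Run the full forecasting experiment protocol
#'
#' Normalizes the series, runs `repetitions` seeded repetitions of the
#' correction-chain fit, selects the repetition with the best validation
#' fitness at its selected depth, and assembles the report: per-depth test
#' metrics (uncorrected row plus one row per correction), stage-over-stage
#' and best-versus-base metric ratios, and the per-stage ACF traces.
#'
#' @param series `time_series` or numeric vector on the original scale.
#' @param config a [run_config()].
#' @return An `experiment_report`: `best_chain`, `metrics_table`,
#'   `ratio_table`, `acf_traces`, `repetition_summary`, `norm_params`,
#'   `config`, `failures`.
#' @export
run_experiment <- function(series, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  ts <- as_time_series(series)
  spec <- split_spec(config$split[1], config$split[2], config$split[3])
  np <- NULL
  work <- ts
  if (isTRUE(config$normalization$enabled)) {
    if (config$normalization$fit_on == "train") {
      tr <- chronological_split(ts, spec)$train
      np <- normalize_minmax(tr)$params
      work <- normalize_minmax(ts, np)$series
    } else {
      nm <- normalize_minmax(ts)
      np <- nm$params
      work <- nm$series
    }
  }
  fac <- config_factories(config)
  rep_seeds <- with_seed(config$seed,
                         sample.int(2147483646L, config$repetitions))
  chains <- vector("list", config$repetitions)
  failures <- character(0)
  summ <- data.frame(repetition = seq_len(config$repetitions),
                     seed = rep_seeds, selected_depth = NA_integer_,
                     val_fitness = NA_real_, stop_reason = NA_character_)
  for (r in seq_len(config$repetitions)) {
    ch <- tryCatch(
      fit_correction_chain(work, fac$base, fac$correction, split = spec,
                           policy = do.call(stop_policy, config$policy),
                           seed = rep_seeds[r],
                           acf_bound = config$acf$bound,
                           acf_tolerance = config$acf$tolerance,
                           selection = config$selection),
      error = function(e) e)
    if (inherits(ch, "error")) {
      failures <- c(failures, sprintf("repetition %d: %s", r,
                                      conditionMessage(ch)))
      next
    }
    chains[[r]] <- ch
    rec <- ch$iteration_records[[ch$selected_depth + 1L]]$validation
    summ$selected_depth[r] <- ch$selected_depth
    summ$val_fitness[r] <- if (!is.null(rec)) rec$fitness else NA_real_
    summ$stop_reason[r] <- ch$stop_reason
  }
  ok <- which(!is.na(summ$val_fitness))
  if (!length(ok))
    stop("run_experiment: every repetition failed", call. = FALSE)
  best_r <- ok[which.max(summ$val_fitness[ok])]
  best <- chains[[best_r]]

  n_stages <- length(best$models)
  base_label <- if (config$base$method == "hs") "HS" else "MLP"
  row_label <- function(d) {
    if (d == 0L) base_label
    else if (d == 1L) paste0(base_label, "+C_1")
    else paste0(base_label, "+C_1+...+C_", d)
  }
  metrics_table <- lapply(seq_len(n_stages) - 1L, function(d)
    best$iteration_records[[d + 1L]]$test)
  names(metrics_table) <- vapply(seq_len(n_stages) - 1L, row_label, "")

  ratio_table <- list()
  for (d in seq_len(n_stages - 1L)) {
    a <- metrics_table[[d + 1L]]; b <- metrics_table[[d]]
    if (!is.null(a) && !is.null(b))
      ratio_table[[sprintf("C_%d-C_%d", d, d - 1L)]] <- metric_ratio(a, b)
  }
  sel <- best$selected_depth
  if (sel >= 1L && !is.null(metrics_table[[sel + 1L]]) &&
      !is.null(metrics_table[[1L]]))
    ratio_table[[sprintf("C_%d-C_0", sel)]] <-
      metric_ratio(metrics_table[[sel + 1L]], metrics_table[[1L]])

  acf_traces <- lapply(best$iteration_records, function(r) r$acf)
  names(acf_traces) <- paste0("stage_", seq_along(acf_traces) - 1L)

  structure(list(best_chain = best, best_repetition = best_r,
                 metrics_table = metrics_table, ratio_table = ratio_table,
                 acf_traces = acf_traces, repetition_summary = summ,
                 norm_params = np, config = config, failures = failures),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d repetition(s), best #%d (val fitness %.3f)\n",
              nrow(x$repetition_summary), x$best_repetition,
              max(x$repetition_summary$val_fitness, na.rm = TRUE)))
  for (nm in names(x$metrics_table)) {
    r <- x$metrics_table[[nm]]
    if (is.null(r)) next
    cat(sprintf("  %-16s MSE %.3E POCID %6.2f U %.4f MAPE %6.2f ARV %.4f IA %.3f Fitness %.2f\n",
                nm, r$mse, r$pocid, r$theil_u, r$mape, r$arv, r$ia, r$fitness))
  }
  if (length(x$failures)) cat("  failures:", length(x$failures), "\n")
  invisible(x)
}
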