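#' Read a univariate series from CSV
#'
#' Expects a header with a `value` column and optionally a leading `date`
#' column of ISO-8601 dates. Parsing is locale-independent (decimal point).
#' Malformed cells are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return A `time_series`.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path))
    stop("read_series_csv: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!"value" %in% names(df))
    stop("read_series_csv: missing 'value' column in ", path, call. = FALSE)
  if (nrow(df) == 0L)
    stop("read_series_csv: no data rows in ", path, call. = FALSE)
  raw <- df$value
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(vals) | !nzchar(raw))
  if (length(bad))
    stop(sprintf("read_series_csv: non-numeric or blank value at line(s) %s",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  stamps <- if ("date" %in% names(df)) df$date else NULL
  time_series(vals, name = sub("\\.csv$", "", basename(path)),
              timestamps = stamps)
}

#' Write a series to CSV
#'
#' Mirrors [read_series_csv()]: a `value` column, preceded by a `date`
#' column when timestamps are present. Values at full double precision.
#'
#' @param series a `time_series`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_series_csv <- function(series, path) {
  ts <- as_time_series(series)
  df <- if (is.null(ts$timestamps))
    data.frame(value = format(ts$values, digits = 17, trim = TRUE,
                              scientific = FALSE))
  else
    data.frame(date = as.character(ts$timestamps),
               value = format(ts$values, digits = 17, trim = TRUE,
                              scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

metrics_row <- function(r) {
  c(MSE = sprintf("%.2E", r$mse), POCID = sprintf("%.2f", r$pocid),
    U = sprintf("%.4f", r$theil_u), MAPE = sprintf("%.2f", r$mape),
    ARV = sprintf("%.4f", r$arv), IA = sprintf("%.3f", r$ia),
    Fitness = sprintf("%.2f", r$fitness))
}

ratio_row <- function(r) {
  f <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  c(MSE = f(r$mse), POCID = f(r$pocid), U = f(r$theil_u), MAPE = f(r$mape),
    ARV = f(r$arv), IA = f(r$ia), Fitness = f(r$fitness))
}

# Cheap polynomial string hash for config provenance (hex).
config_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

report_to_list <- function(report) {
  metric_fields <- function(r) {
    if (is.null(r)) return(NULL)
    list(mse = r$mse, pocid = r$pocid, theil_u = r$theil_u, mape = r$mape,
         arv = r$arv, ia = r$ia, fitness = r$fitness, n = r$n)
  }
  ratio_fields <- function(r) {
    if (is.null(r)) return(NULL)
    list(mse = r$mse, pocid = r$pocid, theil_u = r$theil_u, mape = r$mape,
         arv = r$arv, ia = r$ia, fitness = r$fitness)
  }
  acf_fields <- function(a) {
    if (is.null(a)) return(NULL)
    list(rho = a$rho, bound = a$bound, n = a$n,
         n_exceeding = a$n_exceeding, is_white_noise = a$is_white_noise)
  }
  list(metrics = lapply(report$metrics_table, metric_fields),
       ratios = lapply(report$ratio_table, ratio_fields),
       acf = lapply(report$acf_traces, acf_fields),
       selected_depth = report$best_chain$selected_depth,
       stop_reason = report$best_chain$stop_reason,
       best_repetition = report$best_repetition,
       repetition_summary = report$repetition_summary,
       seed = report$config$seed)
}

#' Write experiment reports to a directory
#'
#' Renders the metrics table (columns Model, MSE, POCID, U, MAPE, ARV, IA,
#' Fitness; MSE in scientific notation, the rest fixed-point at table
#' precision), the ratio table, one ACF trace CSV per stage, a
#' machine-readable JSON twin at full double precision, the chain archive,
#' and a run log carrying the master seed, repetition seeds and a hash of
#' the resolved configuration.
#'
#' @param report an `experiment_report` from [run_experiment()].
#' @param out_dir output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
render_reports <- function(report, out_dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  w <- function(p) { written <<- c(written, p); p }

  keep <- !vapply(report$metrics_table, is.null, logical(1))
  mt <- do.call(rbind, lapply(report$metrics_table[keep], metrics_row))
  mdf <- data.frame(Model = names(report$metrics_table)[keep], mt,
                    check.names = FALSE)
  utils::write.csv(mdf, w(file.path(out_dir, "metrics.csv")),
                   row.names = FALSE, quote = FALSE)

  if (length(report$ratio_table)) {
    rt <- do.call(rbind, lapply(report$ratio_table, ratio_row))
    rdf <- data.frame(Models = names(report$ratio_table), rt,
                      check.names = FALSE)
  } else {
    rdf <- data.frame(Models = character(0))
  }
  utils::write.csv(rdf, w(file.path(out_dir, "ratios.csv")),
                   row.names = FALSE, quote = FALSE)

  for (nm in names(report$acf_traces)) {
    a <- report$acf_traces[[nm]]
    if (is.null(a)) next
    adf <- data.frame(lag = seq_along(a$rho), rho = a$rho, bound = a$bound)
    utils::write.csv(adf, w(file.path(out_dir, paste0("acf_", nm, ".csv"))),
                     row.names = FALSE, quote = FALSE)
  }

  twin <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                           digits = NA, null = "null", dataframe = "rows")
  writeLines(twin, w(file.path(out_dir, "report.json")))
  writeLines(chain_to_json(report$best_chain),
             w(file.path(out_dir, "chain.json")))

  cfg_json <- as.character(jsonlite::toJSON(unclass(report$config),
                                            auto_unbox = TRUE, digits = NA))
  log_lines <- c(
    sprintf("master_seed: %d", report$config$seed),
    sprintf("config_hash: %s", config_hash(cfg_json)),
    sprintf("repetition_seeds: %s",
            paste(report$repetition_summary$seed, collapse = " ")),
    sprintf("best_repetition: %d", report$best_repetition),
    sprintf("selected_depth: %d", report$best_chain$selected_depth),
    sprintf("stop_reason: %s", report$best_chain$stop_reason),
    vapply(seq_along(report$best_chain$iteration_records), function(i) {
      r <- report$best_chain$iteration_records[[i]]
      sprintf("stage %d: val_mape=%s acf_exceeding=%s white=%s", i - 1L,
              if (!is.null(r$validation)) sprintf("%.4f", r$validation$mape)
              else "NA",
              if (!is.null(r$acf)) r$acf$n_exceeding else "NA",
              if (!is.null(r$acf)) r$acf$is_white_noise else "NA")
    }, ""),
    if (length(report$failures)) paste("failure:", report$failures) else
      character(0))
  writeLines(log_lines, w(file.path(out_dir, "run_log.txt")))
  writeLines(cfg_json, w(file.path(out_dir, "config.json")))
  invisible(written)
}
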