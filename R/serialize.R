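# JSON-friendly (de)serialization of models and correction chains, used for
# the chain archive written next to every report and for persistence tests.

model_to_list <- function(model) UseMethod("model_to_list")

#' @export
model_to_list.mlp_model <- function(model) {
  list(type = "mlp",
       config = list(lags = model$config$lags,
                     n_hidden = model$config$n_hidden,
                     trainer = model$config$trainer,
                     output_activation = model$config$output_activation,
                     seed = model$config$seed),
       theta = model$theta,
       stop_reason = model$stop_reason)
}

#' @export
model_to_list.hybrid_model <- function(model) {
  list(type = "hybrid",
       chromosome = model$chromosome,
       phase = model$phase,
       mlp = model_to_list(model$model))
}

model_from_list <- function(x) {
  if (identical(x$type, "mlp")) {
    lags <- sort(as.integer(unlist(x$config$lags)), decreasing = TRUE)
    cfg <- mlp_config(n_inputs = 1L,  # placeholder; lag set restored below
                      n_hidden = x$config$n_hidden,
                      trainer = x$config$trainer,
                      output_activation = x$config$output_activation,
                      seed = x$config$seed)
    # set the stored lag set directly: a length-1 set like {3} must not be
    # re-read as a lag count
    cfg$lags <- lags
    cfg$n_inputs <- length(lags)
    m <- mlp_init(cfg)
    m$theta <- as.numeric(x$theta)
    m$stop_reason <- x$stop_reason
    return(m)
  }
  if (identical(x$type, "hybrid")) {
    ph <- x$phase
    if (!is.null(ph)) {
      ph$applied <- isTRUE(as.logical(ph$applied))
      if (!is.null(ph$shift)) ph$shift <- as.integer(ph$shift)
    }
    return(structure(list(chromosome = x$chromosome,
                          model = model_from_list(x$mlp),
                          phase = ph,
                          validation_report = NULL, search_log = NULL),
                     class = "hybrid_model"))
  }
  stop("model_from_list: unknown model type", call. = FALSE)
}

#' Serialize a correction chain to a JSON string
#'
#' The archive carries every stage model (configuration and weights), the
#' selected depth and stop reason, so forecasts can be reproduced without
#' refitting.
#'
#' @param chain a `correction_chain`.
#' @return A JSON string.
#' @export
chain_to_json <- function(chain) {
  stopifnot(inherits(chain, "correction_chain"))
  payload <- list(models = lapply(chain$models, model_to_list),
                  stage_start = chain$stage_start,
                  selected_depth = chain$selected_depth,
                  stop_reason = chain$stop_reason)
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Restore a correction chain from its JSON archive
#' @param json JSON string produced by [chain_to_json()].
#' @return A `correction_chain` (models, alignment and selection only; the
#'   fitting-time diagnostics are not part of the archive).
#' @export
chain_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  structure(list(models = lapply(x$models, model_from_list),
                 stage_start = as.integer(unlist(x$stage_start)),
                 selected_depth = as.integer(x$selected_depth),
                 stop_reason = x$stop_reason,
                 residual_series = NULL, iteration_records = NULL),
            class = "correction_chain")
}
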