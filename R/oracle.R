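# Step-size verification oracle: a fine-step Euler run is the reference
# against which coarser step sizes are compared.

#' Compare a run against its 5-second reference
#'
#' Runs the same deterministic configuration at the configured step size and
#' at the 5 s reference step, and returns the maximum relative deviation
#' between the two trajectories over all recorded minutes and all sixteen
#' series. Relative deviation at a point is `|x - ref| / max(|ref|, 1)` (the
#' floor of one particle/unit per mL keeps near-extinct pools from dominating
#' the measure). Refuses stochastic configurations, for which two runs differ
#' by sampling noise rather than discretisation error.
#'
#' @param config a deterministic [cocktail_config()].
#' @param horizon hours to simulate (defaults to the configured duration).
#' @return the maximum relative trajectory deviation (0 when the configured
#'   step size is already 5 s).
#' @export
oracle_compare <- function(config, horizon = config$duration) {
  validate_config(config)
  if (config$mutation_mode == "Stochastic")
    stop("oracle_compare is defined for deterministic configurations only",
         call. = FALSE)
  cfg_run <- config; cfg_run$duration <- horizon
  cfg_ref <- cfg_run; cfg_ref$step_size <- 5
  run <- run_cocktail(cfg_run)$series
  ref <- run_cocktail(cfg_ref)$series
  stopifnot(nrow(run) == nrow(ref))
  nm <- cocktail_series_names()
  dev <- 0
  for (v in nm) {
    d <- abs(run[[v]] - ref[[v]]) / pmax(abs(ref[[v]]), 1)
    dev <- max(dev, max(d))
  }
  dev
}
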