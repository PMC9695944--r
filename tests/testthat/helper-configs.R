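# Shared configuration builders and a cache for the heavier scenario runs so
# several test files can reuse one simulation.

# closed vessel (no flow), optionally without phage: the workhorse for
# conservation and exponential-limit checks
cfg_closed <- function(S0 = 1e5, gamma = 0, C0 = 100, C_in = C0, omega = 0,
                       phages = FALSE, step_size = 60, duration = 5, ...) {
  cocktail_config(
    bacteria = bacterial_params(S0 = S0, gamma = gamma,
                                f_RA = 0, f_RB = 0, f_RAB = 0),
    chemostat = chemostat_params(C0 = C0, C_in = C_in, omega = omega),
    phage_A = phage_params(latent = 30,
                           additions = if (phages) cbind(0, 1e8) else NULL),
    phage_B = phage_params(latent = 20,
                           additions = if (phages) cbind(0, 1e8) else NULL),
    step_size = step_size, duration = duration, ...)
}

total_bacteria <- function(series) {
  rowSums(series[, c("S", "I_A", "I_B", "I_AB", "R_A", "R_B", "R_AB",
                     "R_AIB", "R_BIA", "S_r", "R_rA", "R_rB", "R_rAB")])
}

.sim_cache <- new.env(parent = emptyenv())

cached_scenario_sim <- function(name) {
  if (is.null(.sim_cache[[name]])) {
    .sim_cache[[name]] <- run_cocktail(builtin_scenario(name))
  }
  .sim_cache[[name]]
}
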