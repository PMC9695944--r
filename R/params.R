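# Run-configuration containers and validation.
#
# Defaults follow the standard chemostat parameterisation for a fast-growing
# bacterium infected by two T-even-like virulent phages: per-hour rates for
# growth (psi), decay (gamma, phi) and flow (omega); per-minute rates for
# adsorption (delta) and refuge exchange (sigma, rho); latent periods in
# minutes. The double-resistance mutation rate is never set directly: it is
# always the product mu_A * mu_B.

#' Bacterial parameters
#'
#' @param S0 starting bacterial titre (CFU/mL). 0 disables bacteria entirely;
#'   otherwise 0.1--1e12.
#' @param psi,psi_RA,psi_RB,psi_RAB maximum specific growth rates (/h) of
#'   susceptible, singly resistant and doubly resistant bacteria; 0--1.5.
#' @param K Monod half-saturation constant (ug/mL), 0.01--100: the nutrient
#'   concentration at which growth runs at half its maximum rate.
#' @param epsilon conversion efficiency (ug of nutrient consumed per cell
#'   division), 1e-8--1e-4.
#' @param gamma bacterial decay rate (/h), 0--1. Newborn cells of the current
#'   step are excluded from decay.
#' @param mu_A,mu_B mutation rates to resistance against phage A resp. B
#'   (per cell division), 0--1e-2. Double resistance arises at mu_A * mu_B.
#' @param sigma,rho rates of cells into and out of the refuge (/min), 0--0.01.
#'   Both must be positive for a refuge mode to be activated.
#' @param f_RA,f_RB,f_RAB initial frequencies of resistant cells in the
#'   starting population (0--1e-2 for single, 0--1e-6 for double resistance).
#' @return a list of class `bacterial_params`.
#' @export
bacterial_params <- function(S0 = 1e5, psi = 0.7, psi_RA = 0.7, psi_RB = 0.7,
                             psi_RAB = 0.7, K = 5, epsilon = 2e-6, gamma = 0,
                             mu_A = 1e-7, mu_B = 1e-7, sigma = 0, rho = 0,
                             f_RA = 1e-7, f_RB = 1e-7, f_RAB = 1e-14) {
  structure(list(S0 = S0, psi = psi, psi_RA = psi_RA, psi_RB = psi_RB,
                 psi_RAB = psi_RAB, K = K, epsilon = epsilon, gamma = gamma,
                 mu_A = mu_A, mu_B = mu_B, sigma = sigma, rho = rho,
                 f_RA = f_RA, f_RB = f_RB, f_RAB = f_RAB),
            class = "bacterial_params")
}

#' Phage parameters (one phage)
#'
#' @param delta adsorption rate constant (mL/min), 1e-14--1e-7.
#' @param latent latent period (min), 1--60: time from infection to lysis.
#' @param burst burst size (PFU released per lysed cell), 0--1000. A burst
#'   size of 0 models a nonproductive infection: cells lyse, nothing is
#'   released.
#' @param phi phage decay rate (/h), 0--1.
#' @param additions a numeric matrix (or data.frame) with columns `time_h`
#'   and `titre` giving up to three scheduled impulse additions of free phage
#'   to the vessel. An empty matrix (0 rows) disables the phage.
#' @return a list of class `phage_params`.
#' @export
phage_params <- function(delta = 1e-10, latent = 30, burst = 100, phi = 0,
                         additions = cbind(time_h = 0, titre = 1e8)) {
  additions <- if (is.null(additions)) matrix(numeric(0), ncol = 2)
               else as.matrix(additions)
  if (length(additions) == 0L) {
    additions <- matrix(numeric(0), ncol = 2,
                        dimnames = list(NULL, c("time_h", "titre")))
  }
  colnames(additions) <- c("time_h", "titre")
  structure(list(delta = delta, latent = latent, burst = burst, phi = phi,
                 additions = additions),
            class = "phage_params")
}

#' Chemostat parameters
#'
#' @param C0 nutrient concentration at start (ug/mL), 0--1000.
#' @param C_in nutrient concentration in the inflowing reservoir (ug/mL),
#'   0--1000; may differ from `C0`.
#' @param omega flow rate (vessel turnovers/h), 0--100. The outflow washes
#'   out nutrient, planktonic bacteria and free phage alike.
#' @return a list of class `chemostat_params`.
#' @export
chemostat_params <- function(C0 = 100, C_in = 100, omega = 0.2) {
  structure(list(C0 = C0, C_in = C_in, omega = omega),
            class = "chemostat_params")
}

#' Assemble a complete run configuration
#'
#' Bundles all model parameters and mode switches for [run_cocktail()].
#'
#' @param bacteria a [bacterial_params()] object.
#' @param phage_A,phage_B [phage_params()] objects for the two phages. To run
#'   a single-phage infection give the other phage no additions (or a titre
#'   of 0).
#' @param chemostat a [chemostat_params()] object.
#' @param primary_adsorption `"Standard"` (mass action, one phage adsorbs per
#'   encounter) or `"Poisson"` (multiple adsorption with Poisson-distributed
#'   multiplicity of infection).
#' @param secondary_adsorption `"Uninfected"` (phage adsorb to uninfected,
#'   non-resistant cells only) or `"Susceptible"` (phage additionally adsorb
#'   to already-infected cells, which consumes phage without further
#'   productive infection).
#' @param mutation_mode `"Deterministic"` (expected mutant counts) or
#'   `"Stochastic"` (Poisson sampling, normal approximation above mean 10).
#' @param refuge_mode `"Off"`, `"Planktonic"` (metabolically inactive cells
#'   that may still adsorb phage, decay and wash out) or `"LIFO"` (sessile
#'   biofilm-like cells, returned last-in-first-out, exempt from adsorption,
#'   decay and washout). Requires both `sigma > 0` and `rho > 0`.
#' @param round_below_one if `TRUE`, any bacterial or phage pool strictly
#'   below one particle per mL is zeroed after each step.
#' @param log10_output if `TRUE`, file/chart output is log10-transformed with
#'   titre 0 mapped to -16 (see [log10_titre()]).
#' @param step_size Euler step in seconds: one of 60, 30, 15, 5.
#' @param duration simulated time (h).
#' @param seed integer seed for the stochastic mutation sampler.
#' @param output_selection integer indices (1--16) of the series written by
#'   [write_timeseries()] and drawn by [render_chart()], in the order
#'   S, I_A, I_B, I_AB, R_A, R_B, R_AB, R_AIB, R_BIA, S_r, R_rA, R_rB,
#'   R_rAB, A, B, C.
#' @return a list of class `cocktail_config` (validated).
#' @seealso [run_cocktail()], [read_config()], [builtin_scenario()]
#' @examples
#' cfg <- cocktail_config(duration = 1)
#' cfg
#' @export
cocktail_config <- function(bacteria = bacterial_params(),
                            phage_A = phage_params(latent = 30),
                            phage_B = phage_params(latent = 20),
                            chemostat = chemostat_params(),
                            primary_adsorption = "Standard",
                            secondary_adsorption = "Uninfected",
                            mutation_mode = "Deterministic",
                            refuge_mode = "Off",
                            round_below_one = FALSE,
                            log10_output = FALSE,
                            step_size = 60,
                            duration = 24,
                            seed = 1L,
                            output_selection = 1:16) {
  cfg <- structure(list(bacteria = bacteria, phage_A = phage_A,
                        phage_B = phage_B, chemostat = chemostat,
                        primary_adsorption = primary_adsorption,
                        secondary_adsorption = secondary_adsorption,
                        mutation_mode = mutation_mode,
                        refuge_mode = refuge_mode,
                        round_below_one = isTRUE(round_below_one),
                        log10_output = isTRUE(log10_output),
                        step_size = step_size,
                        duration = duration,
                        seed = as.integer(seed),
                        output_selection = as.integer(output_selection)),
                   class = "cocktail_config")
  validate_config(cfg)
}

#' @export
print.cocktail_config <- function(x, ...) {
  b <- x$bacteria; ch <- x$chemostat
  cat("<cocktail_config>\n")
  cat(sprintf("  bacteria : S0 = %.3g CFU/mL, psi = %.3g /h, K = %.3g ug/mL\n",
              b$S0, b$psi, b$K))
  cat(sprintf("  chemostat: C0 = %.3g, C_in = %.3g ug/mL, omega = %.3g /h\n",
              ch$C0, ch$C_in, ch$omega))
  for (p in c("phage_A", "phage_B")) {
    ph <- x[[p]]
    tot <- if (nrow(ph$additions)) sum(ph$additions[, "titre"]) else 0
    cat(sprintf("  %s  : delta = %.3g mL/min, l = %g min, beta = %g, additions = %.3g PFU/mL\n",
                sub("_", " ", p), ph$delta, ph$latent, ph$burst, tot))
  }
  cat(sprintf("  modes    : %s / %s, mutation %s, refuge %s\n",
              x$primary_adsorption, x$secondary_adsorption,
              x$mutation_mode, x$refuge_mode))
  cat(sprintf("  run      : %g h at %g s steps, seed %d\n",
              x$duration, x$step_size, x$seed))
  invisible(x)
}

# range checker collecting messages
.chk_range <- function(errs, val, lo, hi, name, unit = "") {
  if (length(val) != 1L || !is.finite(val) || val < lo || val > hi) {
    errs <- c(errs, sprintf("%s = %s outside allowed range [%g, %g]%s",
                            name, format(val), lo, hi,
                            if (nzchar(unit)) paste0(" ", unit) else ""))
  }
  errs
}

#' Validate a run configuration against the allowed parameter ranges
#'
#' Checks every parameter against its allowed range and the mode switches
#' against their legal values; errors list all offending fields at once.
#'
#' @param config a `cocktail_config`.
#' @return the configuration, invisibly, if valid.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "cocktail_config")) stop("not a cocktail_config", call. = FALSE)
  b <- config$bacteria; ch <- config$chemostat
  e <- character(0)
  if (!(length(b$S0) == 1L && is.finite(b$S0) &&
        (b$S0 == 0 || (b$S0 >= 0.1 && b$S0 <= 1e12)))) {
    e <- c(e, sprintf("S0 = %s outside allowed range 0 or [0.1, 1e12] CFU/mL",
                      format(b$S0)))
  }
  for (nm in c("psi", "psi_RA", "psi_RB", "psi_RAB"))
    e <- .chk_range(e, b[[nm]], 0, 1.5, nm, "/h")
  e <- .chk_range(e, b$K, 0.01, 100, "K", "ug/mL")
  e <- .chk_range(e, b$epsilon, 1e-8, 1e-4, "epsilon", "ug/cell")
  e <- .chk_range(e, b$gamma, 0, 1, "gamma", "/h")
  e <- .chk_range(e, b$mu_A, 0, 1e-2, "mu_A", "/cell division")
  e <- .chk_range(e, b$mu_B, 0, 1e-2, "mu_B", "/cell division")
  e <- .chk_range(e, b$sigma, 0, 0.01, "sigma", "/min")
  e <- .chk_range(e, b$rho, 0, 0.01, "rho", "/min")
  e <- .chk_range(e, b$f_RA, 0, 1e-2, "f_RA")
  e <- .chk_range(e, b$f_RB, 0, 1e-2, "f_RB")
  e <- .chk_range(e, b$f_RAB, 0, 1e-6, "f_RAB")
  e <- .chk_range(e, ch$C0, 0, 1000, "C0", "ug/mL")
  e <- .chk_range(e, ch$C_in, 0, 1000, "C_in", "ug/mL")
  e <- .chk_range(e, ch$omega, 0, 100, "omega", "/h")
  for (pn in c("phage_A", "phage_B")) {
    p <- config[[pn]]
    e <- .chk_range(e, p$delta, 1e-14, 1e-7, paste0(pn, "$delta"), "mL/min")
    e <- .chk_range(e, p$latent, 1, 60, paste0(pn, "$latent"), "min")
    e <- .chk_range(e, p$burst, 0, 1000, paste0(pn, "$burst"), "PFU/cell")
    e <- .chk_range(e, p$phi, 0, 1, paste0(pn, "$phi"), "/h")
    ad <- p$additions
    if (nrow(ad) > 3L) e <- c(e, sprintf("%s: at most 3 phage additions", pn))
    if (nrow(ad) > 0L) {
      if (any(!is.finite(ad)) || any(ad[, "time_h"] < 0) ||
          any(ad[, "titre"] < 0) || any(ad[, "titre"] > 1e13)) {
        e <- c(e, sprintf("%s: addition times must be >= 0 h and titres within [0, 1e13] PFU/mL", pn))
      }
    }
  }
  if (!config$primary_adsorption %in% c("Standard", "Poisson"))
    e <- c(e, "primary_adsorption must be 'Standard' or 'Poisson'")
  if (!config$secondary_adsorption %in% c("Uninfected", "Susceptible"))
    e <- c(e, "secondary_adsorption must be 'Uninfected' or 'Susceptible'")
  if (!config$mutation_mode %in% c("Deterministic", "Stochastic"))
    e <- c(e, "mutation_mode must be 'Deterministic' or 'Stochastic'")
  if (!config$refuge_mode %in% c("Off", "Planktonic", "LIFO"))
    e <- c(e, "refuge_mode must be 'Off', 'Planktonic' or 'LIFO'")
  if (config$refuge_mode != "Off" && !(b$sigma > 0 && b$rho > 0))
    e <- c(e, "refuge_mode != 'Off' requires both sigma > 0 and rho > 0")
  if (!(length(config$step_size) == 1L && config$step_size %in% c(60, 30, 15, 5)))
    e <- c(e, "step_size must be one of 60, 30, 15, 5 seconds")
  if (!(length(config$duration) == 1L && is.finite(config$duration) &&
        config$duration >= 0))
    e <- c(e, "duration must be a nonnegative number of hours")
  if (!(length(config$seed) == 1L && !is.na(config$seed)))
    e <- c(e, "seed must be a single integer")
  sel <- config$output_selection
  if (length(sel) < 1L || anyNA(sel) || any(sel < 1L) || any(sel > 16L) ||
      anyDuplicated(sel))
    e <- c(e, "output_selection must be distinct indices within 1..16")
  if (length(e)) {
    stop(paste0("invalid configuration:\n  - ", paste(e, collapse = "\n  - ")),
         call. = FALSE)
  }
  invisible(config)
}
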