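# Individual kinetic terms. These are the building blocks the Euler stepper
# assembles each step; they are exported so each term can be inspected and
# tested in isolation.

#' Monod growth rate
#'
#' Nutrient-limited specific growth rate `psi_max * C / (K + C)`: half the
#' maximum rate at `C == K`, saturating towards `psi_max` at high nutrient.
#'
#' @param psi_max maximum specific growth rate (/h), >= 0.
#' @param C nutrient concentration (ug/mL), >= 0 (vectorised).
#' @param K Monod half-saturation constant (ug/mL), > 0.
#' @return growth rate (/h).
#' @examples
#' monod_rate(0.7, 5, 5)   # half-maximal: 0.35
#' @export
monod_rate <- function(psi_max, C, K) {
  if (length(K) != 1L || !is.finite(K) || K <= 0)
    stop("K must be a single positive number", call. = FALSE)
  if (any(psi_max < 0) || any(C < 0))
    stop("psi_max and C must be nonnegative", call. = FALSE)
  psi_max * C / (K + C)
}

#' Rate of change of the nutrient concentration
#'
#' `dC/dt = (C_in - C) * omega - sum_i epsilon * psi_i * C/(K+C) * N_i`,
#' where the sum runs over the dividing (uninfected susceptible and
#' resistant) bacterial classes only: infected cells neither consume
#' nutrients nor divide, and refuge cells are dormant.
#'
#' @param C current nutrient concentration (ug/mL).
#' @param chem a [chemostat_params()] object (supplies `C_in` and `omega`).
#' @param N_dividing titres of the dividing classes (CFU/mL); may be a vector
#'   of classes.
#' @param psi_eff maximum growth rates of those classes (/h), recycled
#'   against `N_dividing`.
#' @param K Monod constant (ug/mL).
#' @param epsilon conversion efficiency (ug/cell).
#' @return dC/dt in ug/mL per hour.
#' @examples
#' resource_derivative(5, chemostat_params(C_in = 100, omega = 0.2),
#'                     N_dividing = 1e5, psi_eff = 0.7, K = 5,
#'                     epsilon = 2e-6)  # 19 - 0.07
#' @export
resource_derivative <- function(C, chem, N_dividing, psi_eff, K, epsilon) {
  if (any(N_dividing < 0) || C < 0) stop("titres must be nonnegative", call. = FALSE)
  (chem$C_in - C) * chem$omega -
    sum(epsilon * monod_rate(psi_eff, C, K) * N_dividing)
}

#' Compartments a phage adsorbs to
#'
#' Returns the set of bacterial compartments a phage can adsorb to under a
#' given combination of mode switches. With secondary adsorption
#' `"Uninfected"` a phage attaches only to cells it could productively
#' infect (for phage A: `S`, `I_B`, `R_B`); with `"Susceptible"` it also
#' attaches to already-infected non-resistant cells (`I_A`, `I_AB`,
#' `R_BIA`), consuming phage without additional productive infection.
#' Planktonic refuge cells (`S_r` and the refuge cells resistant to the
#' other phage) adsorb -- but are never infected -- under the Poisson
#' primary model, or under Standard combined with `"Susceptible"`. LIFO
#' (biofilm) refuge cells never adsorb, and doubly resistant cells
#' (`R_AB`, `R_rAB`) never appear.
#'
#' @param phage `"A"` or `"B"`.
#' @param secondary `"Uninfected"` or `"Susceptible"`.
#' @param primary `"Standard"` or `"Poisson"`.
#' @param refuge_mode `"Off"`, `"Planktonic"` or `"LIFO"`.
#' @return character vector of compartment names.
#' @examples
#' adsorption_targets("A", "Uninfected", "Standard", "Off")
#' @export
adsorption_targets <- function(phage = c("A", "B"),
                               secondary = c("Uninfected", "Susceptible"),
                               primary = c("Standard", "Poisson"),
                               refuge_mode = c("Off", "Planktonic", "LIFO")) {
  phage <- match.arg(phage)
  secondary <- match.arg(secondary)
  primary <- match.arg(primary)
  refuge_mode <- match.arg(refuge_mode)
  other <- if (phage == "A") "B" else "A"
  targets <- c("S", paste0("I_", other), paste0("R_", other))
  if (secondary == "Susceptible") {
    # own singly infected, doubly infected, and resistant-to-other infected
    targets <- c(targets, paste0("I_", phage), "I_AB",
                 paste0("R_", other, "I", phage))
  }
  if (refuge_mode == "Planktonic" &&
      (primary == "Poisson" || secondary == "Susceptible")) {
    targets <- c(targets, "S_r", paste0("R_r", other))
  }
  targets
}

#' Mass-action ("Standard") adsorption flux over one step
#'
#' The number of phage adsorbed to (and, for infectable targets, of cells
#' newly infected in) one target compartment during one Euler step:
#' `delta * P_free * N_target * dt`, capped so that neither the target
#' compartment nor the free-phage pool can be driven negative.
#'
#' @param P_free free phage titre (PFU/mL).
#' @param N_target titre of the target compartment (CFU/mL).
#' @param delta adsorption rate constant (mL/min).
#' @param dt step length in minutes.
#' @return adsorbed amount (PFU/mL, equal to newly infected CFU/mL for
#'   infectable targets).
#' @examples
#' standard_adsorption_flux(1e8, 1e5, 1e-10, 1)  # 1e3
#' @export
standard_adsorption_flux <- function(P_free, N_target, delta, dt) {
  if (any(c(P_free, N_target, delta, dt) < 0))
    stop("inputs must be nonnegative", call. = FALSE)
  min(delta * P_free * N_target * dt, N_target, P_free)
}

#' Phage bound under the Poisson multiple-adsorption model
#'
#' `P_bound = (1 - exp(-delta * M * dt)) * P_free`, where `M` is the summed
#' titre of every compartment the phage adsorbs to. Agrees with the
#' mass-action flux to first order when `delta * M * dt` is small.
#'
#' @param P_free free phage titre (PFU/mL).
#' @param M total adsorbing-cell titre (CFU/mL).
#' @param delta adsorption rate constant (mL/min).
#' @param dt step length in minutes.
#' @return bound phage (PFU/mL), never exceeding `P_free`.
#' @export
poisson_bound <- function(P_free, M, delta, dt) {
  if (any(c(P_free, M, delta, dt) < 0))
    stop("inputs must be nonnegative", call. = FALSE)
  -expm1(-delta * M * dt) * P_free
}

#' Cells newly infected under the Poisson model
#'
#' With `P_bound` phage distributed over `M` cells, the multiplicity of
#' infection actually realised is Poisson with mean `P_bound / M`; the
#' newly infected cells are the complement of the zero class:
#' `(1 - exp(-P_bound / M)) * M`. Within the simulator this total is
#' apportioned across the target compartments in proportion to their share
#' of `M`.
#'
#' @param P_bound bound phage from [poisson_bound()] (PFU/mL).
#' @param M the same total adsorbing-cell titre (CFU/mL).
#' @return newly infected cells (CFU/mL); 0 when `M == 0`.
#' @export
poisson_infected <- function(P_bound, M) {
  if (any(c(P_bound, M) < 0)) stop("inputs must be nonnegative", call. = FALSE)
  if (M == 0) return(0)
  -expm1(-P_bound / M) * M
}

#' Bacterial decay over one step
#'
#' `N * gamma * dt`, applied to the population present at the start of the
#' step only -- cells born within the step are excluded from decay. Iterated
#' over steps this reproduces exponential decay `N0 * exp(-gamma * t)` up to
#' Euler discretisation error.
#'
#' @param N_preexisting titre at the start of the step (CFU/mL).
#' @param gamma decay rate (/h).
#' @param dt step length in hours.
#' @return titre lost to decay this step (CFU/mL).
#' @export
decay_flux <- function(N_preexisting, gamma, dt) {
  if (any(c(N_preexisting, gamma, dt) < 0))
    stop("inputs must be nonnegative", call. = FALSE)
  N_preexisting * gamma * dt
}

#' Resolve superinfection by lysis-time competition
#'
#' A cell infected by one phage at `t_first` and superinfected by the other
#' at `t_second` lyses at whichever scheduled lysis time comes first, and
#' produces progeny of that phage only. The superinfecting phage wins only
#' if its lysis time is strictly earlier; on a tie the resident (first)
#' phage produces.
#'
#' @param t_first,l_first infection time and latent period of the resident
#'   phage (min).
#' @param t_second,l_second infection time and latent period of the
#'   superinfecting phage (min); `t_second >= t_first`.
#' @return a list with `lysis_time` (min) and `producing_phage`
#'   (`"first"` or `"second"`).
#' @examples
#' resolve_superinfection(0, 20, 5, 30)  # resident lyses first at 20
#' @export
resolve_superinfection <- function(t_first, l_first, t_second, l_second) {
  v <- c(t_first, l_first, t_second, l_second)
  if (any(!is.finite(v)) || any(v < 0))
    stop("times and latent periods must be nonnegative", call. = FALSE)
  if (t_second < t_first)
    stop("superinfection cannot precede the first infection", call. = FALSE)
  first_lysis <- t_first + l_first
  second_lysis <- t_second + l_second
  if (second_lysis < first_lysis) {
    list(lysis_time = second_lysis, producing_phage = "second")
  } else {
    list(lysis_time = first_lysis, producing_phage = "first")
  }
}
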