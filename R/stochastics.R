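# Random sampling for resistance mutation. Mutation is the only stochastic
# element of the model; everything else is deterministic given the
# configuration.

#' Mutation rate to double resistance
#'
#' Resistance to both phages requires both mutations, so the rate is the
#' product of the two single rates. This rate is never set directly.
#'
#' @param mu_A,mu_B single-resistance mutation rates (/cell division),
#'   each within 0--1e-2.
#' @return the double-resistance rate `mu_A * mu_B`.
#' @examples
#' double_resistance_rate(1e-7, 1e-7)  # 1e-14
#' @export
double_resistance_rate <- function(mu_A, mu_B) {
  .chk_mu(mu_A); .chk_mu(mu_B)
  mu_A * mu_B
}

.chk_mu <- function(mu) {
  if (length(mu) != 1L || !is.finite(mu) || mu < 0 || mu > 1e-2)
    stop("mutation rate must be within [0, 1e-2] per cell division",
         call. = FALSE)
  invisible(mu)
}

#' Number of resistant mutants among newly divided cells
#'
#' Mutation to resistance happens only at cell division, so the expected
#' mutant count is `n_births * mu = lambda`. In `"Deterministic"` mode
#' exactly `lambda` is returned (a real number; fractions of a cell are kept
#' unless rounding below one is enabled at the simulation level). In
#' `"Stochastic"` mode the count is drawn from Poisson(lambda) when
#' `lambda <= 10` and from Normal(lambda, sqrt(lambda)) truncated at zero
#' when `lambda > 10`; the draw never exceeds `n_births`. Stochastic draws
#' consume R's global random number stream ([run_cocktail()] seeds it with
#' the Mersenne-Twister generator and Box-Muller normals).
#'
#' @param n_births cells newly produced by division this step (CFU/mL).
#' @param mu mutation rate per cell division, 0--1e-2.
#' @param mode `"Deterministic"` or `"Stochastic"`.
#' @return mutant count (CFU/mL), >= 0.
#' @examples
#' mutant_count(1e5, 1e-7, "Deterministic")  # 0.01
#' @export
mutant_count <- function(n_births, mu, mode = c("Deterministic", "Stochastic")) {
  mode <- match.arg(mode)
  .chk_mu(mu)
  if (length(n_births) != 1L || !is.finite(n_births) || n_births < 0)
    stop("n_births must be a single nonnegative number", call. = FALSE)
  lambda <- n_births * mu
  if (mode == "Deterministic" || lambda == 0) return(lambda)
  draw <- if (lambda <= 10) {
    stats::rpois(1L, lambda)
  } else {
    max(0, stats::rnorm(1L, mean = lambda, sd = sqrt(lambda)))
  }
  min(draw, n_births)
}
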