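# Property-style invariants of the coupled system.

test_that("phage bookkeeping: dA = released - adsorbed when phi = omega = 0", {
  cfg <- cocktail_config(
    bacteria = bacterial_params(S0 = 1e6, f_RA = 1e-3, f_RB = 1e-3,
                                f_RAB = 1e-7),
    chemostat = chemostat_params(omega = 0),
    phage_A = phage_params(phi = 0, additions = cbind(0, 1e8)),
    phage_B = phage_params(latent = 20, phi = 0, additions = cbind(0, 1e8)),
    secondary_adsorption = "Uninfected",
    step_size = 60, duration = 3)
  for (mode in c("Standard", "Poisson")) {
    cfg$primary_adsorption <- mode
    s <- run_cocktail(cfg, diagnostics = TRUE)$series
    scale <- max(s$A, s$B)
    expect_lt(max(abs(diff(s$A) - (s$rel_A[-1] - s$P_A[-1]))), 1e-9 * scale)
    expect_lt(max(abs(diff(s$B) - (s$rel_B[-1] - s$P_B[-1]))), 1e-9 * scale)
    # bound phage never exceeds the free pool of the step
    expect_true(all(s$P_A[-1] <= s$A[-nrow(s)] + 1e-9 * scale))
  }
})

test_that("standard and Poisson runs agree at low MOI", {
  # MOI_input = 0.01 and delta*M*dt << 1: per-step fluxes within 0.1%
  mk <- function(mode) cocktail_config(
    bacteria = bacterial_params(S0 = 1e5, f_RA = 0, f_RB = 0, f_RAB = 0),
    phage_A = phage_params(additions = cbind(0, 1e3)),
    phage_B = phage_params(latent = 20, additions = cbind(0, 1e3)),
    primary_adsorption = mode, step_size = 60, duration = 1)
  a <- run_cocktail(mk("Standard"))$series
  b <- run_cocktail(mk("Poisson"))$series
  expect_lt(max(abs(a$I_A - b$I_A) / pmax(a$I_A, 1e-9)), 1e-3)
  expect_lt(max(abs(a$A - b$A) / a$A), 1e-3)
})

test_that("exponential limits hold and improve with smaller steps", {
  # pure growth at saturating nutrient: N ~ N0 * exp(psi t)
  grow_err <- function(step) {
    cfg <- cocktail_config(
      bacteria = bacterial_params(S0 = 1e5, mu_A = 0, mu_B = 0,
                                  f_RA = 0, f_RB = 0, f_RAB = 0),
      chemostat = chemostat_params(C0 = 1000, C_in = 1000, omega = 0),
      phage_A = phage_params(additions = NULL),
      phage_B = phage_params(latent = 20, additions = NULL),
      step_size = step, duration = 4)
    s <- run_cocktail(cfg)$series
    mon <- 1000 / (5 + 1000)      # saturation is not exact: K = 5
    ref <- 1e5 * exp(0.7 * mon * s$time_h)
    max(abs(s$S - ref) / ref)
  }
  e60 <- grow_err(60); e30 <- grow_err(30); e15 <- grow_err(15)
  expect_lt(e60, 0.7^2 * (1 / 60) * 4 / 2 * 1.1)   # Euler error bound
  expect_lt(e30, e60)
  expect_lt(e15, e30)
  expect_gt(e60 / e15, 3)        # halving the step roughly halves the error
  # pure decay likewise
  decay_err <- function(step) {
    cfg <- cocktail_config(
      bacteria = bacterial_params(gamma = 0.2, f_RA = 0, f_RB = 0, f_RAB = 0),
      chemostat = chemostat_params(C0 = 0, C_in = 0, omega = 0),
      phage_A = phage_params(additions = NULL),
      phage_B = phage_params(latent = 20, additions = NULL),
      step_size = step, duration = 10)
    s <- run_cocktail(cfg)$series
    ref <- 1e5 * exp(-0.2 * s$time_h)
    max(abs(s$S - ref) / ref)
  }
  d60 <- decay_err(60); d30 <- decay_err(30)
  expect_lt(d30, d60)
})

test_that("step-size convergence towards the 5 s reference is monotone", {
  cfg <- builtin_scenario("fig2B")
  dev60 <- oracle_compare(cfg, horizon = 24)
  cfg$step_size <- 15
  dev15 <- oracle_compare(cfg, horizon = 24)
  expect_gt(dev60, 0)
  expect_gt(dev15, 0)
  expect_gt(dev60, dev15)
  # identical step sizes deviate by exactly zero
  cfg$step_size <- 5
  expect_equal(oracle_compare(cfg, horizon = 2), 0)
  # the oracle refuses stochastic runs
  cfg$mutation_mode <- "Stochastic"
  cfg$bacteria$mu_A <- 1e-7; cfg$bacteria$mu_B <- 1e-7
  expect_error(oracle_compare(cfg, horizon = 1), "deterministic")
})

test_that("full resistance is absolute: no phage term ever removes R_AB", {
  for (mode in c("Standard", "Poisson")) {
    cfg <- cocktail_config(
      bacteria = bacterial_params(S0 = 1e6, f_RA = 1e-3, f_RB = 1e-3,
                                  f_RAB = 1e-6, gamma = 0),
      chemostat = chemostat_params(omega = 0),
      primary_adsorption = mode,
      secondary_adsorption = "Susceptible",
      step_size = 30, duration = 6)
    s <- run_cocktail(cfg)$series
    expect_true(all(diff(s$R_AB) >= 0))
  }
})

test_that("seeded stochastic runs are reproducible and seeds matter", {
  cfg <- cocktail_config(
    bacteria = bacterial_params(S0 = 1e9, mu_A = 1e-5, mu_B = 1e-5,
                                f_RA = 0, f_RB = 0, f_RAB = 0),
    mutation_mode = "Stochastic", seed = 11,
    step_size = 60, duration = 2)
  r1 <- run_cocktail(cfg)$series
  r2 <- run_cocktail(cfg)$series
  expect_identical(r1, r2)
  cfg$seed <- 12L
  expect_false(identical(r1, run_cocktail(cfg)$series))
  # deterministic runs do not touch the global RNG stream
  set.seed(123); before <- .Random.seed
  run_cocktail(cfg_closed(duration = 1))
  expect_identical(before, .Random.seed)
})

test_that("refuge exchange conserves cells and LIFO shields from washout", {
  # closed vessel, no decay: refuge exchange only moves cells around
  cfg <- cocktail_config(
    bacteria = bacterial_params(S0 = 1e6, sigma = 0.01, rho = 0.005,
                                mu_A = 0, mu_B = 0,
                                f_RA = 0, f_RB = 0, f_RAB = 0),
    chemostat = chemostat_params(C0 = 0, C_in = 0, omega = 0),
    phage_A = phage_params(additions = NULL),
    phage_B = phage_params(latent = 20, additions = NULL),
    refuge_mode = "Planktonic", step_size = 60, duration = 5)
  s <- run_cocktail(cfg, check = TRUE)$series
  tot <- total_bacteria(s)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-9 * 300)
  expect_gt(s$S_r[nrow(s)], 0)
  # under washout, LIFO refuge cells are exempt while planktonic ones leave
  wash <- function(mode) {
    cfg2 <- cocktail_config(
      bacteria = bacterial_params(S0 = 1e6, sigma = 0.01, rho = 1e-4,
                                  mu_A = 0, mu_B = 0,
                                  f_RA = 0, f_RB = 0, f_RAB = 0),
      chemostat = chemostat_params(C0 = 0, C_in = 0, omega = 2),
      phage_A = phage_params(additions = NULL),
      phage_B = phage_params(latent = 20, additions = NULL),
      refuge_mode = mode, step_size = 60, duration = 5)
    run_cocktail(cfg2)$series
  }
  sl <- wash("LIFO"); sp <- wash("Planktonic")
  expect_gt(sl$S_r[nrow(sl)], sp$S_r[nrow(sp)])
})

test_that("the small-population refuge rule feeds 0.1 cells per minute", {
  # S well below 10: influx is the flat 0.1 cells/min, not sigma*S
  cfg <- cocktail_config(
    bacteria = bacterial_params(S0 = 5, sigma = 0.01, rho = 0.001,
                                psi = 0, psi_RA = 0, psi_RB = 0, psi_RAB = 0,
                                mu_A = 0, mu_B = 0,
                                f_RA = 0, f_RB = 0, f_RAB = 0),
    chemostat = chemostat_params(C0 = 0, C_in = 0, omega = 0),
    phage_A = phage_params(additions = NULL),
    phage_B = phage_params(latent = 20, additions = NULL),
    refuge_mode = "Planktonic", step_size = 60, duration = 1 / 60)
  s <- run_cocktail(cfg)$series
  expect_equal(s$S_r[2], 0.1)
  expect_equal(s$S[2], 4.9)
})
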