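# The Euler stepping engine and run-level behaviour.

test_that("a zero-duration run returns the initial state only", {
  cfg <- cfg_closed(duration = 0)
  s <- run_cocktail(cfg)$series
  expect_equal(nrow(s), 1L)
  expect_equal(s$S, 1e5)
  expect_equal(s$C, 100)
  expect_equal(s$time_h, 0)
})

test_that("one default step moves delta*S*A*dt cells into I_A", {
  # Table-of-defaults situation, phage A only, one 1-minute step
  cfg <- cocktail_config(
    bacteria = bacterial_params(f_RA = 0, f_RB = 0, f_RAB = 0),
    phage_B = phage_params(latent = 20, additions = NULL),
    step_size = 60, duration = 1 / 60)
  s <- run_cocktail(cfg, diagnostics = TRUE)$series
  expect_equal(s$I_A[2], 1e-10 * 1e5 * 1e8 * 1)   # 1e3 newly infected
  expect_equal(s$P_A[2], 1e3)                     # same amount of phage bound
  # washout of free phage: omega/60 of the pool, plus the adsorbed phage
  expect_equal(s$A[2], 1e8 - 1e3 - 1e8 * 0.2 / 60)
})

test_that("an empty vessel only relaxes the nutrient towards the reservoir", {
  cfg <- cocktail_config(
    bacteria = bacterial_params(S0 = 0, f_RA = 0, f_RB = 0, f_RAB = 0),
    chemostat = chemostat_params(C0 = 0, C_in = 100, omega = 0.2),
    phage_A = phage_params(additions = NULL),
    phage_B = phage_params(latent = 20, additions = NULL),
    step_size = 60, duration = 1 / 60)
  s <- run_cocktail(cfg)$series
  expect_equal(s$C[2], 100 * 0.2 / 60)
  expect_true(all(as.matrix(s[2, 2:16]) == 0))
})

test_that("closed runs conserve nutrient plus biomass", {
  cfg <- cfg_closed(duration = 10, phages = FALSE)
  s <- run_cocktail(cfg)$series
  tot <- s$C + 2e-6 * total_bacteria(s)
  n_steps <- 10 * 60
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-9 * n_steps)
  # also with phage present: infected cells neither consume nor divide, and
  # lysis removes cells without returning nutrient, so conservation holds
  # until the first lysis event (latent period 20 min)
  cfg2 <- cfg_closed(duration = 19 / 60, phages = TRUE)
  s2 <- run_cocktail(cfg2)$series
  tot2 <- s2$C + 2e-6 * total_bacteria(s2)
  expect_lt(max(abs(tot2 - tot2[1])) / tot2[1], 1e-9 * 19)
})

test_that("pure decay reproduces the closed-form half-life", {
  cfg <- cocktail_config(
    bacteria = bacterial_params(gamma = 0.02, f_RA = 0, f_RB = 0, f_RAB = 0),
    chemostat = chemostat_params(C0 = 0, C_in = 0, omega = 0),
    phage_A = phage_params(additions = NULL),
    phage_B = phage_params(latent = 20, additions = NULL),
    step_size = 5, duration = 40)
  s <- run_cocktail(cfg)$series
  i <- which(s$S < 5e4)[1]
  t_half <- s$time_h[i - 1] + (5e4 - s$S[i - 1]) / (s$S[i] - s$S[i - 1]) *
    (s$time_h[i] - s$time_h[i - 1])
  expect_lt(abs(t_half - log(2) / 0.02) / (log(2) / 0.02), 0.005)
})

test_that("newborns are excluded from decay within a step", {
  # one step with growth and decay: N1 = N + g*N*dt - gamma*N*dt, the decay
  # acting on the start-of-step population only
  cfg <- cocktail_config(
    bacteria = bacterial_params(gamma = 0.5, f_RA = 0, f_RB = 0, f_RAB = 0,
                                mu_A = 0, mu_B = 0),
    chemostat = chemostat_params(C0 = 100, C_in = 100, omega = 0),
    phage_A = phage_params(additions = NULL),
    phage_B = phage_params(latent = 20, additions = NULL),
    step_size = 60, duration = 1 / 60)
  s <- run_cocktail(cfg)$series
  dt <- 1 / 60
  g <- 0.7 * 100 / 105
  expect_equal(s$S[2], 1e5 + g * 1e5 * dt - 0.5 * 1e5 * dt)
})

test_that("scheduled additions are exact impulses", {
  cfg <- cocktail_config(
    bacteria = bacterial_params(S0 = 0, f_RA = 0, f_RB = 0, f_RAB = 0),
    chemostat = chemostat_params(C0 = 0, C_in = 0, omega = 0),
    phage_A = phage_params(phi = 0, additions = cbind(time_h = c(0, 1, 2),
                                                      titre = c(1e8, 5e7, 2.5e7))),
    phage_B = phage_params(latent = 20, additions = NULL),
    step_size = 60, duration = 3)
  s <- run_cocktail(cfg)$series
  # no bacteria, no decay, no washout: free phage is conserved between and
  # accumulates exactly the scheduled titres
  expect_equal(s$A[s$time_h == 0.5], 1e8)
  expect_equal(s$A[s$time_h == 1.5], 1.5e8)
  expect_equal(s$A[nrow(s)], 1.75e8)
  expect_true(all(s$B == 0))
})

test_that("rounding below one eliminates fractional pools", {
  expect_equal(apply_rounding(c(S = 0.01, A = 1, B = 2.5)),
               c(S = 0, A = 1, B = 2.5))
  expect_equal(apply_rounding(c(x = 0.999999)), c(x = 0))
  expect_error(apply_rounding(c(-0.5)), "nonnegative")
  # in a run: deterministic mutants arrive at ~0.01 cells/step and are
  # eliminated each step, so no resistant class can ever seed
  mk <- function(round) cocktail_config(
    bacteria = bacterial_params(f_RA = 0, f_RB = 0, f_RAB = 0),
    phage_A = phage_params(additions = NULL),
    phage_B = phage_params(latent = 20, additions = NULL),
    chemostat = chemostat_params(omega = 0),
    round_below_one = round, step_size = 60, duration = 2)
  with_rounding <- run_cocktail(mk(TRUE))$series
  without <- run_cocktail(mk(FALSE))$series
  expect_true(all(with_rounding$R_A == 0))
  expect_true(all(without$R_A[-1] > 0))
})

test_that("a 48 h run records one row per minute plus the start", {
  cfg <- builtin_scenario("fig2D")
  cfg$step_size <- 60                      # cheap step for the row count
  s <- run_cocktail(cfg)$series
  expect_equal(nrow(s), 48 * 60 + 1)
  expect_equal(diff(s$time_h), rep(1 / 60, 48 * 60), tolerance = 1e-12)
})

test_that("validation reports all offending fields at once", {
  cfg <- cocktail_config(duration = 1)
  cfg$bacteria$K <- -5
  cfg$bacteria$gamma <- 7
  cfg$step_size <- 45
  err <- tryCatch(validate_config(cfg), error = conditionMessage)
  expect_match(err, "K = -5")
  expect_match(err, "gamma = 7")
  expect_match(err, "step_size")
  cfg2 <- cocktail_config(duration = 1)
  cfg2$refuge_mode <- "LIFO"      # without sigma/rho
  expect_error(validate_config(cfg2), "sigma > 0 and rho > 0")
})

test_that("log10 output convention maps 0 to -16", {
  expect_equal(log10_titre(0), -16)
  expect_equal(log10_titre(1), 0)
  expect_equal(log10_titre(1e8), 8)
  expect_equal(log10_titre(c(0, 10)), c(-16, 1))
  expect_error(log10_titre(-1), "nonnegative")
})

test_that("result object methods print, summarise and plot", {
  sim <- run_cocktail(cfg_closed(duration = 1))
  expect_output(print(sim), "final titres")
  expect_s3_class(summary(sim), "summary.cocktail_sim")
  expect_output(print(summary(sim)), "series")
  expect_equal(nrow(as.data.frame(sim)), 61)
  pdf(NULL)
  on.exit(dev.off())
  y <- plot(sim, selection = c(1, 16))
  expect_equal(colnames(y), c("S", "C"))
})
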