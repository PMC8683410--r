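test_that("thermogram integration matches the exact pulse heat", {
  tg <- gen_thermogram(seq(0, 600, 0.5), baseline = 0,
                       pulses = data.frame(t_start = 60, duration = 120,
                                           amplitude = -5),
                       n_mol = 2e-7, injection_times = 30)
  expect_equal(integrate_thermogram(tg)$total_J, -600e-6 * 4.184,
               tolerance = 1e-9)
  # identical result on a shifted constant baseline
  tg2 <- gen_thermogram(seq(0, 600, 0.5), baseline = 2,
                        pulses = data.frame(t_start = 60, duration = 120,
                                            amplitude = -5),
                        n_mol = 2e-7, injection_times = 30)
  expect_equal(integrate_thermogram(tg2)$total_J, -600e-6 * 4.184,
               tolerance = 1e-9)
  # flat zero trace integrates to zero
  tg0 <- gen_thermogram(seq(0, 100, 1), baseline = 0, n_mol = 1e-7,
                        injection_times = 10)
  expect_equal(integrate_thermogram(tg0)$total_J, 0)
})

test_that("linear baseline model removes a drifting background", {
  times <- seq(0, 600, 0.5)
  tg <- gen_thermogram(times, baseline = 0,
                       pulses = data.frame(t_start = 200, duration = 100,
                                           amplitude = -4),
                       n_mol = 1e-7, injection_times = 150)
  tg$heat_flow_ucal_s <- tg$heat_flow_ucal_s + 0.01 * times + 1
  tg$baseline_model <- "linear"
  expect_equal(integrate_thermogram(tg)$total_J, -400e-6 * 4.184,
               tolerance = 1e-6)
})

test_that("molar enthalpy normalization", {
  expect_equal(enthalpy_from_heats(-59.548e-3, 2e-7), -297.74)
  expect_equal(enthalpy_from_heats(0, 1e-6), 0)
  expect_equal(enthalpy_from_heats(-4.184e-3, 1e-6), -4.184)
  expect_error(enthalpy_from_heats(-1e-3, 0), "> 0")
})

test_that("equilibrium constant and free energy are consistent", {
  expect_rel(equilibrium_constant(7.5e-7), 1.3333e6, 1e-4)
  expect_equal(equilibrium_constant(1), 1)
  # -RT ln K_F == RT ln [C] for a range of critical concentrations
  for (cc in 10^seq(-9, -0.25, length.out = 12)) {
    lhs <- -8.314 * 293.15 * log(equilibrium_constant(cc)) / 1000
    expect_rel(free_energy(cc, 293.15), lhs, 1e-9)
  }
  expect_equal(free_energy(1, 293.15), 0)
  expect_equal(free_energy(7.5e-7, 293.15), -34.37, tolerance = 1e-3)
  expect_equal(free_energy(1e-6, 310.15), -35.62, tolerance = 1e-3)
  expect_error(free_energy(-1, 293.15), "positive")
})

test_that("Gibbs-Helmholtz entropy", {
  expect_equal(entropy_gibbs_helmholtz(-297.74, -34.36, 293.15), -0.898,
               tolerance = 1e-3)
  expect_equal(entropy_gibbs_helmholtz(-50, -50, 300), 0)
  expect_equal(entropy_gibbs_helmholtz(-100, -50, 250), -0.2)
  expect_error(entropy_gibbs_helmholtz(-100, -50, -1), "> 0")
})

test_that("two-phase heat-capacity fit is exact on noise-free input", {
  for (bp in c(305.15, 310.15, 315.15)) {
    tab <- dh_table_twophase(113.84, -373.51, bp = bp)
    fit <- heat_capacity_fit(tab, breakpoint = bp)
    expect_equal(fit$dCp_low, 113.84, tolerance = 1e-9)
    expect_equal(fit$dCp_high, -373.51, tolerance = 1e-9)
  }
  # constant enthalpy gives zero slopes
  flat <- gen_dH_table(seq(300, 320, 2.5), breakpoint = 310,
                       slope_low = 0, slope_high = 0, intercept = -5)
  fit0 <- heat_capacity_fit(flat, breakpoint = 310)
  expect_equal(fit0$dCp_low, 0, tolerance = 1e-12)
  expect_equal(fit0$dCp_high, 0, tolerance = 1e-12)
})

test_that("single-branch and degenerate heat-capacity inputs", {
  tab <- data.frame(T_K = c(300, 310), dH_kJ_mol = c(-100, -90))
  expect_warning(fit <- heat_capacity_fit(tab, breakpoint = 350),
                 "single-phase")
  expect_equal(fit$dCp_low, 1.0, tolerance = 1e-12)
  expect_true(is.na(fit$dCp_high))
  expect_error(heat_capacity_fit(
    data.frame(T_K = c(300, 300), dH_kJ_mol = c(-1, -2))), "identical")
})

test_that("automatic breakpoint detection finds the true phase split", {
  tab <- dh_table_twophase(113.84, -373.51, bp = 310.15)
  fit <- heat_capacity_fit(tab, breakpoint = "auto")
  expect_equal(fit$breakpoint, 310.15)
  expect_equal(fit$dCp_low, 113.84, tolerance = 1e-9)
})

test_that("stochastic elongation equilibrates at k_diss/k_ass", {
  sim <- simulate_1d_crystallization(1e6, 0.75, n_fibrils = 50,
                                     c0 = 2e-6, volume_L = 2e-15,
                                     t_end = 600, seed = 11)
  expect_lt(abs(sim$conc_eq_M - 7.5e-7), 3 * sim$se_M)
  # and within a few percent in absolute terms
  expect_rel(sim$conc_eq_M, 7.5e-7, 0.05)
})

test_that("irreversible elongation depletes free units monotonically", {
  sim <- simulate_1d_crystallization(1e7, 0, n_fibrils = 20, c0 = 5e-7,
                                     volume_L = 1e-15, t_end = 200,
                                     seed = 3)
  traj <- sim$trajectory$free_units
  expect_true(all(diff(traj[!is.na(traj)]) <= 0))
  expect_lt(sim$conc_eq_M, 5e-8)
})

test_that("starting at the balance point gives no net fibril growth", {
  sim <- simulate_1d_crystallization(1e6, 0.75, n_fibrils = 50,
                                     c0 = 7.5e-7, volume_L = 2e-15,
                                     t_end = 300, init_length = 200,
                                     seed = 5)
  total_growth <- sum(sim$fibril_lengths) - 50 * 200
  # net growth stays within fluctuation scale (sqrt of event count)
  expect_lt(abs(total_growth), 3 * sqrt(0.75 * 50 * 300))
})

test_that("equilibrium concentration error shrinks with volume", {
  err <- vapply(c(5e-16, 4e-15), function(v) {
    sim <- simulate_1d_crystallization(1e6, 0.75, n_fibrils = 50,
                                       c0 = 2e-6, volume_L = v,
                                       t_end = 600, seed = 2)
    abs(sim$conc_eq_M - 7.5e-7) / 7.5e-7
  }, numeric(1))
  expect_lt(err[2], 0.05)
  expect_lt(err[2], err[1] + 0.02)
})

test_that("thermo_params enforces its cross-identities", {
  tp <- thermo_params(7.5e-7, dH_kJ_mol = -297.74,
                      temperature_K = 293.15)
  expect_rel(tp$dG_app, 8.314 * 293.15 * log(7.5e-7) / 1000, 1e-12)
  expect_equal(tp$dG_app, tp$dH - tp$temperature_K * tp$dS,
               tolerance = 1e-9)
  expect_rel(tp$K_F, 1 / 7.5e-7, 1e-12)
  # corrupting a field trips the validator
  tp$dS <- tp$dS + 0.1
  expect_error(validate_thermo_params(tp), "identity violated")
})
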