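test_that("Stokes-Einstein sizing matches closed-form hand evaluation", {
  cfg <- dls_instrument(temperature_K = 293.15, viscosity_Pa_s = 1.002e-3)
  # k_B * 293.15 / (6 pi * 1.002e-3 * 9.40e-11) = 2.28 nm
  expect_equal(stokes_einstein(9.40e-11, cfg), 2.28, tolerance = 1e-3)
  expect_error(stokes_einstein(-1e-11, cfg), "positive")
})

test_that("forward/inverse Stokes-Einstein compose to identity", {
  cfg <- dls_instrument(temperature_K = 310.15)
  for (r in c(0.5, 2.28, 4.1, 17.2, 150)) {
    expect_rel(stokes_einstein(inverse_stokes_einstein(r, cfg), cfg),
               r, 1e-12)
  }
  # D proportional to 1/R: doubling the radius halves D
  expect_rel(inverse_stokes_einstein(4.1, cfg) /
               inverse_stokes_einstein(8.2, cfg), 2, 1e-12)
})

test_that("single-species correlogram inverts to within 1%", {
  tr <- gen_correlogram(data.frame(radius_nm = 4.1, fraction = 1),
                        instrument = inst37)
  fit <- fit_correlogram(tr, 1)
  expect_equal(nrow(fit$species), 1L)
  expect_rel(fit$species$radius_nm, 4.1, 0.01)
})

test_that("two-species correlogram recovers both radii and fractions", {
  sp <- data.frame(radius_nm = c(4.1, 17.2), fraction = c(0.5, 0.5))
  fit <- fit_correlogram(gen_correlogram(sp, instrument = inst37), 2)
  expect_equal(nrow(fit$species), 2L)
  expect_rel(fit$species$radius_nm[1], 4.1, 0.05)
  expect_rel(fit$species$radius_nm[2], 17.2, 0.05)
  expect_true(all(abs(fit$species$fraction - 0.5) < 0.1))
  expect_equal(sum(fit$species$fraction), 1, tolerance = 1e-9)
})

test_that("recovery holds under mild noise across seeds", {
  sp <- data.frame(radius_nm = c(4.1, 17.2), fraction = c(0.6, 0.4))
  for (seed in 1:5) {
    tr <- gen_correlogram(sp, instrument = inst37, noise_sd = 0.002,
                          seed = seed)
    fit <- fit_correlogram(tr, 2)
    expect_rel(fit$species$radius_nm[1], 4.1, 0.10)
    expect_rel(fit$species$radius_nm[2], 17.2, 0.10)
  }
})

test_that("non-decaying traces are rejected", {
  flat <- correlogram_trace(10^seq(-6, 0, length.out = 20),
                            rep(0.9, 20), inst37)
  expect_error(fit_correlogram(flat, 1), "does not decay")
})

test_that("mass calibration recovers an exact power law", {
  # log-log line through (1 nm, 1 kDa) and (10 nm, 1000 kDa): a = 1, b = 3
  cal <- calibrate_mass(data.frame(radius_nm = c(1, 10),
                                   mass_kDa = c(1, 1000)))
  expect_rel(cal$a, 1, 1e-9)
  expect_rel(cal$b, 3, 1e-9)
  # 6-digit recovery on noiseless many-point power-law data
  r <- seq(2, 30, length.out = 12)
  cal2 <- calibrate_mass(data.frame(radius_nm = r,
                                    mass_kDa = 1.7 * r^2.6))
  expect_rel(cal2$a, 1.7, 1e-6)
  expect_rel(cal2$b, 2.6, 1e-6)
  expect_error(calibrate_mass(data.frame(radius_nm = 4, mass_kDa = 80)),
               "at least 2")
  expect_error(calibrate_mass(data.frame(radius_nm = c(4, 4),
                                         mass_kDa = c(80, 90))),
               "distinct")
})

test_that("shipped calibration reproduces the observed oligomer masses", {
  cal <- calibrate_mass(dls_mass_pairs())
  expect_rel(mass_from_radius(17.2, cal), 2300, 0.10)
  expect_rel(mass_from_radius(4.1, cal), 81.5, 0.15)
  # extrapolated monomer mass; loose tolerance
  expect_rel(mass_from_radius(2.28, cal), 19.4, 0.25)
  # power law is monotone for b > 0
  r <- seq(1, 30, length.out = 40)
  expect_true(all(diff(mass_from_radius(r, cal)) > 0))
})

test_that("critical-concentration estimation from a detection series", {
  s <- data.frame(conc_M = c(1e-7, 2.5e-7, 5e-7, 7.5e-7, 1e-6, 2.5e-6),
                  detected = c(0, 0, 0, 1, 1, 1))
  est <- estimate_critical_concentration(s)
  expect_equal(est$critical_conc_M, 7.5e-7)
  expect_equal(est$bound, "interior")
  # all detected: only a lower bound
  s2 <- data.frame(conc_M = c(1e-7, 1e-6), detected = c(1, 1))
  est2 <- estimate_critical_concentration(s2)
  expect_equal(est2$critical_conc_M, 1e-7)
  expect_equal(est2$bound, "lower_bound")
  expect_error(estimate_critical_concentration(
    data.frame(conc_M = 1e-6, detected = 0)), "not determined")
})
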