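test_that("noiseless generators are deterministic and seed-independent", {
  grids <- list(
    correlogram = function(seed)
      gen_correlogram(data.frame(radius_nm = 4.1, fraction = 1),
                      instrument = inst37, noise_sd = 0, seed = seed)$g2m1,
    buildup = function(seed)
      gen_buildup(45, noise_sd = 0, seed = seed)$intensity,
    isotherm = function(seed)
      gen_isotherm(31e-9, 2.4, 100, noise_sd = 0, seed = seed)$response_RU,
    tht = function(seed)
      gen_tht(0, 100, 1.5, 4, noise_sd = 0, seed = seed)$fluorescence_AU)
  for (g in grids) {
    expect_identical(g(1), g(999))
  }
})

test_that("identical seeds give identical noisy output, different seeds differ", {
  g <- function(seed) gen_isotherm(31e-9, 2.4, 100, noise_sd = 2,
                                   seed = seed)$response_RU
  expect_identical(g(7), g(7))
  expect_false(identical(g(7), g(8)))
})

test_that("seeded generation does not disturb the global RNG stream", {
  set.seed(123); a <- rnorm(3)
  set.seed(123); invisible(gen_tht(0, 100, 1.5, 4, noise_sd = 5, seed = 42))
  b <- rnorm(3)
  expect_identical(a, b)
})

test_that("correlogram forward model follows the Siegert relation", {
  sp <- data.frame(radius_nm = 4.1, fraction = 1)
  lags <- 10^seq(-8, -2.5, length.out = 120)
  tr <- gen_correlogram(sp, lags = lags, instrument = inst37)
  # monotone decay from beta toward 0
  expect_true(all(diff(tr$g2m1) < 0))
  expect_lt(abs(tr$g2m1[1] - inst37$beta), 0.01)
  # closed form at an arbitrary lag
  q <- scattering_vector(inst37)
  D <- inverse_stokes_einstein(4.1, inst37)
  tau <- tr$lags[37]
  expect_equal(tr$g2m1[37], inst37$beta * exp(-2 * D * q^2 * tau),
               tolerance = 1e-12)
  expect_error(gen_correlogram(data.frame(radius_nm = numeric(),
                                          fraction = numeric())),
               "at least one row")
  expect_error(gen_correlogram(data.frame(radius_nm = -1, fraction = 1)),
               "positive")
})

test_that("thermogram generator records exact ground-truth heat", {
  tg <- gen_thermogram(seq(0, 600, 0.5), baseline = 0,
                       pulses = data.frame(t_start = 60, duration = 120,
                                           amplitude = -5),
                       n_mol = 2e-7, injection_times = 30)
  expect_equal(attr(tg, "sim_spec")$params$heat_J, -600e-6 * 4.184,
               tolerance = 1e-12)
  # flat baseline with zero pulses
  flat <- gen_thermogram(seq(0, 100, 1), baseline = 2, n_mol = 1e-7)
  expect_true(all(flat$heat_flow_ucal_s == 2))
  expect_error(
    gen_thermogram(seq(0, 100, 1),
                   pulses = data.frame(t_start = 90, duration = 20,
                                       amplitude = -1), n_mol = 1e-7),
    "outside the time grid")
})

test_that("build-up generator matches hand-evaluated values", {
  bc <- gen_buildup(45, mixing_ms = c(2, 5, 10))
  expect_equal(bc$intensity, c(2, 5, 10) / 45, tolerance = 1e-12)
  # cap point and asymptote
  expect_equal(gen_buildup(20, mixing_ms = c(5, 10, 20))$intensity[3], 1)
  expect_equal(gen_buildup(20, mixing_ms = c(5, 10, 1e6),
                           model = "exponential")$intensity[3], 1,
               tolerance = 1e-9)
})

test_that("isotherm generator honors Hill identities", {
  kd <- 31e-9
  for (n in c(0.7, 1, 2.4)) {
    iso <- gen_isotherm(kd, n, 100, conc = c(kd / 10, kd, kd * 10))
    expect_equal(iso$response_RU[2], 50, tolerance = 1e-12)
  }
  # n = 1 reduces to the rectangular hyperbola
  conc <- 10^seq(-9, -6, length.out = 10)
  iso1 <- gen_isotherm(kd, 1, 100, conc = conc)
  expect_equal(iso1$response_RU, 100 * conc / (kd + conc),
               tolerance = 1e-12)
  expect_error(gen_isotherm(kd, 1, 100, conc = c(-1e-9, 1e-9, 1e-8)))
})

test_that("ThT generator: flat, midpoint and logistic quantile", {
  expect_true(all(gen_tht(7, 0, 1.5, 4)$fluorescence_AU == 7))
  tr <- gen_tht(0, 100, 1.5, 4, times = c(0, 4, 4 + log(99) / 1.5))
  expect_equal(tr$fluorescence_AU[2], 50, tolerance = 1e-12)
  expect_equal(tr$fluorescence_AU[3], 99, tolerance = 1e-9)
})

test_that("dH table generator is continuous piecewise linear", {
  tab <- gen_dH_table(c(300, 305, 310), breakpoint = 305,
                      slope_low = 1, slope_high = 0, intercept = -10)
  expect_equal(tab$dH_kJ_mol, c(-15, -10, -10))
  # constant when both slopes vanish
  flat <- gen_dH_table(seq(300, 320, 5), breakpoint = 310,
                       slope_low = 0, slope_high = 0, intercept = -5)
  expect_true(all(flat$dH_kJ_mol == -5))
  # two points 10 K apart on one slope differ by 10 kJ/mol
  expect_warning(
    tab1 <- gen_dH_table(c(300, 305, 310), breakpoint = 350,
                         slope_low = 1, slope_high = 7, intercept = 0),
    "single-phase")
  expect_equal(diff(tab1$dH_kJ_mol[c(1, 3)]), 10)
})

test_that("sim_spec validates its invariants", {
  expect_error(sim_spec("buildup", grid = c(1, 1, 2)), "increasing")
  expect_error(sim_spec("buildup", grid = c(1, 2)), "at least 3")
  expect_error(sim_spec("buildup", grid = 1:5, noise_sd = -1), ">= 0")
  expect_error(sim_spec("nope", grid = 1:5))
})
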