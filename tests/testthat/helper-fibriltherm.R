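# Shared fixtures for the test suite.

# instrument at the aggregation temperature used for most synthetic traces
inst37 <- dls_instrument(temperature_K = 310.15)

expect_rel <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}

withr_like_tempdir <- function() {
  d <- tempfile("fibriltherm-")
  dir.create(d)
  d
}

# noiseless two-phase enthalpy table: 4 points per branch plus breakpoint
dh_table_twophase <- function(slope_low = 113.84, slope_high = -373.51,
                              bp = 310.15, noise_sd = 0, seed = NULL) {
  temps <- sort(unique(c(bp - c(12, 8, 5, 2), bp, bp + c(2, 5, 8, 12))))
  gen_dH_table(temps, breakpoint = bp, slope_low = slope_low,
               slope_high = slope_high, noise_sd = noise_sd, seed = seed)
}
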