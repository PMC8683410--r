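test_that("build-up normalization divides by the reference intensity", {
  raw <- buildup_curve(c(2, 5, 100), c(44, 110, 990))
  norm <- normalize_buildup(raw, 100)
  expect_equal(norm$intensity, c(44, 110, 990) / 990, tolerance = 1e-9)
  expect_equal(norm$intensity[3], 1)
  expect_true(norm$normalized)
  # idempotent
  expect_identical(normalize_buildup(norm, 100), norm)
  zero <- buildup_curve(c(2, 5, 100), c(1, 2, 0))
  expect_error(normalize_buildup(zero, 100), "zero")
})

test_that("initial-slope fit is exact on linear build-ups", {
  fit <- fit_initial_slope(buildup_curve(c(2, 5, 10),
                                         c(2, 5, 10) / 45,
                                         normalized = TRUE))
  expect_equal(fit$t_m_s_ms, 45, tolerance = 1e-9)
  # exact for any build-up time on generated linear_capped curves
  for (tms in c(11, 20, 45, 110)) {
    bc <- gen_buildup(tms, mixing_ms = c(1, 2, 5, 10, 20, 50, 100, 200))
    expect_equal(fit_initial_slope(bc)$t_m_s_ms, tms, tolerance = 1e-9)
  }
})

test_that("initial-slope fit on an exponential curve has bounded bias", {
  tau <- 45
  bc <- gen_buildup(tau, mixing_ms = c(2, 5, 10, 15, 20, 30, 50, 100, 200),
                    model = "exponential")
  fit <- fit_initial_slope(bc, window = 0.2)
  expect_rel(fit$t_m_s_ms, tau, 0.12)
})

test_that("initial-slope fit rejects unusable input", {
  one_pt <- buildup_curve(c(2, 60, 90), c(0.1, 0.9, 0.95),
                          normalized = TRUE)
  expect_error(fit_initial_slope(one_pt), "fewer than 2")
  falling <- buildup_curve(c(2, 5, 10), c(-0.1, -0.2, -0.4),
                           normalized = TRUE)
  expect_error(fit_initial_slope(falling), "nonpositive")
})

test_that("volume-to-surface and diameter chain", {
  expect_equal(volume_to_surface(45, 0.2), sqrt(9 / pi), tolerance = 1e-12)
  expect_equal(volume_to_surface(5 * pi, 0.2), 1, tolerance = 1e-12)
  expect_lt(volume_to_surface(1e-9, 0.2), 1e-4)
  expect_equal(fibril_diameter(1), 4)
  expect_equal(fibril_diameter(volume_to_surface(45, 0.2)), 6.77,
               tolerance = 1e-3)
  expect_error(volume_to_surface(-1, 0.2), "positive")
})

test_that("hydration_analysis preserves its internal identities", {
  for (tms in c(13.5, 45, 110)) {
    bc <- gen_buildup(tms)
    h <- hydration_analysis(bc)
    expect_equal(h$diameter_nm, 4 * h$v_over_s_nm, tolerance = 1e-12)
    expect_equal(h$v_over_s_nm, sqrt(h$D_eff * h$t_m_s_ms / pi),
                 tolerance = 1e-12)
  }
})

test_that("ROI integration approximates the cell-area-weighted sum", {
  # uniform grid of ones: 2x2 cells of area 0.25 ppm^2 sum to 1.0
  x <- seq(0.25, 1.75, by = 0.5); y <- seq(0.25, 1.75, by = 0.5)
  m <- matrix(1, length(y), length(x))
  expect_equal(integrate_roi(m, x, y, xlim = c(0, 1.1), ylim = c(0, 1.1)),
               1.0)
  expect_error(integrate_roi(m, x, y, xlim = c(5, 6), ylim = c(0, 1)),
               "misses the grid")
  # a Gaussian peak fully inside the box integrates to its analytic volume
  xg <- seq(40, 80, by = 0.05); yg <- seq(10, 50, by = 0.05)
  peak <- outer(stats::dnorm(yg, 30, 1.2), stats::dnorm(xg, 60, 1.5))
  got <- integrate_roi(peak, xg, yg, xlim = c(50, 70), ylim = c(20, 40))
  expect_rel(got, 1, 0.02)
})

test_that("chemical-shift classification agrees with a brute-force oracle", {
  ref <- sse_shift_reference()
  # exact reference rows classify as themselves with distance 0
  for (i in seq_len(nrow(ref))) {
    row <- ref[i, ]
    got <- classify_sse(row$residue, row$ca, row$cb)
    expect_equal(got$sse, row$sse)
    expect_equal(got$distance, 0)
  }
  # randomized queries vs an independent nearest-neighbor computation
  set.seed(42)
  for (k in 1:50) {
    res <- sample(unique(ref$residue), 1)
    rows <- ref[ref$residue == res, ]
    ca <- stats::runif(1, min(rows$ca) - 3, max(rows$ca) + 3)
    cb <- if (all(!is.na(rows$cb))) {
      stats::runif(1, min(rows$cb) - 3, max(rows$cb) + 3)
    } else NA_real_
    d <- if (is.na(cb)) abs(rows$ca - ca)
         else sqrt((rows$ca - ca)^2 + (rows$cb - cb)^2)
    got <- classify_sse(res, ca, cb)
    expect_equal(got$distance, min(d), tolerance = 1e-12)
    if (!got$tie) expect_equal(got$sse, rows$sse[which.min(d)])
  }
})

test_that("alanine strand shifts classify as strand; ties fall to coil", {
  expect_equal(classify_sse("A", 50.9, 22.4)$sse, "strand")
  # construct an exact helix/coil tie for alanine in CA-only space
  ref <- sse_shift_reference()
  a_h <- ref$ca[ref$residue == "A" & ref$sse == "helix"]
  a_c <- ref$ca[ref$residue == "A" & ref$sse == "coil"]
  tie <- classify_sse("A", (a_h + a_c) / 2, NA_real_)
  expect_true(tie$tie)
  expect_equal(tie$sse, "coil")
  expect_error(classify_sse("X", 55, 30), "unknown residue")
})
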