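#' Simulation specification for synthetic instrument data
#'
#' A `sim_spec` bundles the ground-truth parameters, sampling grid, noise
#' level and seed used by the synthetic generators, so that every simulated
#' input carries a serializable record of how it was made.
#'
#' @param kind one of `"correlogram"`, `"thermogram"`, `"buildup"`,
#'   `"isotherm"`, `"tht"`, `"dH_table"`, `"cd_spectrum"`.
#' @param params named list of ground-truth parameters (units depend on
#'   `kind`; see the generator documentation).
#' @param grid sampling vector (lag times s / times s / mixing times ms /
#'   concentrations M / temperatures K / wavelengths nm); strictly
#'   increasing, length >= 3.
#' @param noise_sd standard deviation of additive Gaussian noise in the
#'   output's units; `0` gives bit-reproducible, seed-independent output.
#' @param seed integer RNG seed used when `noise_sd > 0`; `NULL` draws from
#'   the global stream.
#'
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(kind, params = list(), grid, noise_sd = 0, seed = NULL) {
  kinds <- c("correlogram", "thermogram", "buildup", "isotherm", "tht",
             "dH_table", "cd_spectrum")
  kind <- match.arg(kind, kinds)
  check_grid(grid)
  check_scalar(noise_sd, "noise_sd", nonnegative = TRUE)
  if (!is.null(seed)) check_scalar(seed, "seed")
  if (!is.list(params)) stopf("'params' must be a named list")
  structure(list(kind = kind, params = params, grid = grid,
                 noise_sd = noise_sd, seed = seed),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("<sim_spec: %s>  %d grid points, noise_sd = %g, seed = %s\n",
              x$kind, length(x$grid), x$noise_sd,
              if (is.null(x$seed)) "NULL" else format(x$seed)))
  invisible(x)
}

#' Simulate a DLS intensity-autocorrelation trace
#'
#' Forward model of the scattered-intensity autocorrelation function under
#' the Siegert relation: `g2 - 1 = beta * (sum_i f_i exp(-Gamma_i tau))^2`
#' with decay rates `Gamma_i = D_i q^2`, where each diffusion coefficient
#' follows from the species' hydrodynamic radius via the Stokes-Einstein
#' relation and `q` is the scattering vector of the instrument.
#'
#' @param species data frame with columns `radius_nm` (> 0) and `fraction`
#'   (intensity fractions summing to 1).
#' @param lags lag-time grid in seconds (strictly increasing, length >= 3).
#' @param instrument an [dls_instrument()] configuration (supplies q, T,
#'   viscosity and the coherence factor beta).
#' @param noise_sd,seed additive Gaussian noise; see [sim_spec()].
#'
#' @return a [correlogram_trace()] with the simulation spec attached as
#'   attribute `"sim_spec"`.
#' @examples
#' tr <- gen_correlogram(data.frame(radius_nm = 4.1, fraction = 1),
#'                       lags = 10^seq(-6, 0, length.out = 80))
#' @export
gen_correlogram <- function(species, lags = 10^seq(-6, 0, length.out = 120),
                            instrument = dls_instrument(),
                            noise_sd = 0, seed = NULL) {
  if (!is.data.frame(species) || nrow(species) == 0L) {
    stopf("'species' must be a data frame with at least one row")
  }
  if (!all(c("radius_nm", "fraction") %in% names(species))) {
    stopf("'species' needs columns 'radius_nm' and 'fraction'")
  }
  check_numeric(species$radius_nm, "radius_nm", positive = TRUE)
  check_numeric(species$fraction, "fraction")
  if (abs(sum(species$fraction) - 1) > 1e-6) {
    stopf("intensity fractions must sum to 1 (got %g)", sum(species$fraction))
  }
  check_grid(lags, "lags")
  q <- scattering_vector(instrument)
  D <- inverse_stokes_einstein(species$radius_nm, instrument)
  gamma <- D * q^2
  g1 <- colSums(species$fraction * exp(-outer(gamma, lags)))
  g2m1 <- instrument$beta * g1^2
  g2m1 <- add_noise(g2m1, noise_sd, seed)
  tr <- correlogram_trace(lags, g2m1, instrument)
  attr(tr, "sim_spec") <- sim_spec(
    "correlogram",
    params = list(radius_nm = species$radius_nm, fraction = species$fraction,
                  beta = instrument$beta),
    grid = lags, noise_sd = noise_sd, seed = seed)
  tr
}

#' Simulate an ITC thermogram
#'
#' Builds a heat-flow trace (microcal/s) as a flat baseline plus one
#' rectangular or Gaussian pulse per heat event. The exact total pulse heat
#' (microcal, and converted to joules at 4.184 J/cal) is recorded as ground
#' truth in the attached `sim_spec`.
#'
#' @param times time grid in seconds.
#' @param baseline constant instrument baseline, microcal/s.
#' @param pulses data frame with columns `t_start` (s), `duration` (s) and
#'   `amplitude` (microcal/s). Pulses may overlap; a pulse extending outside
#'   the grid span is an error. Zero rows give a flat baseline trace.
#' @param n_mol moles of protein associated with the injection (> 0).
#' @param shape `"rect"` (default) or `"gauss"` (a Gaussian with the same
#'   area, sd = duration/4).
#' @param injection_times injection timestamps recorded in the thermogram
#'   metadata; defaults to a single injection at the start of the trace.
#' @param noise_sd,seed additive Gaussian noise, microcal/s.
#'
#' @return a [thermogram()] with ground-truth total heat (J) in
#'   `attr(, "sim_spec")$params$heat_J`.
#' @export
gen_thermogram <- function(times, baseline = 0, pulses = NULL, n_mol,
                           shape = c("rect", "gauss"),
                           injection_times = times[1],
                           noise_sd = 0, seed = NULL) {
  shape <- match.arg(shape)
  check_grid(times, "times")
  check_scalar(baseline, "baseline")
  check_scalar(n_mol, "n_mol", positive = TRUE)
  if (is.null(pulses)) {
    pulses <- data.frame(t_start = numeric(), duration = numeric(),
                         amplitude = numeric())
  }
  flow <- rep(baseline, length(times))
  heat_ucal <- 0
  if (nrow(pulses) > 0L) {
    need <- c("t_start", "duration", "amplitude")
    if (!all(need %in% names(pulses))) {
      stopf("'pulses' needs columns %s", paste(need, collapse = ", "))
    }
    check_numeric(pulses$duration, "duration", positive = TRUE)
    span <- range(times)
    for (i in seq_len(nrow(pulses))) {
      t0 <- pulses$t_start[i]; dur <- pulses$duration[i]; a <- pulses$amplitude[i]
      if (t0 < span[1] || t0 + dur > span[2]) {
        stopf("pulse %d ([%g, %g] s) lies outside the time grid [%g, %g] s",
              i, t0, t0 + dur, span[1], span[2])
      }
      if (shape == "rect") {
        flow <- flow + a * (times >= t0 & times < t0 + dur)
      } else {
        mu <- t0 + dur / 2; sdv <- dur / 4
        flow <- flow + a * dur * stats::dnorm(times, mu, sdv)
      }
      heat_ucal <- heat_ucal + a * dur
    }
  }
  flow <- add_noise(flow, noise_sd, seed)
  tg <- thermogram(times, flow,
                   injections = data.frame(time_s = injection_times,
                                           n_mol = n_mol))
  attr(tg, "sim_spec") <- sim_spec(
    "thermogram",
    params = list(baseline = baseline, pulses = pulses, n_mol = n_mol,
                  heat_ucal = heat_ucal,
                  heat_J = heat_ucal * 1e-6 * .J_PER_CAL),
    grid = times, noise_sd = noise_sd, seed = seed)
  tg
}

#' Simulate a water-edited magnetization build-up curve
#'
#' Normalized transfer curves for a build-up time `t_m_s`:
#' `linear_capped` gives `S(t) = min(t / t_m_s, 1)` (the idealization behind
#' initial-slope fitting) and `exponential` gives `S(t) = 1 - exp(-t/t_m_s)`.
#'
#' @param t_m_s ground-truth build-up time, ms (> 0).
#' @param mixing_ms mixing-time grid, ms.
#' @param model `"linear_capped"` or `"exponential"`.
#' @param noise_sd,seed additive Gaussian noise on the normalized intensity.
#'
#' @return a [buildup_curve()] (flagged normalized) with the spec attached.
#' @export
gen_buildup <- function(t_m_s, mixing_ms = c(2, 5, 10, 20, 35, 50, 75, 100,
                                             150, 250, 500),
                        model = c("linear_capped", "exponential"),
                        noise_sd = 0, seed = NULL) {
  model <- match.arg(model)
  check_scalar(t_m_s, "t_m_s", positive = TRUE)
  check_grid(mixing_ms, "mixing_ms")
  s <- switch(model,
              linear_capped = pmin(mixing_ms / t_m_s, 1),
              exponential   = 1 - exp(-mixing_ms / t_m_s))
  s <- add_noise(s, noise_sd, seed)
  bc <- buildup_curve(mixing_ms, s, normalized = TRUE)
  attr(bc, "sim_spec") <- sim_spec(
    "buildup", params = list(t_m_s = t_m_s, model = model),
    grid = mixing_ms, noise_sd = noise_sd, seed = seed)
  bc
}

#' Simulate an SPR equilibrium binding isotherm
#'
#' Hill model: `R(c) = R_max * c^n / (K_D^n + c^n)` plus additive noise.
#'
#' @param K_D dissociation constant, M (> 0).
#' @param n Hill coefficient (> 0); `n = 1` is the hyperbolic (Langmuir)
#'   isotherm.
#' @param R_max saturating response, RU (> 0).
#' @param conc analyte concentration grid, M, strictly increasing and > 0;
#'   defaults to 12 log-spaced points on `[0.1 K_D, 10 K_D]`.
#' @param noise_sd,seed additive Gaussian noise, RU.
#'
#' @return a [binding_isotherm()] with the spec attached.
#' @export
gen_isotherm <- function(K_D, n, R_max, conc = NULL, noise_sd = 0,
                         seed = NULL) {
  check_scalar(K_D, "K_D", positive = TRUE)
  check_scalar(n, "n", positive = TRUE)
  check_scalar(R_max, "R_max", positive = TRUE)
  if (is.null(conc)) {
    conc <- 10^seq(log10(0.1 * K_D), log10(10 * K_D), length.out = 12)
  }
  check_grid(conc, "conc")
  if (any(conc <= 0)) stopf("analyte concentrations must be > 0")
  resp <- R_max * conc^n / (K_D^n + conc^n)
  resp <- add_noise(resp, noise_sd, seed)
  iso <- binding_isotherm(conc, resp)
  attr(iso, "sim_spec") <- sim_spec(
    "isotherm", params = list(K_D = K_D, n = n, R_max = R_max),
    grid = conc, noise_sd = noise_sd, seed = seed)
  iso
}

#' Simulate a thioflavin-T aggregation time course
#'
#' Four-parameter logistic: `F(t) = F0 + A / (1 + exp(-k (t - t50)))`.
#'
#' @param F0 baseline fluorescence, AU.
#' @param A transition amplitude, AU (>= 0).
#' @param k growth rate, 1/h (> 0).
#' @param t50 half-transition time, h.
#' @param times time grid in hours.
#' @param noise_sd,seed additive Gaussian noise, AU.
#'
#' @return a [tht_trace()] with the spec attached.
#' @export
gen_tht <- function(F0, A, k, t50, times = seq(0, 24, by = 0.25),
                    noise_sd = 0, seed = NULL) {
  check_scalar(F0, "F0"); check_scalar(A, "A", nonnegative = TRUE)
  check_scalar(k, "k", positive = TRUE); check_scalar(t50, "t50")
  check_grid(times, "times")
  f <- F0 + A / (1 + exp(-k * (times - t50)))
  f <- add_noise(f, noise_sd, seed)
  tr <- tht_trace(times, f, background_corrected = TRUE)
  attr(tr, "sim_spec") <- sim_spec(
    "tht", params = list(F0 = F0, A = A, k = k, t50 = t50),
    grid = times, noise_sd = noise_sd, seed = seed)
  tr
}

#' Simulate a two-phase molar-enthalpy vs temperature table
#'
#' Continuous piecewise-linear enthalpy of fibrillization with a single
#' breakpoint: below the breakpoint the slope is `slope_low`, above it
#' `slope_high` (both in kJ/mol/K — the two heat-capacity branches), with
#' `intercept` the enthalpy at the breakpoint.
#'
#' @param temps temperature grid, K.
#' @param breakpoint breakpoint temperature, K; must lie inside the grid
#'   span (a grid entirely on one side yields a single-phase table with a
#'   warning).
#' @param slope_low,slope_high branch slopes, kJ/mol/K.
#' @param intercept enthalpy at the breakpoint, kJ/mol.
#' @param noise_sd,seed additive Gaussian noise, kJ/mol.
#'
#' @return data frame with columns `T_K` and `dH_kJ_mol`, spec attached.
#' @export
gen_dH_table <- function(temps, breakpoint = 310.15, slope_low, slope_high,
                         intercept = -297.74, noise_sd = 0, seed = NULL) {
  check_grid(temps, "temps")
  check_scalar(breakpoint, "breakpoint")
  check_scalar(slope_low, "slope_low"); check_scalar(slope_high, "slope_high")
  check_scalar(intercept, "intercept")
  if (breakpoint <= min(temps) || breakpoint >= max(temps)) {
    warnf("breakpoint %g K lies outside the grid span; single-phase table",
          breakpoint)
  }
  dh <- intercept + ifelse(temps <= breakpoint,
                           slope_low * (temps - breakpoint),
                           slope_high * (temps - breakpoint))
  dh <- add_noise(dh, noise_sd, seed)
  tab <- data.frame(T_K = temps, dH_kJ_mol = dh)
  attr(tab, "sim_spec") <- sim_spec(
    "dH_table",
    params = list(breakpoint = breakpoint, slope_low = slope_low,
                  slope_high = slope_high, intercept = intercept),
    grid = temps, noise_sd = noise_sd, seed = seed)
  tab
}

#' Simulate a far-UV CD spectrum
#'
#' A minimal mixture of two Gaussian negative bands near 208 and 222 nm
#' (helical signature) and one near 217 nm (beta signature), weighted by a
#' helix fraction. This is a plotting/normalization stand-in, not a
#' structure-aware simulator.
#'
#' @param wavelengths grid in nm.
#' @param helix_fraction mixing weight in `[0, 1]`.
#' @param scale overall ellipticity scale, mdeg.
#' @param noise_sd,seed additive Gaussian noise, mdeg.
#'
#' @return a [cd_spectrum()] with the spec attached.
#' @export
gen_cd_spectrum <- function(wavelengths = seq(195, 260, by = 0.5),
                            helix_fraction = 0.5, scale = 10,
                            noise_sd = 0, seed = NULL) {
  check_grid(wavelengths, "wavelengths")
  check_scalar(helix_fraction, "helix_fraction", nonnegative = TRUE)
  if (helix_fraction > 1) stopf("'helix_fraction' must be <= 1")
  check_scalar(scale, "scale", positive = TRUE)
  helical <- -(stats::dnorm(wavelengths, 208, 5) +
               stats::dnorm(wavelengths, 222, 6))
  beta <- -stats::dnorm(wavelengths, 217, 7)
  ell <- scale * 10 * (helix_fraction * helical + (1 - helix_fraction) * beta)
  ell <- add_noise(ell, noise_sd, seed)
  sp <- cd_spectrum(wavelengths, ell)
  attr(sp, "sim_spec") <- sim_spec(
    "cd_spectrum",
    params = list(helix_fraction = helix_fraction, scale = scale),
    grid = wavelengths, noise_sd = noise_sd, seed = seed)
  sp
}
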