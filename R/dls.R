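# Dynamic light scattering: correlogram inversion, Stokes-Einstein sizing,
# empirical mass calibration and critical-concentration estimation.

#' DLS instrument configuration
#'
#' Optical and solvent parameters needed to convert correlogram decay rates
#' into diffusion coefficients and hydrodynamic radii. Defaults describe a
#' typical cuvette instrument (660 nm laser, 90 degree detection, aqueous
#' buffer); every value can be overridden.
#'
#' @param wavelength_nm laser vacuum wavelength, nm.
#' @param angle_deg scattering angle, degrees.
#' @param refractive_index solvent refractive index (dimensionless).
#' @param temperature_K sample temperature, K.
#' @param viscosity_Pa_s solvent dynamic viscosity, Pa s. `NULL` looks up
#'   water viscosity at `temperature_K` from an embedded table.
#' @param beta Siegert coherence factor in (0, 1].
#'
#' @return an object of class `dls_instrument`.
#' @examples
#' dls_instrument(temperature_K = 310.15)
#' @export
dls_instrument <- function(wavelength_nm = 660, angle_deg = 90,
                           refractive_index = 1.33, temperature_K = 293.15,
                           viscosity_Pa_s = NULL, beta = 0.9) {
  check_scalar(wavelength_nm, "wavelength_nm", positive = TRUE)
  check_scalar(angle_deg, "angle_deg", positive = TRUE)
  check_scalar(refractive_index, "refractive_index", positive = TRUE)
  check_scalar(temperature_K, "temperature_K", positive = TRUE)
  check_scalar(beta, "beta", positive = TRUE)
  if (beta > 1) stopf("'beta' must lie in (0, 1]")
  if (is.null(viscosity_Pa_s)) {
    viscosity_Pa_s <- water_viscosity(temperature_K)
  }
  check_scalar(viscosity_Pa_s, "viscosity_Pa_s", positive = TRUE)
  structure(list(wavelength_nm = wavelength_nm, angle_deg = angle_deg,
                 refractive_index = refractive_index,
                 temperature_K = temperature_K,
                 viscosity_Pa_s = viscosity_Pa_s, beta = beta),
            class = "dls_instrument")
}

#' @export
print.dls_instrument <- function(x, ...) {
  cat(sprintf(paste0("<dls_instrument> lambda = %g nm, angle = %g deg, ",
                     "n = %g, T = %g K, eta = %g Pa s, beta = %g\n"),
              x$wavelength_nm, x$angle_deg, x$refractive_index,
              x$temperature_K, x$viscosity_Pa_s, x$beta))
  invisible(x)
}

#' Dynamic viscosity of water
#'
#' Linear interpolation on an embedded table of water viscosities (Pa s)
#' between 283 and 353 K, used as the default solvent model.
#'
#' @param temperature_K temperature, K (within the table range).
#' @return viscosity, Pa s.
#' @export
water_viscosity <- function(temperature_K) {
  check_numeric(temperature_K, "temperature_K", positive = TRUE)
  tab_T <- 273.15 + c(10, 15, 20, 25, 30, 35, 37, 40, 45, 50, 60, 70, 80)
  tab_eta <- c(1.306, 1.138, 1.002, 0.890, 0.797, 0.719, 0.691, 0.653,
               0.596, 0.547, 0.466, 0.404, 0.354) * 1e-3
  if (any(temperature_K < min(tab_T) | temperature_K > max(tab_T))) {
    stopf("water viscosity table covers %g-%g K", min(tab_T), max(tab_T))
  }
  stats::approx(tab_T, tab_eta, xout = temperature_K)$y
}

#' Scattering vector magnitude
#'
#' `q = (4 pi n / lambda) sin(theta / 2)` in 1/m.
#'
#' @param config a [dls_instrument()].
#' @return q, 1/m.
#' @export
scattering_vector <- function(config) {
  stopifnot(inherits(config, "dls_instrument"))
  4 * pi * config$refractive_index / (config$wavelength_nm * 1e-9) *
    sin(config$angle_deg * pi / 360)
}

#' Stokes-Einstein sizing
#'
#' Converts a translational diffusion coefficient into the hydrodynamic
#' radius of the equivalent sphere, `R_H = k_B T / (6 pi eta D)`, and back.
#'
#' @param diffusion diffusion coefficient(s), m^2/s (> 0).
#' @param config a [dls_instrument()] supplying temperature and viscosity.
#' @return `stokes_einstein`: hydrodynamic radius, nm.
#' @examples
#' cfg <- dls_instrument(temperature_K = 293.15, viscosity_Pa_s = 1.002e-3)
#' stokes_einstein(9.4e-11, cfg)  # ~2.28 nm
#' @export
stokes_einstein <- function(diffusion, config = dls_instrument()) {
  check_numeric(diffusion, "diffusion", positive = TRUE)
  stopifnot(inherits(config, "dls_instrument"))
  .kB * config$temperature_K /
    (6 * pi * config$viscosity_Pa_s * diffusion) * 1e9
}

#' @rdname stokes_einstein
#' @param radius_nm hydrodynamic radius (or radii), nm (> 0).
#' @return `inverse_stokes_einstein`: diffusion coefficient, m^2/s.
#' @export
inverse_stokes_einstein <- function(radius_nm, config = dls_instrument()) {
  check_numeric(radius_nm, "radius_nm", positive = TRUE)
  stopifnot(inherits(config, "dls_instrument"))
  .kB * config$temperature_K /
    (6 * pi * config$viscosity_Pa_s * radius_nm * 1e-9)
}

#' DLS correlogram trace
#'
#' Container for an intensity-autocorrelation measurement: lag times and
#' `g2 - 1` values plus the instrument configuration they were recorded
#' under.
#'
#' @param lags lag times, s, strictly increasing, > 0.
#' @param g2m1 `g2(tau) - 1` values, dimensionless, same length as `lags`.
#' @param config a [dls_instrument()].
#' @return an object of class `correlogram_trace`.
#' @export
correlogram_trace <- function(lags, g2m1, config = dls_instrument()) {
  check_numeric(lags, "lags", positive = TRUE)
  check_numeric(g2m1, "g2m1")
  if (length(lags) != length(g2m1)) stopf("'lags' and 'g2m1' lengths differ")
  if (any(diff(lags) <= 0)) stopf("'lags' must be strictly increasing")
  stopifnot(inherits(config, "dls_instrument"))
  structure(list(lags = lags, g2m1 = g2m1, config = config),
            class = "correlogram_trace")
}

#' @export
print.correlogram_trace <- function(x, ...) {
  cat(sprintf("<correlogram_trace> %d lags in [%.2g, %.2g] s\n",
              length(x$lags), min(x$lags), max(x$lags)))
  invisible(x)
}

#' Invert a correlogram into a hydrodynamic size distribution
#'
#' Fits `g2 - 1 = beta (sum_i f_i exp(-Gamma_i tau))^2` by bounded
#' nonlinear least squares with log-spaced initial decay rates, then maps
#' each `Gamma_i` to a diffusion coefficient `D_i = Gamma_i / q^2` and a
#' hydrodynamic radius via [stokes_einstein()]. Intensity fractions are
#' parameterized as squared weights so they stay nonnegative and are
#' renormalized to sum to 1.
#'
#' @param trace a [correlogram_trace()].
#' @param n_components number of exponential components, 1 to 3.
#' @return a `size_distribution`: data frame `species` with columns
#'   `radius_nm`, `diffusion_m2_s`, `fraction`, `mass_kDa` (NA until
#'   calibrated), sorted by radius, plus the fit residual norm.
#' @examples
#' tr <- gen_correlogram(data.frame(radius_nm = 4.1, fraction = 1))
#' fit_correlogram(tr, 1)
#' @export
fit_correlogram <- function(trace, n_components = 1) {
  stopifnot(inherits(trace, "correlogram_trace"))
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > 3L) {
    stopf("'n_components' must be 1, 2 or 3")
  }
  if (length(trace$lags) < 5L * n_components) {
    stopf("need at least %d points for %d components",
          5L * n_components, n_components)
  }
  y <- trace$g2m1
  if (y[length(y)] >= 0.9 * y[1]) {
    stopf("trace does not decay (final value >= 90%% of initial); %s",
          "no exponential analysis possible")
  }
  beta <- trace$config$beta
  tau <- trace$lags
  k <- n_components
  model_fn <- function(p) {
    gam <- exp(p[seq_len(k)])
    w <- p[k + seq_len(k)]^2
    f <- w / sum(w)
    beta * colSums(f * exp(-outer(gam, tau)))^2
  }
  # characteristic decay rate from where the trace falls to beta e^-2,
  # used to center one of the restart initializations
  i_c <- which(y < beta * exp(-2))[1]
  gamma_eff <- if (is.na(i_c)) 1 / max(tau) else 1 / tau[i_c]
  starts <- list(
    # log-spaced rates spanning the lag window
    seq(log(1 / max(tau)), log(1 / min(tau)),
        length.out = k + 2)[2:(k + 1)],
    # rates bracketing the characteristic decay
    log(gamma_eff) + seq(-1.5, 1.5, length.out = max(k, 2))[seq_len(k)])
  lg_lim <- c(log(0.01 / max(tau)), log(100 / min(tau)))
  fits <- lapply(starts, function(lg0) {
    start <- c(lg0, rep(1, k))
    names(start) <- c(paste0("lg", seq_len(k)), paste0("w", seq_len(k)))
    tryCatch(
      minpack.lm::nls.lm(par = start,
                         fn = function(p) y - model_fn(p),
                         lower = c(rep(lg_lim[1], k), rep(1e-6, k)),
                         upper = c(rep(lg_lim[2], k), rep(1e6, k)),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && !(f$info %in% c(0, 9)), fits)
  if (length(fits) == 0L) {
    stopf("correlogram fit did not converge from any initialization; %s",
          "check the lag range against the decay")
  }
  fit <- fits[[which.min(vapply(fits, function(f) sum(f$fvec^2),
                                numeric(1)))]]
  p <- fit$par
  gam <- exp(p[seq_len(k)])
  w <- p[k + seq_len(k)]^2
  frac <- w / sum(w)
  q <- scattering_vector(trace$config)
  D <- gam / q^2
  radius <- stokes_einstein(D, trace$config)
  ord <- order(radius)
  size_distribution(
    data.frame(radius_nm = radius[ord], diffusion_m2_s = D[ord],
               fraction = frac[ord], mass_kDa = NA_real_,
               row.names = NULL),
    residual = sqrt(sum(fit$fvec^2)))
}

#' @rdname fit_correlogram
#' @param species data frame of species (see return value).
#' @param residual residual norm of the originating fit.
#' @export
size_distribution <- function(species, residual = NA_real_) {
  stopifnot(is.data.frame(species),
            all(c("radius_nm", "fraction") %in% names(species)))
  if (is.unsorted(species$radius_nm)) {
    species <- species[order(species$radius_nm), , drop = FALSE]
  }
  if (abs(sum(species$fraction) - 1) > 1e-6) {
    stopf("species fractions must sum to 1")
  }
  structure(list(species = species, residual = residual),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat("<size_distribution>\n")
  sp <- x$species
  for (i in seq_len(nrow(sp))) {
    cat(sprintf("  R_H = %6.2f nm  fraction = %5.3f  M = %s\n",
                sp$radius_nm[i], sp$fraction[i],
                if (is.na(sp$mass_kDa[i])) "NA"
                else sprintf("%.3g kDa", sp$mass_kDa[i])))
  }
  cat(sprintf("  residual norm = %.3g\n", x$residual))
  invisible(x)
}

#' Reference radius/mass pairs for the empirical mass calibration
#'
#' Hydrodynamic radius (nm) and instrument-reported molecular mass (kDa)
#' pairs observed for the DISC1 C-region oligomer series, used as the
#' default training data for [calibrate_mass()]. The instrument's internal
#' radius-to-mass relation is proprietary, so the calibration is shipped as
#' data and replaceable by the user.
#'
#' @return data frame with columns `radius_nm`, `mass_kDa`.
#' @export
dls_mass_pairs <- function() {
  data.frame(
    radius_nm = c(4.1, 4.0, 4.1, 4.4, 17.2, 18.9, 4.1, 13.0),
    mass_kDa  = c(81.5, 81.3, 84.0, 87.0, 2300, 2800, 85.7, 1200))
}

#' Power-law mass calibration from (radius, mass) pairs
#'
#' Least-squares fit of `log M = log a + b log R_H`, giving the scaling law
#' `M = a R_H^b` used to annotate fitted species with molecular masses.
#'
#' @param pairs data frame with columns `radius_nm`, `mass_kDa`; at least
#'   two pairs with distinct radii.
#' @return an object of class `mass_calibration` with elements `a`
#'   (kDa/nm^b), `b` and the training pairs.
#' @examples
#' calibrate_mass(dls_mass_pairs())
#' @export
calibrate_mass <- function(pairs = dls_mass_pairs()) {
  stopifnot(is.data.frame(pairs),
            all(c("radius_nm", "mass_kDa") %in% names(pairs)))
  check_numeric(pairs$radius_nm, "radius_nm", positive = TRUE)
  check_numeric(pairs$mass_kDa, "mass_kDa", positive = TRUE)
  if (nrow(pairs) < 2L || length(unique(pairs$radius_nm)) < 2L) {
    stopf("need at least 2 pairs with distinct radii")
  }
  fit <- stats::lm(log(mass_kDa) ~ log(radius_nm), data = pairs)
  cf <- stats::coef(fit)
  structure(list(a = exp(unname(cf[1])), b = unname(cf[2]), pairs = pairs),
            class = "mass_calibration")
}

#' @export
print.mass_calibration <- function(x, ...) {
  cat(sprintf("<mass_calibration> M = %.4g * R_H^%.4g kDa (%d pairs)\n",
              x$a, x$b, nrow(x$pairs)))
  invisible(x)
}

#' Predict molecular mass from hydrodynamic radius
#'
#' @param radius_nm radius or radii, nm (> 0).
#' @param cal a fitted [calibrate_mass()] object.
#' @return mass in kDa, `M = a R_H^b`.
#' @export
mass_from_radius <- function(radius_nm, cal = calibrate_mass()) {
  if (!inherits(cal, "mass_calibration")) {
    stopf("'cal' must be a fitted mass_calibration")
  }
  check_numeric(radius_nm, "radius_nm", positive = TRUE)
  cal$a * radius_nm^cal$b
}

#' Annotate a size distribution with calibrated masses
#'
#' @param dist a `size_distribution`.
#' @param cal a [calibrate_mass()] object.
#' @return the distribution with `mass_kDa` filled in.
#' @export
annotate_mass <- function(dist, cal = calibrate_mass()) {
  stopifnot(inherits(dist, "size_distribution"))
  dist$species$mass_kDa <- mass_from_radius(dist$species$radius_nm, cal)
  dist
}

#' Critical concentration from a detection-limit dilution series
#'
#' Under the one-dimensional crystallization model the free monomer /
#' oligomer concentration in equilibrium with fibrils sits at the
#' instrument's detection limit. Given a dilution series with a detected /
#' not-detected flag per concentration, the estimate is the lowest
#' concentration at which the species is still seen; the result records
#' whether undetected lower concentrations bracket it (interior estimate)
#' or whether it is only a bound.
#'
#' @param series data frame with columns `conc_M` (> 0) and `detected`
#'   (logical or 0/1).
#' @return list with `critical_conc_M` and `bound` (`"interior"` or
#'   `"lower_bound"`).
#' @examples
#' s <- data.frame(conc_M = c(2.5e-7, 5e-7, 7.5e-7, 1e-6),
#'                 detected = c(FALSE, FALSE, TRUE, TRUE))
#' estimate_critical_concentration(s)
#' @export
estimate_critical_concentration <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("conc_M", "detected") %in% names(series)))
  if (nrow(series) < 1L) stopf("empty detection series")
  check_numeric(series$conc_M, "conc_M", positive = TRUE)
  det <- as.logical(series$detected)
  if (any(is.na(det))) stopf("'detected' must be logical or 0/1")
  if (!any(det)) stopf("species never detected; critical %s",
                       "concentration not determined")
  cc <- min(series$conc_M[det])
  bound <- if (any(series$conc_M < cc & !det)) "interior" else "lower_bound"
  list(critical_conc_M = cc, bound = bound)
}
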