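# Thioflavin-T aggregation kinetics descriptors and circular-dichroism
# spectrum normalization.

#' Thioflavin-T fluorescence time course
#'
#' @param time_h times, h, strictly increasing.
#' @param fluorescence_AU fluorescence, arbitrary units, same length.
#' @param background_corrected logical flag.
#' @return an object of class `tht_trace`.
#' @export
tht_trace <- function(time_h, fluorescence_AU, background_corrected = FALSE) {
  check_numeric(time_h, "time_h")
  check_numeric(fluorescence_AU, "fluorescence_AU")
  if (length(time_h) != length(fluorescence_AU)) stopf("length mismatch")
  if (any(diff(time_h) <= 0)) stopf("'time_h' must be strictly increasing")
  structure(list(time_h = time_h, fluorescence_AU = fluorescence_AU,
                 background_corrected = isTRUE(background_corrected)),
            class = "tht_trace")
}

#' @export
print.tht_trace <- function(x, ...) {
  cat(sprintf("<tht_trace> %d points over %.3g h%s\n",
              length(x$time_h), diff(range(x$time_h)),
              if (x$background_corrected) ", background-corrected" else ""))
  invisible(x)
}

#' Subtract a buffer-control trace
#'
#' Pointwise subtraction of a buffer well from a reaction well. Time grids
#' must match; with `interpolate = TRUE` the buffer is linearly
#' interpolated onto the reaction grid (grids must overlap).
#'
#' @param trace,buffer [tht_trace()] objects.
#' @param interpolate allow interpolation of the buffer trace.
#' @return a background-corrected `tht_trace`.
#' @export
subtract_background <- function(trace, buffer, interpolate = FALSE) {
  stopifnot(inherits(trace, "tht_trace"), inherits(buffer, "tht_trace"))
  if (identical(trace$time_h, buffer$time_h)) {
    bg <- buffer$fluorescence_AU
  } else if (interpolate) {
    if (min(buffer$time_h) > max(trace$time_h) ||
        max(buffer$time_h) < min(trace$time_h)) {
      stopf("buffer and reaction time grids do not overlap")
    }
    bg <- stats::approx(buffer$time_h, buffer$fluorescence_AU,
                        xout = trace$time_h, rule = 2)$y
  } else {
    stopf("time grids differ; set interpolate = TRUE to resample the buffer")
  }
  tht_trace(trace$time_h, trace$fluorescence_AU - bg,
            background_corrected = TRUE)
}

#' Fit a logistic model to a ThT aggregation trace
#'
#' Four-parameter logistic `F(t) = F0 + A / (1 + exp(-k (t - t50)))` by
#' least squares, with derived descriptors: the lag time from the tangent
#' construction at the midpoint, `lag = t50 - 2/k`, and the plateau time
#' at 99% of the transition, `plateau = t50 + ln(99)/k`.
#'
#' @param trace a [tht_trace()].
#' @param noise_floor_AU dynamic range below which the trace is treated as
#'   transition-free.
#' @return an object of class `tht_fit` with `F0`, `A`, `k`, `t50`,
#'   `lag_h`, `plateau_h`, `rss` and `no_transition` flag (TRUE for flat
#'   traces, in which case the kinetic fields are NA).
#' @examples
#' tr <- gen_tht(10, 100, k = 1.5, t50 = 4)
#' fit_tht_sigmoid(tr)
#' @export
fit_tht_sigmoid <- function(trace, noise_floor_AU = 0) {
  stopifnot(inherits(trace, "tht_trace"))
  t <- trace$time_h; f <- trace$fluorescence_AU
  if (length(t) < 8L) stopf("need at least 8 time points")
  rng <- diff(range(f))
  if (rng <= max(noise_floor_AU, 0)) {
    return(structure(list(F0 = mean(f), A = 0, k = NA_real_,
                          t50 = NA_real_, lag_h = NA_real_,
                          plateau_h = NA_real_, rss = sum((f - mean(f))^2),
                          no_transition = TRUE),
                     class = "tht_fit"))
  }
  t50_0 <- t[which.min(abs(f - (min(f) + rng / 2)))]
  dat <- data.frame(t = t, f = f)
  fit <- minpack.lm::nlsLM(
    f ~ F0 + A / (1 + exp(-k * (t - t50))), data = dat,
    start = list(F0 = min(f), A = rng, k = 4 / diff(range(t)) * 4,
                 t50 = t50_0),
    lower = c(-Inf, 0, 1e-6, min(t) - diff(range(t))),
    upper = c(Inf, Inf, Inf, max(t) + diff(range(t))),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- as.list(stats::coef(fit))
  no_trans <- cf$A <= max(noise_floor_AU, 1e-9 * max(abs(f), 1))
  structure(list(F0 = cf$F0, A = cf$A, k = cf$k, t50 = cf$t50,
                 lag_h = if (no_trans) NA_real_ else cf$t50 - 2 / cf$k,
                 plateau_h = if (no_trans) NA_real_ else
                   cf$t50 + log(99) / cf$k,
                 rss = sum(stats::resid(fit)^2),
                 no_transition = no_trans),
            class = "tht_fit")
}

#' @export
print.tht_fit <- function(x, ...) {
  if (x$no_transition) {
    cat(sprintf("<tht_fit> no transition (flat at %.3g AU)\n", x$F0))
  } else {
    cat(sprintf(paste0("<tht_fit> F0 = %.3g, A = %.3g AU, k = %.3g 1/h, ",
                       "t50 = %.3g h\n  lag = %.3g h, plateau at %.3g h\n"),
                x$F0, x$A, x$k, x$t50, x$lag_h, x$plateau_h))
  }
  invisible(x)
}

#' Detect the plateau time of a trace
#'
#' Returns the earliest time after which every value stays within
#' `tol` times the trace's dynamic range of the trailing-window median.
#' A trace still drifting in the trailing window (projected change beyond
#' the same band) is flagged not-reached.
#'
#' @param trace a [tht_trace()].
#' @param tol band half-width as a fraction of the dynamic range
#'   (default 0.02).
#' @param trailing fraction of the trace used as the trailing window
#'   (default 0.2, at least 3 points).
#' @return list with `plateau_h` (NA when not reached), `reached`
#'   (logical) and `level_AU` (trailing median).
#' @export
detect_plateau <- function(trace, tol = 0.02, trailing = 0.2) {
  stopifnot(inherits(trace, "tht_trace"))
  check_scalar(tol, "tol", positive = TRUE)
  t <- trace$time_h; f <- trace$fluorescence_AU
  n <- length(t)
  k <- max(3L, ceiling(trailing * n))
  if (n < 3L) stopf("need at least 3 trailing points")
  tail_idx <- (n - k + 1L):n
  med <- stats::median(f[tail_idx])
  if (diff(range(f)) == 0) {
    return(list(plateau_h = t[1], reached = TRUE, level_AU = med))
  }
  band <- tol * diff(range(f))
  slope <- stats::coef(stats::lm(f[tail_idx] ~ t[tail_idx]))[2]
  drift <- unname(slope) * diff(range(t[tail_idx]))
  if (abs(drift) > band) {
    return(list(plateau_h = NA_real_, reached = FALSE, level_AU = med))
  }
  ok <- abs(f - med) <= band
  # earliest index from which all later points stay inside the band
  idx <- which(rev(cumprod(rev(ok))) == 1)[1]
  list(plateau_h = t[idx], reached = TRUE, level_AU = med)
}

#' Circular-dichroism spectrum
#'
#' @param wavelength_nm wavelengths, nm, strictly increasing.
#' @param ellipticity_mdeg ellipticities, mdeg, same length.
#' @param normalized logical flag.
#' @param reference_nm wavelength used for normalization (NA when raw).
#' @return an object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelength_nm, ellipticity_mdeg, normalized = FALSE,
                        reference_nm = NA_real_) {
  check_numeric(wavelength_nm, "wavelength_nm", positive = TRUE)
  check_numeric(ellipticity_mdeg, "ellipticity_mdeg")
  if (length(wavelength_nm) != length(ellipticity_mdeg)) {
    stopf("length mismatch")
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stopf("'wavelength_nm' must be strictly increasing")
  }
  structure(list(wavelength_nm = wavelength_nm,
                 ellipticity_mdeg = ellipticity_mdeg,
                 normalized = isTRUE(normalized),
                 reference_nm = reference_nm),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum> %d wavelengths in [%g, %g] nm%s\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm),
              if (x$normalized) sprintf(", normalized at %g nm",
                                        x$reference_nm) else ""))
  invisible(x)
}

#' Normalize a CD spectrum to a reference wavelength
#'
#' Divides the whole spectrum by the absolute ellipticity at the grid
#' point nearest the reference wavelength (default 217 nm, the beta-sheet
#' band), so spectra of different concentrations become comparable in
#' shape. Scale-invariant and idempotent.
#'
#' @param spec a [cd_spectrum()].
#' @param reference_nm reference wavelength, nm (must lie inside the
#'   spectrum's span).
#' @return a normalized `cd_spectrum` with `|ellipticity(reference)| = 1`.
#' @export
normalize_cd <- function(spec, reference_nm = 217) {
  stopifnot(inherits(spec, "cd_spectrum"))
  check_scalar(reference_nm, "reference_nm", positive = TRUE)
  if (reference_nm < min(spec$wavelength_nm) ||
      reference_nm > max(spec$wavelength_nm)) {
    stopf("reference %g nm outside the spectral range", reference_nm)
  }
  i <- which.min(abs(spec$wavelength_nm - reference_nm))
  ref <- abs(spec$ellipticity_mdeg[i])
  if (ref == 0) stopf("zero ellipticity at the reference wavelength")
  cd_spectrum(spec$wavelength_nm, spec$ellipticity_mdeg / ref,
              normalized = TRUE, reference_nm = spec$wavelength_nm[i])
}

#' Helicity band ratio of a CD spectrum
#'
#' Two-point descriptor of helical content change: the ratio of the
#' ellipticities at the 208 and 222 nm minima (nearest grid points). No
#' deconvolution is attempted.
#'
#' @param spec a [cd_spectrum()].
#' @return ratio `theta(208) / theta(222)`.
#' @export
helicity_ratio <- function(spec) {
  stopifnot(inherits(spec, "cd_spectrum"))
  v <- function(wl) {
    spec$ellipticity_mdeg[which.min(abs(spec$wavelength_nm - wl))]
  }
  v(208) / v(222)
}
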