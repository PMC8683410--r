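# Fibrillization thermodynamics under the one-dimensional crystallization
# model: ITC thermogram integration, the free-energy / entropy chain, the
# two-phase heat-capacity fit and a stochastic check of the elongation
# reaction scheme.

#' ITC thermogram container
#'
#' @param times_s time grid, s, strictly increasing.
#' @param heat_flow_ucal_s heat flow, microcal/s, same length.
#' @param injections data frame with columns `time_s` and `n_mol` (> 0),
#'   one row per injection; integration windows run from each injection to
#'   the next (or to the end of the trace).
#' @param baseline_model `"constant"` (estimated from pre-injection
#'   samples), `"linear"` (fitted to samples outside all injection
#'   windows), or `"none"`.
#' @return an object of class `thermogram`.
#' @export
thermogram <- function(times_s, heat_flow_ucal_s, injections,
                       baseline_model = c("constant", "linear", "none")) {
  baseline_model <- match.arg(baseline_model)
  check_numeric(times_s, "times_s")
  check_numeric(heat_flow_ucal_s, "heat_flow_ucal_s")
  if (length(times_s) != length(heat_flow_ucal_s)) {
    stopf("time and heat-flow vectors differ in length")
  }
  if (any(diff(times_s) <= 0)) stopf("'times_s' must be strictly increasing")
  stopifnot(is.data.frame(injections),
            all(c("time_s", "n_mol") %in% names(injections)))
  if (nrow(injections) > 0L) {
    check_numeric(injections$n_mol, "n_mol", positive = TRUE)
  }
  structure(list(times_s = times_s, heat_flow_ucal_s = heat_flow_ucal_s,
                 injections = injections[order(injections$time_s), ,
                                         drop = FALSE],
                 baseline_model = baseline_model),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %d samples over %.4g s, %d injection(s), %s baseline\n",
              length(x$times_s), diff(range(x$times_s)),
              nrow(x$injections), x$baseline_model))
  invisible(x)
}

#' Integrate an ITC thermogram to heats per injection
#'
#' Estimates and subtracts the instrument baseline, then integrates the
#' residual heat flow over each injection window by the trapezoidal rule.
#' Heats are converted from microcalories to joules at 4.184 J/cal.
#'
#' The constant baseline is the median heat flow before the first
#' injection; if no pre-injection samples exist it falls back to 0 with a
#' warning. The linear baseline is a least-squares line through all
#' samples outside the injection windows.
#'
#' @param tg a [thermogram()].
#' @return list with `per_injection_J` (one heat per injection, J),
#'   `total_J`, and the `baseline` used (microcal/s, per sample).
#' @examples
#' tg <- gen_thermogram(seq(0, 600, 0.5), baseline = 0,
#'                      pulses = data.frame(t_start = 60, duration = 120,
#'                                          amplitude = -5),
#'                      n_mol = 2e-7, injection_times = 60)
#' integrate_thermogram(tg)$total_J  # -2.5104e-3
#' @export
integrate_thermogram <- function(tg) {
  stopifnot(inherits(tg, "thermogram"))
  t <- tg$times_s; y <- tg$heat_flow_ucal_s
  if (length(t) < 3L) stopf("need at least 3 samples")
  inj <- tg$injections
  if (nrow(inj) == 0L) stopf("thermogram has no injections to integrate")
  win_start <- inj$time_s
  win_end <- c(inj$time_s[-1], max(t))
  in_window <- rep(FALSE, length(t))
  for (i in seq_along(win_start)) {
    in_window <- in_window | (t >= win_start[i] & t <= win_end[i])
  }
  base <- switch(tg$baseline_model,
    none = rep(0, length(t)),
    constant = {
      pre <- y[t < min(win_start)]
      if (length(pre) == 0L) {
        warnf("no pre-injection samples; baseline taken as 0")
        rep(0, length(t))
      } else rep(stats::median(pre), length(t))
    },
    linear = {
      out <- !in_window
      if (sum(out) < 2L) stopf("baseline fit degenerate: %s",
                               "fewer than 2 samples outside windows")
      cf <- stats::coef(stats::lm(y[out] ~ t[out]))
      unname(cf[1] + cf[2] * t)
    })
  resid <- y - base
  per <- vapply(seq_along(win_start), function(i) {
    sel <- t >= win_start[i] & t <= win_end[i]
    if (sum(sel) < 2L) {
      warnf("injection %d window holds < 2 samples; heat taken as 0", i)
      return(0)
    }
    trapz(t[sel], resid[sel]) * 1e-6 * .J_PER_CAL
  }, numeric(1))
  list(per_injection_J = per, total_J = sum(per), baseline = base)
}

#' Molar enthalpy from integrated heat
#'
#' Normalizes an integrated heat against the amount of protein converted:
#' `dH = Q / n`, reported in kJ/mol.
#'
#' @param Q_J heat, J (per injection or total).
#' @param n_mol protein amount, mol (> 0).
#' @return molar enthalpy, kJ/mol.
#' @examples
#' enthalpy_from_heats(-59.548e-3, 2e-7)  # -297.74
#' @export
enthalpy_from_heats <- function(Q_J, n_mol) {
  check_numeric(Q_J, "Q_J")
  check_scalar(n_mol, "n_mol", positive = TRUE)
  Q_J / n_mol / 1000
}

#' Fibril-elongation equilibrium constant from the critical concentration
#'
#' Under one-dimensional crystallization the concentration of fibril ends
#' is effectively constant, so the elongation equilibrium constant is the
#' reciprocal of the critical concentration: `K_F = 1 / [C]` (standard
#' state 1 M).
#'
#' @param critical_conc_M critical concentration, M (> 0).
#' @return K_F, 1/M.
#' @export
equilibrium_constant <- function(critical_conc_M) {
  check_numeric(critical_conc_M, "critical_conc_M", positive = TRUE)
  1 / critical_conc_M
}

#' Apparent free energy of fibrillization
#'
#' `dG_app = -R T ln K_F = R T ln([C] / 1 M)`, in kJ/mol.
#'
#' @param critical_conc_M critical concentration, M (> 0).
#' @param temperature_K temperature, K (> 0).
#' @return dG_app, kJ/mol.
#' @examples
#' free_energy(7.5e-7, 293.15)  # about -34.37
#' @export
free_energy <- function(critical_conc_M, temperature_K = 293.15) {
  check_numeric(critical_conc_M, "critical_conc_M", positive = TRUE)
  check_scalar(temperature_K, "temperature_K", positive = TRUE)
  .R_GAS * temperature_K * log(critical_conc_M) / 1000
}

#' Entropy of fibrillization via Gibbs-Helmholtz
#'
#' `dS = (dH - dG) / T`, in kJ/mol/K.
#'
#' @param dH_kJ_mol enthalpy, kJ/mol.
#' @param dG_kJ_mol free energy, kJ/mol.
#' @param temperature_K temperature, K (> 0).
#' @return dS, kJ/mol/K.
#' @examples
#' entropy_gibbs_helmholtz(-297.74, -34.36, 293.15)  # about -0.898
#' @export
entropy_gibbs_helmholtz <- function(dH_kJ_mol, dG_kJ_mol, temperature_K) {
  check_scalar(dH_kJ_mol, "dH_kJ_mol")
  check_scalar(dG_kJ_mol, "dG_kJ_mol")
  check_scalar(temperature_K, "temperature_K", positive = TRUE)
  (dH_kJ_mol - dG_kJ_mol) / temperature_K
}

#' Two-phase heat-capacity fit of dH(T)
#'
#' The temperature derivative of the molar enthalpy at constant pressure is
#' the heat-capacity change; when dH(T) shows two linear phases around a
#' breakpoint, independent least-squares lines on each side give the two
#' dCp branches.
#'
#' @param table data frame with columns `T_K` and `dH_kJ_mol`.
#' @param breakpoint breakpoint temperature in K, or `"auto"` to choose the
#'   interior candidate minimizing total residual sum of squares. Default
#'   310.15 K (37 C).
#' @return list with `dCp_low` and `dCp_high` (slopes, kJ/mol/K; NA when a
#'   branch has fewer than 2 points), the `breakpoint` used, per-branch
#'   intercepts and residual sum of squares.
#' @examples
#' tab <- gen_dH_table(seq(293.15, 333.15, 5), breakpoint = 310.15,
#'                     slope_low = 113.84, slope_high = -373.51)
#' heat_capacity_fit(tab)
#' @export
heat_capacity_fit <- function(table, breakpoint = 310.15) {
  stopifnot(is.data.frame(table),
            all(c("T_K", "dH_kJ_mol") %in% names(table)))
  temps <- table$T_K; dh <- table$dH_kJ_mol
  check_numeric(temps, "T_K"); check_numeric(dh, "dH_kJ_mol")
  if (length(unique(temps)) < 2L) stopf("all temperatures identical")
  branch_fit <- function(sel) {
    if (sum(sel) < 2L) return(list(slope = NA_real_, intercept = NA_real_,
                                   rss = 0))
    cf <- stats::coef(fit <- stats::lm(dh[sel] ~ temps[sel]))
    list(slope = unname(cf[2]), intercept = unname(cf[1]),
         rss = sum(stats::resid(fit)^2))
  }
  fit_at <- function(bp) {
    lo <- branch_fit(temps <= bp)
    hi <- branch_fit(temps >= bp)
    list(lo = lo, hi = hi, rss = lo$rss + hi$rss)
  }
  if (identical(breakpoint, "auto")) {
    cand <- sort(unique(temps))
    cand <- cand[cand > min(temps) & cand < max(temps)]
    if (length(cand) == 0L) stopf("no interior breakpoint candidates")
    rss <- vapply(cand, function(b) fit_at(b)$rss, numeric(1))
    breakpoint <- cand[which.min(rss)]
  }
  check_scalar(breakpoint, "breakpoint")
  res <- fit_at(breakpoint)
  if (is.na(res$lo$slope) || is.na(res$hi$slope)) {
    warnf("only one branch has >= 2 points; single-phase fit")
  }
  list(dCp_low = res$lo$slope, dCp_high = res$hi$slope,
       breakpoint = breakpoint,
       intercept_low = res$lo$intercept, intercept_high = res$hi$intercept,
       rss = res$rss)
}

#' Thermodynamic state of fibrillization
#'
#' Assembles the full parameter set of the elongation equilibrium —
#' critical concentration, K_F, dG_app, dH, dS and the two dCp branches —
#' and verifies the internal identities `dG = R T ln [C]` and
#' `dG = dH - T dS` when enough fields are supplied.
#'
#' @param critical_conc_M critical concentration, M.
#' @param dH_kJ_mol molar enthalpy, kJ/mol (optional).
#' @param temperature_K temperature for the dG / dS chain, K.
#' @param dCp_low,dCp_high heat-capacity branches, kJ/mol/K (optional).
#' @return an object of class `thermo_params` with fields
#'   `critical_conc_M`, `K_F`, `dG_app`, `dH`, `dS`, `dCp_low`,
#'   `dCp_high`, `temperature_K`.
#' @examples
#' thermo_params(7.5e-7, dH_kJ_mol = -297.74)
#' @export
thermo_params <- function(critical_conc_M, dH_kJ_mol = NA_real_,
                          temperature_K = 293.15,
                          dCp_low = NA_real_, dCp_high = NA_real_) {
  check_scalar(critical_conc_M, "critical_conc_M", positive = TRUE)
  check_scalar(temperature_K, "temperature_K", positive = TRUE)
  dG <- free_energy(critical_conc_M, temperature_K)
  dS <- if (is.na(dH_kJ_mol)) NA_real_ else
    entropy_gibbs_helmholtz(dH_kJ_mol, dG, temperature_K)
  out <- structure(list(critical_conc_M = critical_conc_M,
                        K_F = equilibrium_constant(critical_conc_M),
                        dG_app = dG, dH = dH_kJ_mol, dS = dS,
                        dCp_low = dCp_low, dCp_high = dCp_high,
                        temperature_K = temperature_K),
                   class = "thermo_params")
  validate_thermo_params(out)
}

#' @rdname thermo_params
#' @param x a `thermo_params` object.
#' @export
validate_thermo_params <- function(x) {
  stopifnot(inherits(x, "thermo_params"))
  dG_from_cc <- .R_GAS * x$temperature_K * log(x$critical_conc_M) / 1000
  if (abs(x$dG_app - dG_from_cc) > 1e-6) {
    stopf("thermo_params identity violated: dG_app != RT ln [C]")
  }
  if (!is.na(x$dH) && !is.na(x$dS)) {
    if (abs(x$dG_app - (x$dH - x$temperature_K * x$dS)) > 1e-6) {
      stopf("thermo_params identity violated: dG_app != dH - T dS")
    }
  }
  x
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("<thermo_params>\n")
  cat(sprintf("  [C]      = %.4g M      K_F = %.4g 1/M\n",
              x$critical_conc_M, x$K_F))
  cat(sprintf("  dG_app   = %.2f kJ/mol at T = %.2f K\n",
              x$dG_app, x$temperature_K))
  if (!is.na(x$dH)) cat(sprintf("  dH       = %.2f kJ/mol\n", x$dH))
  if (!is.na(x$dS)) cat(sprintf("  dS       = %.4g kJ/mol/K\n", x$dS))
  if (!is.na(x$dCp_low) || !is.na(x$dCp_high)) {
    cat(sprintf("  dCp      = %.4g / %.4g kJ/mol/K (low/high branch)\n",
                x$dCp_low, x$dCp_high))
  }
  invisible(x)
}

#' Stochastic simulation of reversible fibril elongation
#'
#' Gillespie simulation of the one-dimensional crystallization scheme
#' `C + F_(i-1) <-> F_i`: single units add to a fixed number of fibril
#' ends at rate `k_ass [C]` per end and dissociate at rate `k_diss` per
#' end. Concentrations are represented as copy numbers in an explicit
#' volume. At equilibrium, detailed balance gives a free-unit
#' concentration of `k_diss / k_ass = 1 / K_F`, independent of the number
#' of fibrils — the stochastic counterpart of the critical concentration.
#'
#' @param k_ass association rate constant, 1/(M s) (> 0).
#' @param k_diss dissociation rate constant, 1/s (>= 0).
#' @param n_fibrils number of growing fibril ends (>= 1).
#' @param c0 initial free-unit concentration, M.
#' @param volume_L simulation volume, L; sets the copy-number scale
#'   (`c0 * N_A * volume_L` initial free units).
#' @param t_end simulated time, s.
#' @param equil_window fraction of `t_end` (from the end) used as the
#'   late, assumed-equilibrated window.
#' @param init_length initial units per fibril (keeps ends active under
#'   downward fluctuations).
#' @param seed integer RNG seed.
#' @return list with `conc_eq_M` (time-averaged late-window free-unit
#'   concentration), `se_M` (batch-means standard error, 8 batches),
#'   `trajectory` (data frame `time_s`, `free_units`, `conc_M`), and the
#'   inputs.
#' @examples
#' sim <- simulate_1d_crystallization(1e6, 0.75, c0 = 2e-6,
#'                                    volume_L = 5e-16, t_end = 150,
#'                                    seed = 1)
#' @export
simulate_1d_crystallization <- function(k_ass, k_diss, n_fibrils = 50,
                                        c0 = 2e-6, volume_L = 2e-15,
                                        t_end = 600, equil_window = 2 / 3,
                                        init_length = 50, seed = NULL) {
  check_scalar(k_ass, "k_ass", positive = TRUE)
  check_scalar(k_diss, "k_diss", nonnegative = TRUE)
  n_fibrils <- as.integer(n_fibrils)
  if (n_fibrils < 1L) stopf("'n_fibrils' must be >= 1")
  check_scalar(c0, "c0", positive = TRUE)
  check_scalar(volume_L, "volume_L", positive = TRUE)
  check_scalar(t_end, "t_end", positive = TRUE)
  nav <- .AVOGADRO * volume_L            # copies per molar
  c_units <- round(c0 * nav)
  if (c_units < 10) stopf("volume too small: < 10 free units at c0")
  k_ass_n <- k_ass / nav                 # per-copy association propensity
  lengths <- rep(init_length, n_fibrils)
  with_seed(seed, {
    t_now <- 0
    # trajectory recorded on a fixed grid by piecewise-constant sampling
    rec_t <- seq(0, t_end, length.out = 501L)
    rec_c <- rep(NA_real_, length(rec_t)); rec_i <- 1L
    t_eq <- (1 - equil_window) * t_end
    area <- 0                            # integral of C dt over [t_eq, t_end]
    nb <- 8L
    batch_edges <- seq(t_eq, t_end, length.out = nb + 1L)
    batch_area <- rep(0, nb)
    repeat {
      a_ass <- k_ass_n * c_units * n_fibrils
      a_diss <- k_diss * sum(lengths > 0L)
      a_tot <- a_ass + a_diss
      dt <- if (a_tot > 0) stats::rexp(1, a_tot) else Inf
      t_next <- min(t_now + dt, t_end)
      while (rec_i <= length(rec_t) && rec_t[rec_i] <= t_next) {
        rec_c[rec_i] <- c_units; rec_i <- rec_i + 1L
      }
      # accumulate time-weighted free-unit count in the late window
      lo <- max(t_now, t_eq); hi <- min(t_next, t_end)
      if (hi > lo) {
        area <- area + c_units * (hi - lo)
        b1 <- findInterval(lo, batch_edges, rightmost.closed = TRUE)
        b2 <- findInterval(hi, batch_edges, rightmost.closed = TRUE)
        for (b in b1:b2) {
          s <- max(lo, batch_edges[b]); e <- min(hi, batch_edges[b + 1L])
          if (e > s) batch_area[b] <- batch_area[b] + c_units * (e - s)
        }
      }
      if (t_next >= t_end || !is.finite(dt)) break
      t_now <- t_next
      if (stats::runif(1) * a_tot < a_ass) {
        idx <- sample.int(n_fibrils, 1L)
        lengths[idx] <- lengths[idx] + 1L
        c_units <- c_units - 1L
      } else {
        grow <- which(lengths > 0L)
        idx <- grow[sample.int(length(grow), 1L)]
        lengths[idx] <- lengths[idx] - 1L
        c_units <- c_units + 1L
      }
      if (c_units == 0L && a_diss == 0) break
    }
    batch_means <- batch_area / diff(batch_edges) / nav
    conc_eq <- area / (t_end - t_eq) / nav
    se <- stats::sd(batch_means) / sqrt(nb)
    list(conc_eq_M = conc_eq, se_M = se,
         trajectory = data.frame(time_s = rec_t, free_units = rec_c,
                                 conc_M = rec_c / nav),
         k_ass = k_ass, k_diss = k_diss, n_fibrils = n_fibrils,
         volume_L = volume_L, fibril_lengths = lengths)
  })
}
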