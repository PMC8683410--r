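# Equilibrium SPR analysis: double referencing, plateau extraction, Hill
# fitting and the cooperative-vs-hyperbolic model comparison.

#' Equilibrium binding isotherm
#'
#' @param conc_M analyte concentrations, M, strictly increasing, > 0.
#' @param response_RU equilibrium responses, RU, same length.
#' @param ligand,analyte optional labels.
#' @return an object of class `binding_isotherm`.
#' @export
binding_isotherm <- function(conc_M, response_RU, ligand = NA_character_,
                             analyte = NA_character_) {
  check_numeric(conc_M, "conc_M", positive = TRUE)
  check_numeric(response_RU, "response_RU")
  if (length(conc_M) != length(response_RU)) {
    stopf("'conc_M' and 'response_RU' lengths differ")
  }
  if (any(diff(conc_M) <= 0)) stopf("'conc_M' must be strictly increasing")
  structure(list(conc_M = conc_M, response_RU = response_RU,
                 ligand = ligand, analyte = analyte),
            class = "binding_isotherm")
}

#' @export
print.binding_isotherm <- function(x, ...) {
  cat(sprintf("<binding_isotherm> %d concentrations in [%.3g, %.3g] M\n",
              length(x$conc_M), min(x$conc_M), max(x$conc_M)))
  invisible(x)
}

#' Double-reference a sensorgram
#'
#' Standard SPR correction: subtract the reference flow cell from the
#' active cell and subtract the same difference recorded in a buffer-only
#' cycle: `(active - reference) - (buffer_active - buffer_reference)`.
#'
#' @param active,reference,buffer_active,buffer_reference RU traces of
#'   equal length.
#' @return corrected RU trace.
#' @examples
#' double_reference(10, 2, 3, 1)  # 6
#' @export
double_reference <- function(active, reference, buffer_active,
                             buffer_reference) {
  check_numeric(active, "active"); check_numeric(reference, "reference")
  check_numeric(buffer_active, "buffer_active")
  check_numeric(buffer_reference, "buffer_reference")
  n <- length(active)
  if (length(reference) != n || length(buffer_active) != n ||
      length(buffer_reference) != n) {
    stopf("all four traces must have equal length")
  }
  (active - reference) - (buffer_active - buffer_reference)
}

#' Extract the equilibrium response from a corrected sensorgram
#'
#' Takes the median response over the trailing `window` fraction of the
#' trace and checks that the trace has actually plateaued there: the
#' least-squares slope over the window, projected over the window span,
#' must stay below `slope_tol` times the response scale.
#'
#' @param times_s time grid, s.
#' @param response_RU corrected response trace, RU.
#' @param window trailing fraction used (default 0.1).
#' @param slope_tol relative drift tolerance for the plateau check.
#' @return list with `R_eq_RU`, `equilibrated` (logical) and `drift_RU`
#'   (projected change over the window).
#' @export
extract_equilibrium <- function(times_s, response_RU, window = 0.1,
                                slope_tol = 0.02) {
  check_numeric(times_s, "times_s"); check_numeric(response_RU, "response_RU")
  if (length(times_s) != length(response_RU)) stopf("length mismatch")
  check_scalar(window, "window", positive = TRUE)
  t0 <- max(times_s) - window * diff(range(times_s))
  sel <- times_s >= t0
  if (sum(sel) < 3L) stopf("equilibrium window holds fewer than 3 samples")
  tw <- times_s[sel]; rw <- response_RU[sel]
  r_eq <- stats::median(rw)
  slope <- stats::coef(stats::lm(rw ~ tw))[2]
  drift <- unname(slope) * diff(range(tw))
  scale <- max(abs(r_eq), diff(range(response_RU)), .Machine$double.eps)
  list(R_eq_RU = r_eq, equilibrated = abs(drift) <= slope_tol * scale,
       drift_RU = drift)
}

#' Fit the Hill equation to an equilibrium isotherm
#'
#' Least-squares fit of `R = R_max c^n / (K_D^n + c^n)`, parameterized in
#' `log K_D` for conditioning (the model is
#' `R_max / (1 + exp(n (log K_D - log c)))`). Standard errors come from
#' the fit covariance. With `fix_n = 1` the fit reduces to the hyperbolic
#' (Langmuir) isotherm.
#'
#' @param iso a [binding_isotherm()] (or data frame with `conc_M`,
#'   `response_RU`).
#' @param fix_n optional fixed Hill coefficient (commonly 1).
#' @return an object of class `hill_fit` with `K_D_M`, `n`, `R_max_RU`,
#'   standard errors (`K_D_se_M`, `n_se`, `R_max_se_RU`), `rss`, residual
#'   `df`, and `verdict` (`"untested"` until [compare_cooperativity()]).
#' @examples
#' iso <- gen_isotherm(31e-9, 2.4, 100)
#' fit_hill(iso)
#' @export
fit_hill <- function(iso, fix_n = NULL) {
  if (is.data.frame(iso)) iso <- binding_isotherm(iso$conc_M, iso$response_RU)
  stopifnot(inherits(iso, "binding_isotherm"))
  conc <- iso$conc_M; resp <- iso$response_RU
  if (length(conc) < 4L) stopf("need at least 4 concentration points")
  if (max(conc) / min(conc) < 10) {
    warnf("concentrations span less than one decade; fit may be %s",
          "ill-conditioned")
  }
  lc <- log(conc)
  rmax0 <- max(resp) * 1.05
  lkd0 <- lc[which.min(abs(resp - rmax0 / 2))]
  dat <- data.frame(lc = lc, resp = resp)
  fit <- tryCatch({
    if (is.null(fix_n)) {
      minpack.lm::nlsLM(resp ~ rmax / (1 + exp(nh * (lkd - lc))),
                        data = dat,
                        start = list(rmax = rmax0, lkd = lkd0, nh = 1),
                        lower = c(0, min(lc) - 20, 1e-3),
                        upper = c(Inf, max(lc) + 20, 20),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      check_scalar(fix_n, "fix_n", positive = TRUE)
      nh_fixed <- fix_n
      minpack.lm::nlsLM(resp ~ rmax / (1 + exp(nh_fixed * (lkd - lc))),
                        data = dat,
                        start = list(rmax = rmax0, lkd = lkd0),
                        lower = c(0, min(lc) - 20),
                        upper = c(Inf, max(lc) + 20),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) {
    stopf("Hill fit failed to converge: %s (try rescaling responses %s)",
          conditionMessage(e), "or widening the concentration range")
  })
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, length(cf)))
  kd <- exp(unname(cf["lkd"]))
  n_hat <- if (is.null(fix_n)) unname(cf["nh"]) else fix_n
  n_se <- if (is.null(fix_n)) unname(se["nh"]) else 0
  structure(list(K_D_M = kd, n = n_hat, R_max_RU = unname(cf["rmax"]),
                 K_D_se_M = kd * unname(se["lkd"]), n_se = n_se,
                 R_max_se_RU = unname(se["rmax"]),
                 rss = sum(stats::resid(fit)^2),
                 df = length(resp) - length(cf),
                 n_fixed = !is.null(fix_n),
                 verdict = "untested", comparison = NULL,
                 ligand = iso$ligand, analyte = iso$analyte),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> K_D = %.4g M, n = %.3g%s, R_max = %.4g RU\n",
              x$K_D_M, x$n, if (x$n_fixed) " (fixed)" else "",
              x$R_max_RU))
  if (!identical(x$verdict, "untested")) {
    cat(sprintf("  cooperativity verdict: %s", x$verdict))
    if (!is.null(x$comparison)) {
      cat(sprintf(" (F = %.3g, p = %.3g)", x$comparison$F,
                  x$comparison$p))
    }
    cat("\n")
  }
  invisible(x)
}

#' Predicted Hill response
#'
#' @param fit a `hill_fit`.
#' @param conc_M concentrations, M.
#' @return predicted responses, RU.
#' @export
predict_hill <- function(fit, conc_M) {
  stopifnot(inherits(fit, "hill_fit"))
  check_numeric(conc_M, "conc_M", positive = TRUE)
  fit$R_max_RU * conc_M^fit$n / (fit$K_D_M^fit$n + conc_M^fit$n)
}

#' Test an isotherm for cooperative binding
#'
#' Nested model comparison between the hyperbolic fit (`n = 1`) and the
#' free-n Hill fit by the extra-sum-of-squares F-test. The verdict is
#' `"cooperative"` only when the free-n model is preferred at level
#' `alpha` and the fitted `n > 1`; `"noncooperative"` when the free-n
#' model is not preferred; `"indeterminate"` when residual variance is
#' (numerically) zero — noise-free data cannot support an F-test — or when
#' the preferred fit has `n <= 1`. AIC values for both fits are reported
#' alongside.
#'
#' @param iso a [binding_isotherm()].
#' @param alpha significance level of the F-test (default 0.05).
#' @return the free-n `hill_fit` with `verdict` set and a `comparison`
#'   record (`F`, `p`, `rss0`, `rss1`, `aic0`, `aic1`).
#' @export
compare_cooperativity <- function(iso, alpha = 0.05) {
  check_scalar(alpha, "alpha", positive = TRUE)
  fit1 <- fit_hill(iso)
  fit0 <- fit_hill(iso, fix_n = 1)
  n_obs <- length(iso$conc_M)
  aic <- function(rss, k) n_obs * log(rss / n_obs) + 2 * k
  scale2 <- sum(iso$response_RU^2)
  if (fit1$rss <= 1e-12 * max(scale2, 1) || fit1$df <= 0) {
    fit1$verdict <- "indeterminate"
    fit1$comparison <- list(F = NA_real_, p = NA_real_,
                            rss0 = fit0$rss, rss1 = fit1$rss,
                            aic0 = NA_real_, aic1 = NA_real_)
    return(fit1)
  }
  Fstat <- (fit0$rss - fit1$rss) / 1 / (fit1$rss / fit1$df)
  p <- stats::pf(Fstat, 1, fit1$df, lower.tail = FALSE)
  preferred <- is.finite(p) && p < alpha
  fit1$verdict <- if (!preferred) "noncooperative"
                  else if (fit1$n > 1) "cooperative"
                  else "indeterminate"
  fit1$comparison <- list(F = Fstat, p = p, rss0 = fit0$rss,
                          rss1 = fit1$rss, aic0 = aic(fit0$rss, 3),
                          aic1 = aic(fit1$rss, 4))
  fit1
}

#' Reference binding constants for the DISC1 C-region interactions
#'
#' Dissociation constants and Hill coefficients for the nanobody VHH B5,
#' NDEL1 and LIS1 binding the monomeric and the two oligomeric/fibrillar
#' C-region preparations, as determined by equilibrium SPR. Used as
#' ground-truth parameter sets for synthetic recovery benchmarks.
#'
#' @return data frame with columns `analyte`, `preparation`, `K_D_M`, `n`.
#' @export
hill_reference_table <- function() {
  data.frame(
    analyte = rep(c("VHH_B5", "NDEL1", "LIS1"), each = 3),
    preparation = rep(c("monomer_MBP", "oligomer_His", "oligomer_MBP"), 3),
    K_D_M = c(46e-9, 66e-9, 70e-9,
              20e-6, 13e-6, 14e-6,
              71e-9, 31e-9, 31e-9),
    n = c(1.4, 1.1, 1.1,
          1.4, 2.1, 2.5,
          1.2, 2.4, 2.8))
}
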