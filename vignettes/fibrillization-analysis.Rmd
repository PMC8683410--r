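---
title: "Fibrillization thermodynamics and biophysical analysis with fibriltherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fibrillization thermodynamics and biophysical analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibriltherm)
```

## Scope and model

fibriltherm analyses the self-association of an aggregating protein — the
motivating system is the C-region of DISC1 (residues 691–836), which forms
tetramers and elongates into amyloid-like fibrils — through the
one-dimensional crystallization model of fibril growth. Elongation is a
reversible addition of a single free unit `C` (monomer or small oligomer)
to a fibril end:

$$C + F_{i-1} \rightleftharpoons F_i,
\qquad K_F = \frac{k_\mathrm{ass}}{k_\mathrm{diss}}$$

Late in aggregation the number of growing fibrils is approximately
constant, so the concentration of docking sites drops out and the
elongation equilibrium constant reduces to the reciprocal of the *critical
concentration* `[C]`, the free-unit concentration in equilibrium with the
fibril suspension. The thermodynamic chain follows:

$$\Delta G_\mathrm{app} = -RT\ln K_F = RT\ln [C], \qquad
\Delta S = \frac{\Delta H - \Delta G_\mathrm{app}}{T}, \qquad
\Delta C_p = \left(\frac{\partial \Delta H}{\partial T}\right)_p$$

with `ΔH` measured calorimetrically. Each link of the chain is a separate
function (`estimate_critical_concentration`, `free_energy`,
`enthalpy_from_heats`, `entropy_gibbs_helmholtz`, `heat_capacity_fit`) so
intermediate quantities stay inspectable, and `thermo_params` re-validates
the cross-identities (`ΔG = RT ln [C]`, `ΔG = ΔH − TΔS`) every time a
report is assembled.

```{r chain}
tp <- thermo_params(7.5e-7, dH_kJ_mol = -297.74, temperature_K = 293.15)
tp
```

### Choice of temperature

The free-energy/entropy chain defaults to `temperature_K = 293.15` (20 °C,
the temperature at which long fibrils grow and the critical concentration
is observable by DLS), while the calorimetric enthalpy is typically
measured at 37 °C. Mixing temperatures across the chain is a physical
approximation the user controls: `temperature_K` is an explicit argument
of every function involved, and the report records the value used. The
standard state for `K_F` is 1 M.

### Stochastic verification

`simulate_1d_crystallization` is a Gillespie simulation of the same
scheme: `n_fibrils` ends gain units with propensity
`k_ass [C]` per end and lose them with propensity `k_diss` per end,
with concentrations represented as copy numbers in an explicit volume. By
detailed balance the free-unit concentration relaxes to
`k_diss/k_ass = 1/K_F` regardless of fibril count — the defaults
(50 fibrils, 2 fL, 600 s, two-thirds of the run used as the equilibrated
window) give roughly 900 free units at equilibrium and a batch-means
standard error under 1%, which the test suite compares against `1/K_F`
within three standard errors. The volume is a numerical knob, not a
physical claim: accuracy improves as the volume (copy number) grows, which
the tests check at two volumes.

## DLS inversion and sizing

The intensity autocorrelation of a mixture of diffusing species follows
the Siegert relation

$$g_2(\tau) - 1 = \beta\left(\sum_i f_i e^{-\Gamma_i\tau}\right)^2,
\qquad \Gamma_i = D_i q^2$$

with coherence factor `β`, intensity fractions `f_i` and scattering vector
`q = (4\pi n/\lambda)\sin(\theta/2)`. `fit_correlogram` fits 1–3
exponential components by Levenberg–Marquardt least squares; decay rates
are parameterized on the log scale and bounded to the dynamic range the
lag window can resolve, fractions as squared weights renormalized to sum
to one. Two initializations are tried — rates log-spaced across the lag
window, and rates bracketing the lag at which the trace falls to
`β e^{-2}` — and the lower-residual solution kept; this avoids the local
minimum in which one component collapses onto the noise floor. A trace
whose final value exceeds 90% of its initial value is rejected as
non-decaying. Regularized inversion (CONTIN-style) is deliberately out of
scope at 1–3 components.

Radii follow from Stokes–Einstein, `R_H = k_B T/(6\pi\eta D)`. Instrument
defaults (`λ = 660` nm, `θ = 90°`, `n = 1.33`, water viscosity from an
embedded 283–353 K table, `β = 0.9`) describe a typical cuvette
instrument and are all overridable — the coherence factor in particular is
instrument-specific and unreported in most studies.

Because DLS instruments report molecular masses through an undocumented
internal relation, the package ships the observed (R_H, M) pairs of the
DISC1 C-region oligomer series (`dls_mass_pairs`) and fits a power law
`M = a R_H^b` to them (`calibrate_mass`). The calibration is data, not
physics: users with their own standards should supply their own pairs.
Extrapolation below the smallest training radius (e.g. to a monomer at
2.28 nm) is correspondingly soft, which the tests acknowledge with a
wider tolerance there.

The critical concentration is read off a detection-limit dilution series
as the lowest concentration at which the free species is still detected;
the result is flagged `interior` only when undetected lower
concentrations bracket it, otherwise `lower_bound`. The detection
protocol itself (how a "detected" flag is assigned) is the instrument
operator's convention.

## ITC integration

`integrate_thermogram` estimates the instrument baseline — by default a
constant taken as the median of the pre-injection samples; alternatively a
line fitted to all samples outside the injection windows — subtracts it,
and integrates the residual heat flow trapezoidally over each injection
window (injection time to next injection, or end of trace). Heats convert
at exactly 4.184 J/cal and normalize to kJ/mol by the protein amount. On
a sampled rectangular pulse the trapezoidal rule is exact provided the
window covers both pulse edges, which is why the synthetic fixtures place
the injection marker ahead of the first pulse.

The heat-capacity branches come from independent least-squares lines on
either side of a breakpoint (default 310.15 K; points at the breakpoint
belong to both branches, which is exact for continuous piecewise-linear
input). `breakpoint = "auto"` scans the interior grid points and keeps
the split minimizing the total residual sum of squares. A branch with
fewer than two points degrades to a single-phase fit with a warning.

## Water-edited build-up and hydration

Magnetization transferred from surface water into the fibril grows with
the proton–proton mixing time; the initial, approximately linear part of
the normalized build-up defines the build-up time `t_m^s` (the time at
which the zero-intercept initial-slope line reaches 100% transfer).
`fit_initial_slope` uses a zero-intercept least-squares line over the
points with normalized intensity at or below `window = 0.5`; both the
zero intercept and the window are package conventions (configurable),
since initial-slope protocols rarely state them. On curves that are
truly exponential rather than linear-capped, the window introduces a
downward bias that stays within about 12% at `window = 0.2`, which the
test suite measures by construction.

The hydration geometry chain is closed-form:
`V/S = sqrt(D_eff t_m^s / π)` with `D_eff = 0.2` nm²/ms (the accepted
effective spin-diffusion coefficient; overridable), and `d = 4 V/S` for a
long cylinder. The cylinder assumption is applied untested and recorded
in the result (`shape = "cylinder"`); for non-fibrillar morphologies the
diameter is not meaningful. `hydration_analysis` asserts both identities
to 1e−9 on every result it constructs.

`integrate_roi` supports region-of-interest integration of 2D spectral
matrices (cell-area-scaled sums, optional per-scan normalization);
spectral processing itself (FT, phasing, peak picking) is out of scope.

## Chemical-shift secondary structure

`classify_sse` assigns helix/strand/coil by nearest reference in
(CA, CB) ppm space (CA only where CB does not exist, e.g. glycine). The
shipped reference table (`sse_shift_reference`) is built from published
random-coil shift compilations with the canonical helix/strand secondary
shift offsets (CA +2.6/−1.4 ppm, CB −0.4/+1.9 ppm) applied; it is a
coarse classification aid, not a shift predictor, and users can pass
their own table. Exact ties resolve to coil — the least-committal class —
and are flagged.

## SPR binding and cooperativity

After double referencing
(`(active − reference) − (buffer_active − buffer_reference)`) and plateau
extraction (median of the trailing window, with a drift check),
equilibrium responses are fitted with the Hill equation. The fit is
unweighted least squares in a log-`K_D` parameterization,
`R = R_\max / (1 + e^{\,n(\ln K_D - \ln c)})`, which conditions the
problem well on log-spaced concentration grids and keeps `K_D` positive
without constraints on the original scale.

Cooperativity is decided by a nested comparison: the hyperbolic `n = 1`
fit against the free-`n` fit via the extra-sum-of-squares F-test at
`alpha = 0.05` (AIC reported alongside). The verdict is `cooperative`
only when the free-`n` model is preferred *and* the fitted `n > 1`;
noise-free data have (numerically) zero residual variance and return
`indeterminate` rather than a spurious verdict.

Synthetic recovery benchmarks use 12 log-spaced concentrations on
`[0.1 K_D, 10 K_D]`. This grid is chosen for identifiability: a titration
far above `K_D` saturates the site and cannot pin down `n`, so recovery
is benchmarked on a grid that brackets the transition. The reference
parameter sets (`hill_reference_table`) cover a nanobody (VHH B5), NDEL1
and LIS1 binding the monomeric and two oligomeric/fibrillar C-region
preparations; the noisy-recovery suite (σ = 2 RU on `R_max = 100`)
exercises the six Hill-fitted LIS1/NDEL1 interactions, while the nanobody
isotherms — hyperbolic, with `n` near 1 and correspondingly soft `K_D`
identifiability — are benchmarked noiselessly.

## ThT kinetics and CD

ThT time courses are summarized by a four-parameter logistic
`F(t) = F_0 + A/(1 + e^{-k(t - t_{50})})`. The logistic is a descriptive
stand-in, not a mechanistic nucleation–elongation model: it yields
comparable descriptors (amplitude, rate, half-time) without claiming
kinetic interpretation. Derived descriptors are conventions declared
here: the lag time is the tangent construction `t_{50} - 2/k`, the
plateau time the 99% point `t_{50} + \ln(99)/k`. `detect_plateau` is
model-free: the earliest time after which the trace stays within
`tol = 2%` of the dynamic range around the trailing-window median, with a
not-reached flag when the trailing window itself still drifts. Signal
decline after the plateau (seen at low growth temperatures, attributed to
precipitation or plate adhesion) is observational and not modelled.

CD spectra are normalized by the absolute ellipticity at 217 nm (the
β-sheet band), making spectra shape-comparable across concentrations; the
208/222 nm two-point ratio is available as a helicity-change descriptor.
No secondary-structure deconvolution is attempted.

## Synthetic data: what it emulates, and what it does not

Every generator produces the statistical structure its analysis assumes —
Siegert-squared exponential decays, baseline-plus-pulse thermograms,
linear-capped or exponential build-ups, Hill isotherms, logistic ThT
curves, continuous two-phase `ΔH(T)` tables — with additive Gaussian
noise throughout. Gaussian additivity is the simplest model consistent
with unreported instrument error structure; none of the published
measurements state noise magnitudes, so the fixture defaults (e.g.
0.002 on `g2−1`, 0.05 µcal/s, 0.5 RU) are package choices of a plausible
magnitude, fixed once. `noise_sd = 0` bypasses the RNG entirely, so
noiseless output is bit-identical across seeds; seeded generation
restores the caller's RNG state.

Passing round-trip tests therefore demonstrates correctness of the
estimators under the assumed forward models — they do not validate those
models against real instruments, where baselines drift nonlinearly, DLS
noise is correlated across lags, SPR suffers mass-transport limitation
and rebinding, and aggregation produces polydispersity beyond 2–3 discrete
species.

## Problem sizes and determinism

The test and acceptance workloads are sized for interactive use: 120-point
correlograms, 3001-sample thermograms, 8–11-point build-ups, 12-point
isotherms, 100-seed recovery ensembles, and a single 600 s Gillespie run
(~45,000 events); the full suite runs in well under a minute. Pipeline
reports are deterministic for a fixed configuration and seed, and
`write_report` serializes them to byte-identical JSON (fit objects
flattened to their numeric fields, units recorded for every reported
quantity).

## Known limitations

- The critical-concentration estimate inherits the granularity of the
  dilution series; it is a grid value, not an interpolation.
- The mass calibration is system-specific training data; treat masses for
  other proteins as indicative only.
- `t_m^s` from initial slopes is semiquantitative; the diameter inherits
  both the `D_eff` convention and the cylinder assumption.
- The Hill `n` is a phenomenological cooperativity index, not a site
  count; the F-test verdict depends on the stated `alpha` and on noise
  being approximately i.i.d. Gaussian.
- No kinetic (k_on/k_off) SPR analysis, no mechanistic aggregation rate
  laws, no CD deconvolution, no spectral NMR processing.
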