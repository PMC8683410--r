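# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Boltzmann constant [J/K] and gas constant [J/mol/K]
.kB <- 1.380649e-23
.R_GAS <- 8.314
.AVOGADRO <- 6.02214076e23
.J_PER_CAL <- 4.184

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_numeric <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L) {
    stopf("'%s' must be a non-empty numeric vector", name)
  }
  if (finite && any(!is.finite(x))) stopf("'%s' contains non-finite values", name)
  if (positive && any(x <= 0)) stopf("'%s' must be strictly positive", name)
  invisible(x)
}

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("'%s' must be > 0 (got %g)", name, x)
  if (nonnegative && x < 0) stopf("'%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}

check_grid <- function(grid, name = "grid", min_len = 3L) {
  check_numeric(grid, name)
  if (length(grid) < min_len) stopf("'%s' needs at least %d points", name, min_len)
  if (any(diff(grid) <= 0)) stopf("'%s' must be strictly increasing", name)
  invisible(grid)
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
# With seed = NULL the global stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Additive Gaussian noise; noise_sd = 0 never touches the RNG, so noiseless
# output is bit-identical for any seed.
add_noise <- function(x, noise_sd, seed = NULL) {
  check_scalar(noise_sd, "noise_sd", nonnegative = TRUE)
  if (noise_sd == 0) return(x)
  x + with_seed(seed, stats::rnorm(length(x), sd = noise_sd))
}

# Trapezoidal quadrature on an irregular grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
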