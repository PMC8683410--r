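# File input, fixture generation and pipeline orchestration: reads the
# plain-CSV schemas, runs the selected analysis stages in dependency order
# and assembles a unit-annotated report.

# Strict CSV reader: exact header requirements, numeric coercion with row
# diagnostics, explicit rejection of decimal commas.
read_table_checked <- function(path, numeric_cols, logical_cols = character()) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) stopf("empty table: %s", path)
  missing <- setdiff(c(numeric_cols, logical_cols), names(raw))
  if (length(missing) > 0L) {
    stopf("%s: missing column(s) %s", path, paste(missing, collapse = ", "))
  }
  for (col in numeric_cols) {
    v <- raw[[col]]
    if (any(grepl(",", v, fixed = TRUE))) {
      stopf("%s: column '%s' contains commas (decimal-comma locale?); %s",
            path, col, "use '.' as decimal separator")
    }
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !(v %in% c("NA", "")))
    if (length(bad) > 0L) {
      stopf("%s: non-numeric value(s) in '%s' at data row(s) %s",
            path, col, paste(utils::head(bad, 5), collapse = ", "))
    }
    raw[[col]] <- num
  }
  for (col in logical_cols) {
    v <- raw[[col]]
    lg <- v %in% c("1", "TRUE", "true", "T")
    bad <- !(v %in% c("0", "1", "TRUE", "FALSE", "true", "false", "T", "F"))
    if (any(bad)) {
      stopf("%s: column '%s' must be 0/1 or TRUE/FALSE", path, col)
    }
    raw[[col]] <- lg
  }
  raw
}

#' Read instrument tables from CSV
#'
#' Strict readers for the package's plain-CSV schemas. Headers must match
#' exactly, all cells must parse as numbers (decimal point, not comma) and
#' offending rows are reported by number.
#'
#' * `read_correlogram`: columns `lag_s`, `g2m1`.
#' * `read_detection_series`: columns `conc_M`, `detected` (0/1).
#' * `read_thermogram`: columns `time_s`, `heatflow_ucal_per_s`;
#'   injections are passed separately.
#' * `read_dh_table`: columns `T_K`, `dH_kJ_mol`.
#' * `read_buildup`: columns `mixing_ms`, `intensity`.
#' * `read_isotherm`: columns `conc_M`, `response_RU`.
#' * `read_tht`: columns `time_h`, `fluorescence_AU`.
#' * `read_cd`: columns `wavelength_nm`, `ellipticity_mdeg`.
#' * `read_shift_table`: columns `residue`, `atom`, `ppm`.
#'
#' @param path CSV file path.
#' @param instrument a [dls_instrument()] for correlograms.
#' @param injections data frame (`time_s`, `n_mol`) for thermograms.
#' @return the corresponding package object or validated data frame.
#' @name readers
NULL

#' @rdname readers
#' @export
read_correlogram <- function(path, instrument = dls_instrument()) {
  d <- read_table_checked(path, c("lag_s", "g2m1"))
  correlogram_trace(d$lag_s, d$g2m1, instrument)
}

#' @rdname readers
#' @export
read_detection_series <- function(path) {
  read_table_checked(path, "conc_M", logical_cols = "detected")
}

#' @rdname readers
#' @export
read_thermogram <- function(path, injections) {
  d <- read_table_checked(path, c("time_s", "heatflow_ucal_per_s"))
  thermogram(d$time_s, d$heatflow_ucal_per_s, injections)
}

#' @rdname readers
#' @export
read_dh_table <- function(path) {
  read_table_checked(path, c("T_K", "dH_kJ_mol"))
}

#' @rdname readers
#' @export
read_buildup <- function(path) {
  d <- read_table_checked(path, c("mixing_ms", "intensity"))
  buildup_curve(d$mixing_ms, d$intensity)
}

#' @rdname readers
#' @export
read_isotherm <- function(path) {
  d <- read_table_checked(path, c("conc_M", "response_RU"))
  binding_isotherm(d$conc_M, d$response_RU)
}

#' @rdname readers
#' @export
read_tht <- function(path) {
  d <- read_table_checked(path, c("time_h", "fluorescence_AU"))
  tht_trace(d$time_h, d$fluorescence_AU)
}

#' @rdname readers
#' @export
read_cd <- function(path) {
  d <- read_table_checked(path, c("wavelength_nm", "ellipticity_mdeg"))
  cd_spectrum(d$wavelength_nm, d$ellipticity_mdeg)
}

#' @rdname readers
#' @export
read_shift_table <- function(path) {
  d <- read_table_checked(path, "ppm")
  if (!all(c("residue", "atom") %in% names(d))) {
    stopf("%s: missing column(s) residue/atom", path)
  }
  d
}

#' Write a synthetic fixture set
#'
#' Writes one CSV per input class — correlogram, detection series,
#' thermogram, enthalpy-vs-temperature table, build-up curve, one isotherm
#' per reference binding pair, ThT trace and CD spectrum — each with a
#' JSON sidecar recording the ground-truth parameters and seed. The
#' parameter values are the package's embedded reference values
#' (critical concentration 750 nM; total heat -59.548 mJ for 0.2 umol;
#' heat-capacity branches 113.84 / -373.51 kJ/mol/K; build-up time 45 ms;
#' the [hill_reference_table()] binding constants).
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed; noise seeds for individual files are derived
#'   from it.
#' @param noise list of per-class noise standard deviations (in the output
#'   units); the defaults are modest, realistic levels.
#' @return invisibly, a character vector of the files written.
#' @export
make_fixtures <- function(outdir, seed = 1,
                          noise = list(correlogram = 0.002,
                                       thermogram = 0.05,
                                       buildup = 0.005,
                                       isotherm = 0.5,
                                       tht = 2, dH = 1, cd = 0.05)) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory %s", outdir)
  }
  check_scalar(seed, "seed")
  files <- character()
  emit <- function(name, df, truth) {
    csv <- file.path(outdir, paste0(name, ".csv"))
    utils::write.csv(df, csv, row.names = FALSE)
    side <- file.path(outdir, paste0(name, ".truth.json"))
    jsonlite::write_json(truth, side, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <<- c(files, csv, side)
  }

  # DLS: two-species correlogram (tetramer + oligomer) at 37 C
  inst <- dls_instrument(temperature_K = 310.15)
  sp <- data.frame(radius_nm = c(4.1, 17.2), fraction = c(0.5, 0.5))
  tr <- gen_correlogram(sp, instrument = inst,
                        noise_sd = noise$correlogram, seed = seed + 1)
  emit("correlogram", data.frame(lag_s = tr$lags, g2m1 = tr$g2m1),
       list(radius_nm = sp$radius_nm, fraction = sp$fraction,
            temperature_K = inst$temperature_K, beta = inst$beta,
            noise_sd = noise$correlogram, seed = seed + 1))

  # detection-limit dilution series around the 750 nM critical concentration
  conc <- c(1e-7, 2.5e-7, 5e-7, 7.5e-7, 1e-6, 2.5e-6, 5e-6)
  det <- conc >= 7.5e-7
  emit("detection_series",
       data.frame(conc_M = conc, detected = as.integer(det)),
       list(critical_conc_M = 7.5e-7))

  # ITC thermogram: pulses totalling -59.548 mJ for 0.2 umol of protein
  total_ucal <- -59.548e-3 / .J_PER_CAL * 1e6     # -14232.3 ucal
  amps <- total_ucal * c(0.5, 0.3, 0.2) / 120
  pl <- data.frame(t_start = c(150, 600, 1080), duration = 120,
                   amplitude = amps)
  n_mol <- 2e-7
  tg <- gen_thermogram(seq(0, 1500, by = 0.5), baseline = 1.5, pulses = pl,
                       n_mol = n_mol, injection_times = 120,
                       noise_sd = noise$thermogram, seed = seed + 2)
  emit("thermogram",
       data.frame(time_s = tg$times_s,
                  heatflow_ucal_per_s = tg$heat_flow_ucal_s),
       list(total_heat_J = attr(tg, "sim_spec")$params$heat_J,
            n_mol = n_mol,
            dH_kJ_mol = enthalpy_from_heats(
              attr(tg, "sim_spec")$params$heat_J, n_mol),
            injection_time_s = 120, baseline_ucal_s = 1.5,
            noise_sd = noise$thermogram, seed = seed + 2))

  # two-phase dH(T) table
  temps <- c(seq(293.15, 308.15, 5), 310.15, seq(313.15, 333.15, 5))
  dtab <- gen_dH_table(temps, breakpoint = 310.15, slope_low = 113.84,
                       slope_high = -373.51, intercept = -297.74,
                       noise_sd = noise$dH, seed = seed + 3)
  emit("dh_table", dtab,
       list(breakpoint_K = 310.15, dCp_low = 113.84, dCp_high = -373.51,
            noise_sd = noise$dH, seed = seed + 3))

  # water-edited build-up, 45 ms build-up time
  bc <- gen_buildup(45, noise_sd = noise$buildup, seed = seed + 4)
  emit("buildup",
       data.frame(mixing_ms = bc$mixing_ms, intensity = bc$intensity),
       list(t_m_s_ms = 45, D_eff = 0.2,
            diameter_nm = fibril_diameter(volume_to_surface(45, 0.2)),
            noise_sd = noise$buildup, seed = seed + 4))

  # one isotherm per reference (analyte, preparation) pair
  ref <- hill_reference_table()
  for (i in seq_len(nrow(ref))) {
    iso <- gen_isotherm(ref$K_D_M[i], ref$n[i], R_max = 100,
                        noise_sd = noise$isotherm, seed = seed + 10 + i)
    emit(sprintf("isotherm_%s_%s", ref$analyte[i], ref$preparation[i]),
         data.frame(conc_M = iso$conc_M, response_RU = iso$response_RU),
         list(analyte = ref$analyte[i], preparation = ref$preparation[i],
              K_D_M = ref$K_D_M[i], n = ref$n[i], R_max = 100,
              noise_sd = noise$isotherm, seed = seed + 10 + i))
  }

  # ThT kinetics plateauing after ~8 h
  tt <- gen_tht(F0 = 50, A = 1000, k = 1.2, t50 = 4,
                noise_sd = noise$tht, seed = seed + 30)
  emit("tht",
       data.frame(time_h = tt$time_h, fluorescence_AU = tt$fluorescence_AU),
       list(F0 = 50, A = 1000, k = 1.2, t50 = 4,
            noise_sd = noise$tht, seed = seed + 30))

  # CD spectrum
  cs <- gen_cd_spectrum(noise_sd = noise$cd, seed = seed + 31)
  emit("cd",
       data.frame(wavelength_nm = cs$wavelength_nm,
                  ellipticity_mdeg = cs$ellipticity_mdeg),
       list(helix_fraction = 0.5, noise_sd = noise$cd, seed = seed + 31))

  invisible(files)
}

#' Run the full analysis pipeline
#'
#' Executes the analysis stages whose inputs are present in the
#' configuration, in dependency order: DLS correlogram inversion and
#' critical-concentration estimation; ITC integration to molar enthalpy;
#' the free-energy / entropy / heat-capacity chain; build-up hydration
#' analysis; Hill fitting with cooperativity testing per isotherm; ThT
#' kinetics. Missing inputs leave the corresponding report sections NULL;
#' a failing stage is recorded under `errors` and its dependents are
#' skipped.
#'
#' @param config a list with elements
#'   * `inputs`: named file paths — `correlogram`, `detection_series`,
#'     `thermogram`, `dh_table`, `buildup`, `tht`, `cd`, and `isotherms`
#'     (named character vector of paths);
#'   * `params`: overrides — `temperature_K` (default 293.15, for the
#'     dG/dS chain), `itc_n_mol` and `itc_injection_time_s`,
#'     `dls_temperature_K`, `n_components`, `D_eff`, `slope_window`,
#'     `breakpoint_K`, `alpha`, `reference_ms`;
#'   * `seed`: integer recorded in the provenance block.
#' @return an object of class `fibril_report`: a list with sections
#'   `dls`, `thermo`, `hydration`, `binding`, `kinetics`, `units`,
#'   `errors` and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  inputs <- config$inputs %||% list()
  p <- config$params %||% list()
  temperature_K <- p$temperature_K %||% 293.15
  errors <- list()
  fail <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    NULL
  }
  for (nm in setdiff(names(inputs), "isotherms")) {
    if (!is.null(inputs[[nm]]) && !file.exists(inputs[[nm]])) {
      stopf("configured input '%s' does not exist: %s", nm, inputs[[nm]])
    }
  }

  # --- DLS sizing -----------------------------------------------------
  dls_out <- NULL
  if (!is.null(inputs$correlogram)) {
    dls_out <- tryCatch({
      inst <- dls_instrument(
        temperature_K = p$dls_temperature_K %||% 310.15)
      tr <- read_correlogram(inputs$correlogram, inst)
      dist <- fit_correlogram(tr, n_components = p$n_components %||% 2)
      annotate_mass(dist)
    }, error = function(e) fail("dls", e))
  }

  # --- critical concentration ----------------------------------------
  cc <- NULL
  if (!is.null(inputs$detection_series)) {
    cc <- tryCatch(
      estimate_critical_concentration(
        read_detection_series(inputs$detection_series)),
      error = function(e) fail("critical_concentration", e))
  }

  # --- ITC enthalpy ---------------------------------------------------
  dH <- NA_real_
  itc <- NULL
  if (!is.null(inputs$thermogram)) {
    itc <- tryCatch({
      n_mol <- p$itc_n_mol %||%
        stopf("params$itc_n_mol required with a thermogram input")
      inj <- data.frame(time_s = p$itc_injection_time_s %||% 0,
                        n_mol = n_mol)
      tg <- read_thermogram(inputs$thermogram, inj)
      heats <- integrate_thermogram(tg)
      list(total_J = heats$total_J,
           per_injection_J = heats$per_injection_J,
           dH_kJ_mol = enthalpy_from_heats(heats$total_J, sum(inj$n_mol)))
    }, error = function(e) fail("itc", e))
    if (!is.null(itc)) dH <- itc$dH_kJ_mol
  }

  # --- heat capacity --------------------------------------------------
  dcp <- NULL
  if (!is.null(inputs$dh_table)) {
    dcp <- tryCatch(
      heat_capacity_fit(read_dh_table(inputs$dh_table),
                        breakpoint = p$breakpoint_K %||% 310.15),
      error = function(e) fail("heat_capacity", e))
  }

  # --- thermodynamic chain -------------------------------------------
  thermo_out <- NULL
  if (!is.null(cc)) {
    thermo_out <- tryCatch(
      thermo_params(cc$critical_conc_M, dH_kJ_mol = dH,
                    temperature_K = temperature_K,
                    dCp_low = if (is.null(dcp)) NA_real_ else dcp$dCp_low,
                    dCp_high = if (is.null(dcp)) NA_real_ else dcp$dCp_high),
      error = function(e) fail("thermo", e))
  }

  # --- hydration ------------------------------------------------------
  hydration_out <- NULL
  if (!is.null(inputs$buildup)) {
    hydration_out <- tryCatch({
      bc <- read_buildup(inputs$buildup)
      bc <- normalize_buildup(bc, reference_ms = p$reference_ms %||% 100)
      hydration_analysis(bc, D_eff = p$D_eff %||% 0.2,
                         window = p$slope_window %||% 0.5)
    }, error = function(e) fail("hydration", e))
  }

  # --- binding --------------------------------------------------------
  binding_out <- NULL
  if (!is.null(inputs$isotherms) && length(inputs$isotherms) > 0L) {
    binding_out <- lapply(seq_along(inputs$isotherms), function(i) {
      tryCatch({
        iso <- read_isotherm(inputs$isotherms[[i]])
        iso$ligand <- names(inputs$isotherms)[i] %||% NA_character_
        compare_cooperativity(iso, alpha = p$alpha %||% 0.05)
      }, error = function(e) fail(paste0("binding_", i), e))
    })
    names(binding_out) <- names(inputs$isotherms)
  }

  # --- kinetics -------------------------------------------------------
  kinetics_out <- NULL
  if (!is.null(inputs$tht)) {
    kinetics_out <- tryCatch({
      tr <- read_tht(inputs$tht)
      fit <- fit_tht_sigmoid(tr)
      list(fit = fit, plateau = detect_plateau(tr))
    }, error = function(e) fail("kinetics", e))
  }

  structure(list(
    dls = dls_out,
    critical_concentration = cc,
    itc = itc,
    heat_capacity = dcp,
    thermo = thermo_out,
    hydration = hydration_out,
    binding = binding_out,
    kinetics = kinetics_out,
    units = list(critical_conc = "M", K_F = "1/M", dG_app = "kJ/mol",
                 dH = "kJ/mol", dS = "kJ/mol/K", dCp = "kJ/mol/K",
                 radius = "nm", mass = "kDa", t_m_s = "ms",
                 v_over_s = "nm", diameter = "nm", K_D = "M",
                 R_max = "RU", time = "h", heat = "J"),
    errors = errors,
    provenance = list(
      package = "fibriltherm",
      version = as.character(utils::packageVersion("fibriltherm")),
      seed = config$seed %||% NA_integer_,
      temperature_K = temperature_K)),
    class = "fibril_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fibril_report <- function(x, ...) {
  cat("<fibril_report>\n")
  if (!is.null(x$thermo)) print(x$thermo)
  if (!is.null(x$hydration)) print(x$hydration)
  if (!is.null(x$dls)) print(x$dls)
  if (!is.null(x$binding)) {
    for (nm in names(x$binding)) {
      cat(sprintf("  [%s] ", nm)); print(x$binding[[nm]])
    }
  }
  if (length(x$errors) > 0L) {
    cat("  stage errors:\n")
    for (nm in names(x$errors)) cat(sprintf("    %s: %s\n", nm,
                                            x$errors[[nm]]))
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the report (numeric payload plus units and provenance) as
#' pretty-printed JSON. Fit objects are flattened to their numeric
#' fields; rerunning the same configuration and seed yields a
#' byte-identical file.
#'
#' @param report a `fibril_report`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "fibril_report"))
  strip <- function(x) {
    if (inherits(x, "hill_fit")) {
      x <- unclass(x)[c("K_D_M", "n", "R_max_RU", "K_D_se_M", "n_se",
                        "rss", "verdict")]
    } else if (inherits(x, c("thermo_params", "hydration_result",
                             "tht_fit"))) {
      x <- unclass(x)
    } else if (inherits(x, "size_distribution")) {
      x <- list(species = x$species, residual = x$residual)
    }
    if (is.list(x)) lapply(x, strip) else x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       force = TRUE)
  invisible(path)
}
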