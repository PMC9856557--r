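#' Run the full coupled pipeline
#'
#' One-way coupling of the three models, mirroring the experimental
#' protocol: solve the acoustic field for the configured transducer
#' setting, form the absorbed power density, integrate the bioheat
#' equation over the insonation time, average the chamber temperature,
#' and evaluate the DLVO stability of the suspension before exposure
#' (at the initial 37 deg C with the pre-exposure zeta potential) and
#' after exposure (at the simulated chamber temperature with the
#' post-exposure zeta potential). Release is predicted by comparing the
#' after-state barrier to the calibrated threshold.
#'
#' @param config A configuration (path, list, or `lipus_config`).
#' @param keep_fields Keep the full pressure/thermal fields in the
#'   report (default FALSE to keep reports small).
#' @return An object of class `run_report`.
#' @export
run_full <- function(config, keep_fields = FALSE) {
  cfg <- resolve_config(config)
  media <- config_media(cfg)
  setting <- config_setting(cfg)
  grid <- config_grid(cfg, media)

  stage <- "acoustic"
  report <- tryCatch({
    field <- solve_helmholtz(grid, media, setting,
                             pml_strength = cfg$run$pml_strength)
    intensity <- intensity_from_pressure(field, media)  # duty deferred
    stage <- "thermal"
    sched <- pulse_schedule(on_time = setting$duty * setting$pulse_period,
                            period = setting$pulse_period,
                            total_time = setting$insonation_time,
                            mode = cfg$run$pulse_mode)
    src <- heat_source(intensity, media, sched)
    thermal <- solve_bht(grid, media, src, dt = cfg$run$dt,
                         bath_temperature = media$water$initial_temperature,
                         initial_temperature = media$water$initial_temperature)
    chamber_T <- chamber_mean_temperature(thermal)
    stage <- "dlvo"
    hgrid <- dlvo_h_grid(cfg$run$h_min, cfg$run$h_max, cfg$run$h_points)
    # the before-state is the unexposed suspension at its initial 37 C
    before <- config_suspension(cfg, cfg$gnp$zeta_before,
                                cfg$media$chamber$initial_temperature)
    after <- config_suspension(cfg, cfg$gnp$zeta_after, chamber_T)
    bar_b <- find_energy_barrier(compute_curve(before, hgrid))
    bar_a <- find_energy_barrier(compute_curve(after, hgrid))
    pct <- percent_change(bar_b$height, bar_a$height)
    structure(
      list(setting = setting,
           chamber_mean_T = chamber_T,
           max_chamber_pressure = max(Mod(field$p)[grid$mask == "chamber"]),
           max_chamber_intensity = max(intensity$I[grid$mask == "chamber"]),
           barrier_before = bar_b, barrier_after = bar_a,
           percent_drop = pct,
           release = predict_release(bar_a, cfg$run$release_threshold),
           threshold = cfg$run$release_threshold,
           provenance = list(
             config_hash = config_hash(cfg),
             grid = c(nr = grid$nr, nz = grid$nz),
             points_per_wavelength = cfg$run$points_per_wavelength,
             dt = cfg$run$dt, pulse_mode = cfg$run$pulse_mode,
             pml_strength = cfg$run$pml_strength),
           config = cfg,
           fields = if (keep_fields) {
             list(pressure = field, intensity = intensity, thermal = thermal)
           }),
      class = "run_report")
  }, error = function(e) {
    stop(sprintf("pipeline failed in %s stage: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  report
}

resolve_config <- function(config) {
  if (inherits(config, "lipus_config")) return(config)
  if (is.character(config)) return(read_config(config))
  validate_config(config)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$setting)
  cat(sprintf("  chamber mean T after %g s: %.2f C\n",
              x$setting$insonation_time, x$chamber_mean_T))
  cat(sprintf("  max chamber |p| = %.3g MPa, I = %.3g W/cm^2 (duty deferred)\n",
              x$max_chamber_pressure / 1e6, x$max_chamber_intensity / 1e4))
  cat(sprintf("  DLVO barrier: %.3f kBT (before) -> %.3f kBT (after), drop %.2f%%\n",
              x$barrier_before$height, x$barrier_after$height,
              x$percent_drop))
  cat(sprintf("  release predicted (threshold %.2f kBT): %s\n",
              x$threshold, x$release))
  cat(sprintf("  config %s, grid %d x %d\n", x$provenance$config_hash,
              x$provenance$grid["nr"], x$provenance$grid["nz"]))
  invisible(x)
}

#' Sweep the nine LIPUS drive settings
#'
#' Runs the coupled pipeline for every combination of acoustic power
#' and duty cycle (by default the device's 3 x 3 grid: 8.40/3.66/1.82 W
#' at continuous wave/50%/40%). The acoustic field is solved once at
#' the calibration displacement and rescaled (pressure is linear in
#' displacement, intensity quadratic), then the thermal solve runs per
#' setting. The post-exposure zeta potential is held at the single
#' measured value for all settings; the after-state barrier is computed
#' at each setting's simulated chamber temperature. A linear trend of
#' barrier height versus cycle-averaged power is fitted.
#'
#' @param config A configuration.
#' @param powers Acoustic power levels (W).
#' @param duties Duty-cycle fractions.
#' @return An object of class `sweep_table` with one row per setting
#'   and the fitted trend.
#' @export
sweep_lipus_settings <- function(config,
                                 powers = c(8.40, 3.66, 1.82),
                                 duties = c(1.0, 0.5, 0.4)) {
  cfg <- resolve_config(config)
  media <- config_media(cfg)
  grid <- config_grid(cfg, media)
  tr <- cfg$transducer
  ref_setting <- transducer_setting(tr$frequency, tr$element_diameter,
                                    tr$calibration_displacement,
                                    tr$calibration_power, 1.0,
                                    tr$pulse_period, tr$insonation_time)
  field <- solve_helmholtz(grid, media, ref_setting,
                           pml_strength = cfg$run$pml_strength)
  intensity_ref <- intensity_from_pressure(field, media)
  hgrid <- dlvo_h_grid(cfg$run$h_min, cfg$run$h_max, cfg$run$h_points)
  T0 <- cfg$media$chamber$initial_temperature

  combos <- expand.grid(power = powers, duty = duties,
                        KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    P <- combos$power[i]; du <- combos$duty[i]
    intensity <- intensity_ref
    intensity$I <- intensity_ref$I * (P / tr$calibration_power)
    sched <- pulse_schedule(on_time = du * tr$pulse_period,
                            period = tr$pulse_period,
                            total_time = tr$insonation_time,
                            mode = "averaged")
    src <- heat_source(intensity, media, sched)
    thermal <- solve_bht(grid, media, src, dt = cfg$run$dt,
                         bath_temperature = T0, initial_temperature = T0)
    chamber_T <- chamber_mean_temperature(thermal)
    after <- config_suspension(cfg, cfg$gnp$zeta_after, chamber_T)
    bar <- find_energy_barrier(compute_curve(after, hgrid))
    data.frame(power = P, duty = du, cycle_averaged_power = P * du,
               chamber_mean_T = chamber_T, barrier_kBT = bar$height)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$cycle_averaged_power), ]
  rownames(tab) <- NULL
  fit <- stats::lm(barrier_kBT ~ cycle_averaged_power, data = tab)
  structure(
    list(parameter = "cycle_averaged_power", table = tab,
         fit = list(degree = 1, coefficients = stats::coef(fit),
                    r_squared = summary(fit)$r.squared),
         zeta_after = cfg$gnp$zeta_after),
    class = "sweep_table"
  )
}

#' Parametric sweep of the GNP suspension
#'
#' Computes the DLVO energy barrier while varying one suspension
#' parameter with the others held at the base state: `temperature`
#' (deg C), `diameter` (m) or `zeta` (V). Every swept value must keep
#' kappa a < 5 (the LSA validity guard). A linear trend is fitted for
#' the temperature and diameter sweeps and a second-order polynomial
#' for the zeta sweep, with R^2 reported.
#'
#' @param base A [gnp_suspension()] giving the held-fixed parameters.
#' @param which One of `"temperature"`, `"diameter"`, `"zeta"`.
#' @param values Swept values (units above). May be empty (empty table,
#'   no fit).
#' @param h Separation grid for the curves.
#' @return An object of class `sweep_table`.
#' @export
sweep_gnp_parameters <- function(base,
                                 which = c("temperature", "diameter", "zeta"),
                                 values, h = dlvo_h_grid()) {
  stopifnot(inherits(base, "gnp_suspension"))
  which <- match.arg(which)
  values <- as.numeric(values)
  if (length(values) == 0) {
    return(structure(list(parameter = which,
                          table = data.frame(value = numeric(0),
                                             barrier_kBT = numeric(0)),
                          fit = NULL),
                     class = "sweep_table"))
  }
  base_tC <- kelvin_to_celsius(base$temperature)
  heights <- vapply(values, function(v) {
    susp <- switch(which,
      temperature = gnp_suspension(base$radius, base$hamaker, base$zeta,
                                   base$ionic_strength, v),
      diameter = gnp_suspension(v / 2, base$hamaker, base$zeta,
                                base$ionic_strength, base_tC),
      zeta = gnp_suspension(base$radius, base$hamaker, v,
                            base$ionic_strength, base_tC))
    deb <- inverse_debye_length(susp$ionic_strength, susp$temperature,
                                susp$permittivity)
    if (deb$kappa * susp$radius >= 5) {
      stop(sprintf("swept %s value %g violates the kappa*a < 5 LSA guard",
                   which, v), call. = FALSE)
    }
    find_energy_barrier(compute_curve(susp, h))$height
  }, numeric(1))
  tab <- data.frame(value = values, barrier_kBT = heights)
  degree <- if (which == "zeta") 2 else 1
  fit <- if (nrow(tab) > degree) {
    fm <- stats::lm(barrier_kBT ~ poly(value, degree, raw = TRUE), data = tab)
    list(degree = degree, coefficients = stats::coef(fm),
         r_squared = summary(fm)$r.squared)
  }
  structure(list(parameter = which, table = tab, fit = fit),
            class = "sweep_table")
}

#' @export
print.sweep_table <- function(x, ...) {
  cat(sprintf("<sweep_table> %s, %d rows\n", x$parameter, nrow(x$table)))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  if (!is.null(x$fit)) {
    cat(sprintf("  degree-%d fit, R^2 = %.4f\n", x$fit$degree,
                x$fit$r_squared))
  }
  invisible(x)
}

#' Write canonical configuration fixtures
#'
#' Emits the baseline configuration reproducing the tabulated media,
#' transducer calibration and GNP suspension parameters, together with
#' a small coarse-grid configuration for fast tests. Regeneration is
#' deterministic (byte-identical output).
#'
#' @param out_dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
generate_fixtures <- function(out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    stop("cannot write to ", out_dir, call. = FALSE)
  }
  baseline <- file.path(out_dir, "baseline.yaml")
  # the defaults ARE the baseline study configuration; serialise canonically
  writeLines(c(
    "# Baseline configuration: tabulated media and transducer calibration,",
    "# measured GNP suspension parameters, documented geometry assumptions.",
    "# Lengths in metres, temperatures in deg C.",
    canonical_config(default_config())), baseline)

  coarse_cfg <- default_config()
  coarse_cfg$geometry <- list(
    water_radius = 14e-3, standoff = 4e-3,
    tissue_radius = 10e-3, tissue_height = 10e-3,
    chamber_radius = 3e-3, chamber_height = 3e-3,
    water_below = 4e-3, pml_thickness = 2e-3)
  coarse_cfg$transducer$element_diameter <- 10e-3
  coarse_cfg$transducer$insonation_time <- 60
  coarse_cfg$run$h_points <- 800
  coarse <- file.path(out_dir, "coarse.yaml")
  writeLines(c(
    "# Reduced-domain configuration for fast tests: small tank and tissue,",
    "# 10 mm element, 60 s exposure. Not a physical study configuration.",
    canonical_config(coarse_cfg)), coarse)
  invisible(c(baseline = baseline, coarse = coarse))
}

#' Export a DLVO curve as delimited text
#'
#' Columns: h_nm, Vvdw_kBT, Velec_kBT, Vdlvo_kBT.
#'
#' @param curve A [compute_curve()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_curve <- function(curve, path) {
  stopifnot(inherits(curve, "dlvo_curve"))
  tab <- curve$table
  out <- data.frame(h_nm = tab$h * 1e9, Vvdw_kBT = tab$Vvdw_kBT,
                    Velec_kBT = tab$Velec_kBT, Vdlvo_kBT = tab$Vdlvo_kBT)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Structured barrier summary for one suspension state
#'
#' @param susp A [gnp_suspension()].
#' @param threshold Release threshold (k_B T).
#' @param h Separation grid.
#' @return Named list: barrier_kBT, h_star_nm, kappa_per_m, Y, release,
#'   threshold.
#' @export
barrier_summary <- function(susp, threshold = 0.24, h = dlvo_h_grid()) {
  curve <- compute_curve(susp, h)
  bar <- find_energy_barrier(curve)
  list(barrier_kBT = bar$height, h_star_nm = bar$h_star * 1e9,
       kappa_per_m = curve$kappa, Y = curve$Y,
       release = predict_release(bar, threshold), threshold = threshold)
}
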