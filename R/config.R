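#' Default configuration
#'
#' Fully resolved default parameter set: the tabulated media and
#' transducer calibration, the documented geometry assumptions, the
#' tabulated GNP suspension parameters, and the numerical run controls.
#' All lengths are SI metres, temperatures deg C in the config (the
#' DLVO engine converts to kelvin internally).
#'
#' @return Nested named list with sections `media`, `geometry`,
#'   `transducer`, `gnp`, `run`.
#' @export
default_config <- function() {
  list(
    media = list(
      water = list(density = 994.23, sound_speed = 1520.6,
                   attenuation_db = 0.0022, thermal_conductivity = 0.62,
                   specific_heat = 4178, initial_temperature = 37.0),
      tissue = list(density = 1090, sound_speed = 1600,
                    attenuation_db = 0.780, thermal_conductivity = 0.49,
                    specific_heat = 3421, initial_temperature = 37.0),
      chamber = list(density = 994.23, sound_speed = 1520.6,
                     attenuation_db = 0.0022, thermal_conductivity = 0.62,
                     specific_heat = 4178, initial_temperature = 37.0)
    ),
    geometry = list(
      water_radius = 40e-3,
      standoff = 10e-3,
      tissue_radius = sqrt(60e-3 * 73e-3 / pi),
      tissue_height = 25e-3,
      chamber_radius = sqrt(10e-3 * 10e-3 / pi),
      chamber_height = 5e-3,
      water_below = 10e-3,
      pml_thickness = 3e-3
    ),
    transducer = list(
      frequency = 1.0e6,
      element_diameter = 24e-3,
      calibration_displacement = 24.944e-9,
      calibration_power = 8.40,
      acoustic_power = 8.40,
      duty = 0.5,
      pulse_period = 1e-3,
      insonation_time = 300
    ),
    gnp = list(
      radius = 3.7e-9,
      hamaker = 2.5e-19,
      zeta_before = -30.3e-3,
      zeta_after = -15.8e-3,
      ionic_strength = 0.4052,
      permittivity_override = NULL
    ),
    run = list(
      points_per_wavelength = 5,
      dt = 0.5,
      pulse_mode = "averaged",
      pml_strength = 2,
      release_threshold = 0.24,
      h_min = 0.1e-9,
      h_max = 100e-9,
      h_points = 2000
    )
  )
}

# recursive merge of user config over defaults; unknown keys are an error
merge_config <- function(default, user, path = "") {
  if (!is.list(user)) stop("config section '", path, "' must be a mapping",
                           call. = FALSE)
  unknown <- setdiff(names(user), names(default))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "),
         call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(default[[k]]) && !is.null(default[[k]])) {
      default[[k]] <- merge_config(default[[k]], user[[k]],
                                   paste0(path, ".", k))
    } else {
      default[k] <- user[k]   # [ ] keeps explicit NULLs
    }
  }
  default
}

#' Read and resolve a configuration file
#'
#' Reads a YAML configuration, merges it over [default_config()]
#' (partial configs are allowed; every field is addressable), and
#' rejects unknown keys.
#'
#' @param path YAML file path, or NULL for the pure defaults.
#' @return Resolved configuration list of class `lipus_config`.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
}

#' Validate a configuration list
#'
#' Checks types, positivity and consistency constraints of a resolved
#' configuration, and constructs (then discards) the domain objects so
#' their own invariants are exercised.
#'
#' @param config Nested configuration list.
#' @return The config, classed `lipus_config`, invisibly usable onward.
#' @export
validate_config <- function(config) {
  cfg <- merge_config(default_config(), unclass(config))  # key check
  for (m in names(cfg$media)) do.call(medium, c(name = m, cfg$media[[m]]))
  do.call(axisym_geometry, cfg$geometry)
  tr <- cfg$transducer
  if (tr$acoustic_power < 0 || tr$calibration_power <= 0) {
    stop("acoustic power must be >= 0 and calibration power > 0",
         call. = FALSE)
  }
  transducer_setting(tr$frequency, tr$element_diameter,
                     tr$calibration_displacement, tr$calibration_power,
                     tr$duty, tr$pulse_period, tr$insonation_time)
  g <- cfg$gnp
  gnp_suspension(g$radius, g$hamaker, g$zeta_before, g$ionic_strength,
                 cfg$media$chamber$initial_temperature,
                 permittivity = g$permittivity_override)
  r <- cfg$run
  if (r$points_per_wavelength < 2) {
    stop("points_per_wavelength must be >= 2", call. = FALSE)
  }
  if (r$dt <= 0 || r$h_min <= 0 || r$h_max <= r$h_min || r$h_points < 2 ||
      r$release_threshold <= 0) {
    stop("invalid run controls", call. = FALSE)
  }
  if (!r$pulse_mode %in% c("averaged", "explicit")) {
    stop("pulse_mode must be 'averaged' or 'explicit'", call. = FALSE)
  }
  structure(cfg, class = "lipus_config")
}

#' Canonical configuration document
#'
#' Serialises the fully resolved configuration as canonical YAML (fixed
#' key order from the defaults, full precision). Identical
#' configurations produce byte-identical documents, which also back the
#' provenance hash.
#'
#' @param config A resolved configuration.
#' @return A single YAML string.
#' @export
canonical_config <- function(config) {
  yaml::as.yaml(unclass(validate_config(config)), precision = 12)
}

# rolling polynomial hash of the canonical config document (provenance id)
config_hash <- function(config) {
  bytes <- utf8ToInt(canonical_config(config))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# --- constructors from a resolved config ------------------------------

config_media <- function(cfg) {
  lapply(stats::setNames(nm = names(cfg$media)), function(m) {
    do.call(medium, c(name = m, cfg$media[[m]]))
  })
}

config_geometry <- function(cfg) do.call(axisym_geometry, cfg$geometry)

# transducer setting at the configured acoustic power, with the element
# displacement scaled from the calibration point (zero power allowed)
config_setting <- function(cfg) {
  tr <- cfg$transducer
  d <- tr$calibration_displacement * sqrt(tr$acoustic_power /
                                            tr$calibration_power)
  transducer_setting(tr$frequency, tr$element_diameter, d,
                     tr$acoustic_power, tr$duty, tr$pulse_period,
                     tr$insonation_time)
}

config_suspension <- function(cfg, zeta, temperature_C) {
  g <- cfg$gnp
  gnp_suspension(g$radius, g$hamaker, zeta, g$ionic_strength, temperature_C,
                 permittivity = g$permittivity_override)
}

config_grid <- function(cfg, media = config_media(cfg)) {
  wavelength <- min(vapply(media, `[[`, numeric(1), "sound_speed")) /
    cfg$transducer$frequency
  build_grid(config_geometry(cfg), wavelength,
             cfg$run$points_per_wavelength)
}
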