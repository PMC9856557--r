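#' Acoustic and thermal properties of one medium
#'
#' A medium bundles the acoustic (density, sound speed, attenuation) and
#' thermal (conductivity, specific heat) properties of one region of the
#' computational domain: the water bath, the tissue block, or the GNP
#' chamber contents (modelled as water).
#'
#' @param name Region name (character).
#' @param density Mass density rho (kg/m^3), > 0.
#' @param sound_speed Speed of sound c (m/s), > 0.
#' @param attenuation_db Acoustic attenuation coefficient in
#'   dB/(cm MHz^2), >= 0. Converted to Np/m at a given frequency by
#'   [attenuation_np_per_m()].
#' @param thermal_conductivity k (W/(m C)), > 0.
#' @param specific_heat C (J/(kg C)), > 0.
#' @param initial_temperature Initial temperature (deg C).
#' @return An object of class `medium`.
#' @examples
#' water <- medium("water", 994.23, 1520.6, 0.0022, 0.62, 4178)
#' attenuation_np_per_m(water, 1e6)
#' @export
medium <- function(name, density, sound_speed, attenuation_db,
                   thermal_conductivity, specific_heat,
                   initial_temperature = 37.0) {
  stopifnot(is.character(name), length(name) == 1L)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (v in list(density, sound_speed, attenuation_db, thermal_conductivity,
                 specific_heat, initial_temperature)) {
    if (!num1(v)) stop("medium properties must be finite scalars", call. = FALSE)
  }
  if (density <= 0 || sound_speed <= 0 || thermal_conductivity <= 0 ||
      specific_heat <= 0) {
    stop("density, sound speed, thermal conductivity and specific heat must be > 0",
         call. = FALSE)
  }
  if (attenuation_db < 0) {
    stop("invalid medium: attenuation coefficient must be >= 0", call. = FALSE)
  }
  structure(
    list(name = name, density = density, sound_speed = sound_speed,
         attenuation_db = attenuation_db,
         thermal_conductivity = thermal_conductivity,
         specific_heat = specific_heat,
         initial_temperature = initial_temperature),
    class = "medium"
  )
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> %s\n", x$name))
  cat(sprintf("  rho = %g kg/m^3, c = %g m/s, alpha = %g dB/(cm MHz^2)\n",
              x$density, x$sound_speed, x$attenuation_db))
  cat(sprintf("  k = %g W/(m C), C = %g J/(kg C), T0 = %g C\n",
              x$thermal_conductivity, x$specific_heat, x$initial_temperature))
  invisible(x)
}

#' Attenuation coefficient in Np/m at a given frequency
#'
#' Converts the tabulated attenuation coefficient, quoted in
#' dB/(cm MHz^2) with quadratic frequency dependence, to the natural
#' (Neper) absorption coefficient per metre used in the complex
#' wavenumber and in the absorbed-power heat source Qext = 2 alpha I.
#'
#' alpha(f) = alpha_dB * (f / 1 MHz)^2 * 100 * ln(10) / 20
#'
#' @param medium A [medium()].
#' @param frequency Acoustic frequency (Hz), > 0.
#' @return Absorption coefficient alpha (Np/m).
#' @examples
#' tissue <- medium("tissue", 1090, 1600, 0.780, 0.49, 3421)
#' attenuation_np_per_m(tissue, 1e6)  # ~8.98 Np/m
#' @export
attenuation_np_per_m <- function(medium, frequency) {
  stopifnot(inherits(medium, "medium"))
  if (!is.numeric(frequency) || frequency <= 0) {
    stop("frequency must be > 0", call. = FALSE)
  }
  if (medium$attenuation_db < 0) {
    stop("invalid medium: negative attenuation coefficient", call. = FALSE)
  }
  f_mhz <- frequency / 1e6
  medium$attenuation_db * f_mhz^2 * 100 * log(10) / 20
}

#' One LIPUS transducer drive setting
#'
#' Drive parameters of the piston transducer. The device provides three
#' acoustic power settings (8.40, 3.66, 1.82 W) and three duty cycles
#' (continuous wave, 50%, 40%), giving nine cycle-averaged power levels.
#' Any duty in (0, 1] is accepted.
#'
#' @param frequency Drive frequency (Hz).
#' @param element_diameter Active element diameter (m).
#' @param displacement Element displacement amplitude (m), >= 0.
#' @param acoustic_power Total acoustic power while on (W).
#' @param duty Duty cycle, fraction in (0, 1].
#' @param pulse_period Pulse repetition period (s); default 1 ms.
#' @param insonation_time Total exposure time (s); default 300 s.
#' @return An object of class `transducer_setting`.
#' @export
transducer_setting <- function(frequency, element_diameter, displacement,
                               acoustic_power, duty = 1.0,
                               pulse_period = 1e-3, insonation_time = 300) {
  if (!is.numeric(duty) || duty <= 0 || duty > 1) {
    stop("duty must lie in (0, 1]", call. = FALSE)
  }
  if (displacement < 0) stop("displacement must be >= 0", call. = FALSE)
  if (frequency <= 0 || element_diameter <= 0) {
    stop("frequency and element diameter must be > 0", call. = FALSE)
  }
  structure(
    list(frequency = frequency, element_diameter = element_diameter,
         displacement = displacement, acoustic_power = acoustic_power,
         duty = duty, pulse_period = pulse_period,
         insonation_time = insonation_time),
    class = "transducer_setting"
  )
}

#' @export
print.transducer_setting <- function(x, ...) {
  cat(sprintf(
    "<transducer_setting> %g MHz, D = %g mm, d = %.3f nm, %g W at duty %.2f (%.3g W cycle-averaged)\n",
    x$frequency / 1e6, x$element_diameter * 1e3, x$displacement * 1e9,
    x$acoustic_power, x$duty, cycle_averaged_power(x)))
  invisible(x)
}

#' Scale element displacement to a target acoustic power
#'
#' Pressure amplitude is proportional to element displacement and power
#' to pressure amplitude squared, so the calibrated displacement at one
#' reference power scales as the square root of the power ratio. This
#' extends the single calibration point (24.944 nm at 8.40 W) to the
#' other power settings.
#'
#' @param reference A [transducer_setting()] with displacement and
#'   acoustic_power set.
#' @param target_power Target acoustic power (W), > 0.
#' @return Displacement (m) at the target power.
#' @examples
#' ref <- transducer_setting(1e6, 24e-3, 24.944e-9, 8.40, 0.5)
#' displacement_for_power(ref, 3.66) * 1e9  # 16.47 nm
#' @export
displacement_for_power <- function(reference, target_power) {
  stopifnot(inherits(reference, "transducer_setting"))
  if (!is.numeric(target_power) || target_power <= 0) {
    stop("target power must be > 0", call. = FALSE)
  }
  if (reference$acoustic_power <= 0) {
    stop("reference acoustic power must be > 0", call. = FALSE)
  }
  reference$displacement * sqrt(target_power / reference$acoustic_power)
}

#' Cycle-averaged acoustic power of a setting
#'
#' Acoustic power multiplied by the duty cycle; the abscissa of the
#' barrier-versus-power trend across the nine LIPUS settings.
#'
#' @param setting A [transducer_setting()].
#' @return Cycle-averaged power (W).
#' @export
cycle_averaged_power <- function(setting) {
  stopifnot(inherits(setting, "transducer_setting"))
  setting$acoustic_power * setting$duty
}

#' Axisymmetric computational geometry
#'
#' The experimental setup - a rectangular tissue block holding a small
#' GNP chamber, submerged in a temperature-controlled water tank and
#' insonated from above by a piston transducer - is idealised as a 2D
#' axisymmetric (r, z) domain. z increases away from the transducer face
#' at z = 0; r = 0 is the beam axis. The rectangular tissue block and
#' chamber are mapped to cylinders of equal cross-sectional area, which
#' preserves the heated volume. A perfectly matched layer (PML) of the
#' given thickness is appended on the outer radial and bottom boundaries.
#'
#' @param water_radius Radius of the water tank domain (m).
#' @param standoff Distance from the transducer face to the tissue top (m).
#' @param tissue_radius,tissue_height Equivalent tissue cylinder (m).
#' @param chamber_radius,chamber_height Equivalent GNP chamber cylinder
#'   (m); the chamber is centred on the axis at the tissue mid-depth.
#' @param water_below Water layer between the tissue bottom and the
#'   bottom PML (m).
#' @param pml_thickness PML thickness (m), default 3 mm.
#' @return An object of class `axisym_geometry` with derived z-extents
#'   of each region.
#' @examples
#' geom <- axisym_geometry()
#' geom$chamber_z  # axial extent of the GNP chamber (m)
#' @export
axisym_geometry <- function(water_radius = 40e-3,
                            standoff = 10e-3,
                            tissue_radius = sqrt(60e-3 * 73e-3 / pi),
                            tissue_height = 25e-3,
                            chamber_radius = sqrt(10e-3 * 10e-3 / pi),
                            chamber_height = 5e-3,
                            water_below = 10e-3,
                            pml_thickness = 3e-3) {
  vals <- c(water_radius, standoff, tissue_radius, tissue_height,
            chamber_radius, chamber_height, water_below, pml_thickness)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry dimensions must be finite and > 0", call. = FALSE)
  }
  tissue_z <- c(standoff, standoff + tissue_height)
  z_mid <- mean(tissue_z)
  chamber_z <- z_mid + c(-0.5, 0.5) * chamber_height
  if (chamber_radius >= tissue_radius ||
      chamber_z[1] < tissue_z[1] || chamber_z[2] > tissue_z[2]) {
    stop("GNP chamber must be strictly contained in the tissue block",
         call. = FALSE)
  }
  if (tissue_radius >= water_radius) {
    stop("tissue block must be contained in the water domain", call. = FALSE)
  }
  structure(
    list(water_radius = water_radius, standoff = standoff,
         tissue_radius = tissue_radius, tissue_height = tissue_height,
         chamber_radius = chamber_radius, chamber_height = chamber_height,
         water_below = water_below, pml_thickness = pml_thickness,
         tissue_z = tissue_z, chamber_z = chamber_z,
         interior_depth = standoff + tissue_height + water_below),
    class = "axisym_geometry"
  )
}

#' @export
print.axisym_geometry <- function(x, ...) {
  mm <- function(v) paste0(format(round(v * 1e3, 3)), " mm")
  cat("<axisym_geometry>\n")
  cat(sprintf("  water: r <= %s, z in [0, %s] + PML %s\n",
              mm(x$water_radius), mm(x$interior_depth), mm(x$pml_thickness)))
  cat(sprintf("  tissue: r <= %s, z in [%s, %s]\n",
              mm(x$tissue_radius), mm(x$tissue_z[1]), mm(x$tissue_z[2])))
  cat(sprintf("  chamber: r <= %s, z in [%s, %s]\n",
              mm(x$chamber_radius), mm(x$chamber_z[1]), mm(x$chamber_z[2])))
  invisible(x)
}

#' Build the finite-difference grid
#'
#' Uniform (r, z) grid over the domain including the PML, with spacing
#' no coarser than wavelength / points_per_wavelength in either
#' direction (the mesh rule under which the chamber temperature is
#' mesh-converged). Each node carries a region label used to assign
#' material properties.
#'
#' @param geometry An [axisym_geometry()].
#' @param wavelength Acoustic wavelength in the slowest medium (m).
#' @param points_per_wavelength Minimum grid points per wavelength
#'   (default 5).
#' @return An object of class `sim_grid`: node coordinates `r`, `z`,
#'   spacings `dr`, `dz`, the region label matrix `mask`
#'   (nr x nz; "water", "tissue", "chamber" or "pml"), and axisymmetric
#'   volume weights.
#' @export
build_grid <- function(geometry, wavelength, points_per_wavelength = 5) {
  stopifnot(inherits(geometry, "axisym_geometry"))
  if (!is.numeric(wavelength) || wavelength <= 0) {
    stop("wavelength must be > 0", call. = FALSE)
  }
  if (points_per_wavelength < 2) {
    stop("points_per_wavelength must be >= 2", call. = FALSE)
  }
  hmax <- wavelength / points_per_wavelength
  r_max <- geometry$water_radius + geometry$pml_thickness
  z_max <- geometry$interior_depth + geometry$pml_thickness
  nr <- ceiling(r_max / hmax) + 1L
  nz <- ceiling(z_max / hmax) + 1L
  dr <- r_max / (nr - 1L)
  dz <- z_max / (nz - 1L)
  r <- seq(0, r_max, length.out = nr)
  z <- seq(0, z_max, length.out = nz)

  # region labels; boundaries land on the nearest grid line (half-cell snap)
  tol_r <- dr / 2
  tol_z <- dz / 2
  mask <- matrix("water", nr, nz)
  in_t <- outer(r <= geometry$tissue_radius + tol_r,
                z >= geometry$tissue_z[1] - tol_z &
                z <= geometry$tissue_z[2] + tol_z, FUN = "&")
  mask[in_t] <- "tissue"
  in_c <- outer(r <= geometry$chamber_radius + tol_r,
                z >= geometry$chamber_z[1] - tol_z &
                z <= geometry$chamber_z[2] + tol_z, FUN = "&")
  mask[in_c] <- "chamber"
  in_pml <- outer(r > geometry$water_radius + tol_r, rep(TRUE, nz),
                  FUN = "&") |
    outer(rep(TRUE, nr), z > geometry$interior_depth + tol_z, FUN = "&")
  mask[in_pml] <- "pml"

  # axisymmetric volume weight per node (per radian): integral of r dr dz
  # over the node's control cell; the axis node's radial measure is dr^2/8
  wr <- r * dr
  wr[1] <- dr^2 / 8
  wr[nr] <- (r[nr]^2 - (r[nr] - dr / 2)^2) / 2
  wz <- rep(dz, nz)
  wz[c(1L, nz)] <- dz / 2
  vol <- outer(wr, wz)

  structure(
    list(r = r, z = z, dr = dr, dz = dz, nr = nr, nz = nz,
         mask = mask, vol = vol, geometry = geometry,
         points_per_wavelength = points_per_wavelength,
         wavelength = wavelength),
    class = "sim_grid"
  )
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> %d x %d nodes, dr = %.4g mm, dz = %.4g mm\n",
              x$nr, x$nz, x$dr * 1e3, x$dz * 1e3))
  tab <- table(x$mask)
  cat("  regions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Per-node material property arrays for a grid. media is a named list with
# elements water, tissue, chamber (each a medium); PML nodes continue the
# water properties.
media_arrays <- function(grid, media, frequency) {
  stopifnot(inherits(grid, "sim_grid"))
  key <- grid$mask
  key[key == "pml"] <- "water"
  pick <- function(field) {
    v <- vapply(media, `[[`, numeric(1), field)
    matrix(v[key], grid$nr, grid$nz)
  }
  alpha_of <- vapply(media, attenuation_np_per_m, numeric(1),
                     frequency = frequency)
  list(
    rho = pick("density"),
    c = pick("sound_speed"),
    alpha = matrix(alpha_of[key], grid$nr, grid$nz),
    k = pick("thermal_conductivity"),
    Cp = pick("specific_heat")
  )
}
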