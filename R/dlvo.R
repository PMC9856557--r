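#' GNP colloidal suspension state
#'
#' One DLVO state of the gold-nanoparticle suspension: particle radius,
#' Hamaker constant, zeta potential, ionic strength, and temperature.
#' Unless an explicit permittivity override is supplied, the water
#' permittivity is computed from the suspension temperature via
#' [water_relative_permittivity()].
#'
#' @param radius Particle radius a (m), > 0.
#' @param hamaker Hamaker constant A_H (J), > 0.
#' @param zeta Zeta (surface) potential psi0 (V); sign is kept.
#' @param ionic_strength Ionic strength I (mol/m^3), > 0.
#' @param temperature_C Suspension temperature (deg C).
#' @param permittivity Optional absolute permittivity override
#'   (C^2/(N m^2)); by default computed from temperature.
#' @return An object of class `gnp_suspension`; component `temperature`
#'   is in kelvin, `permittivity` is resolved.
#' @examples
#' before <- gnp_suspension(3.7e-9, 2.5e-19, -30.3e-3, 0.4052, 37.0)
#' @export
gnp_suspension <- function(radius, hamaker, zeta, ionic_strength,
                           temperature_C, permittivity = NULL) {
  if (radius <= 0 || hamaker <= 0 || ionic_strength <= 0) {
    stop("radius, Hamaker constant and ionic strength must be > 0",
         call. = FALSE)
  }
  T_K <- celsius_to_kelvin(temperature_C)
  if (T_K <= 0) stop("temperature must be above absolute zero", call. = FALSE)
  eps <- if (is.null(permittivity)) {
    water_relative_permittivity(T_K) * physical_constants()$eps0
  } else {
    if (permittivity <= 0) stop("permittivity must be > 0", call. = FALSE)
    permittivity
  }
  structure(
    list(radius = radius, hamaker = hamaker, zeta = zeta,
         ionic_strength = ionic_strength, temperature = T_K,
         permittivity = eps,
         permittivity_overridden = !is.null(permittivity)),
    class = "gnp_suspension"
  )
}

#' @export
print.gnp_suspension <- function(x, ...) {
  cat(sprintf("<gnp_suspension> a = %.3g nm, A_H = %.3g J, zeta = %.4g mV\n",
              x$radius * 1e9, x$hamaker, x$zeta * 1e3))
  cat(sprintf("  I = %.4g mol/m^3, T = %.2f K, eps = %.4g C^2/(N m^2)%s\n",
              x$ionic_strength, x$temperature, x$permittivity,
              if (x$permittivity_overridden) " (override)" else ""))
  invisible(x)
}

#' Static relative permittivity of water
#'
#' Handbook polynomial fit for the static dielectric constant of liquid
#' water as a function of temperature,
#' eps_r(t) = 87.740 - 0.40008 t + 9.398e-4 t^2 - 1.410e-6 t^3 (t in
#' deg C), valid over 0-100 deg C. Multiplied by the vacuum
#' permittivity this gives the temperature-dependent permittivity used
#' in the Debye length and the electrostatic potential.
#'
#' @param T_K Temperature (K), in (273.15, 373.15).
#' @return Relative permittivity (dimensionless). Vectorised.
#' @examples
#' water_relative_permittivity(298.15)  # ~78.30
#' @export
water_relative_permittivity <- function(T_K) {
  if (any(T_K <= 273.15 | T_K >= 373.15)) {
    stop("temperature outside the liquid-water fit range (273.15, 373.15) K",
         call. = FALSE)
  }
  t <- kelvin_to_celsius(T_K)
  87.740 - 0.40008 * t + 9.398e-4 * t^2 - 1.410e-6 * t^3
}

#' Inverse Debye screening length
#'
#' kappa = sqrt(2 e^2 N_A I / (eps k_B T)) for a symmetric electrolyte
#' with ionic strength I in mol/m^3. 1/kappa is the Debye length, the
#' decay length of the screened electrostatic interaction.
#'
#' @param ionic_strength I (mol/m^3), > 0.
#' @param T_K Temperature (K), > 0.
#' @param permittivity Absolute permittivity eps (C^2/(N m^2)), > 0.
#' @return List with `kappa` (1/m) and `lambda_D` = 1/kappa (m).
#' @examples
#' eps <- water_relative_permittivity(310.15) * physical_constants()$eps0
#' inverse_debye_length(0.4052, 310.15, eps)$lambda_D * 1e9  # ~15 nm
#' @export
inverse_debye_length <- function(ionic_strength, T_K, permittivity) {
  if (ionic_strength <= 0 || T_K <= 0 || permittivity <= 0) {
    stop("ionic strength, temperature and permittivity must be > 0",
         call. = FALSE)
  }
  const <- physical_constants()
  kappa <- sqrt(2 * const$e^2 * const$N_A * ionic_strength /
                  (permittivity * const$k_B * T_K))
  list(kappa = kappa, lambda_D = 1 / kappa)
}

#' Sphere-sphere van der Waals interaction potential
#'
#' Attractive van der Waals potential between two identical spheres of
#' radius a at surface-to-surface separation h, in the unretarded
#' Hamaker form with x = h/(2a):
#'
#' V_vdw = -(A_H/12) [ 1/(x(x+2)) + 1/(x+1)^2 + 2 ln(x(x+2)/(x+1)^2) ]
#'
#' @param h Surface separation (m), > 0. Vectorised.
#' @param a Particle radius (m), > 0.
#' @param hamaker Hamaker constant A_H (J).
#' @return Potential (J), negative (attractive).
#' @export
vdw_potential <- function(h, a, hamaker) {
  if (any(h <= 0)) {
    stop("separation h must be > 0 (contact singularity excluded)",
         call. = FALSE)
  }
  if (a <= 0) stop("radius must be > 0", call. = FALSE)
  x <- h / (2 * a)
  -(hamaker / 12) * (1 / (x * (x + 2)) + 1 / (x + 1)^2 +
                       2 * log(x * (x + 2) / (x + 1)^2))
}

#' Reduced surface potential of the LSA electrostatic model
#'
#' Y = 8 tanh(e psi0 / (4 k_B T)) /
#'     (1 + sqrt(1 - (2 kappa a + 1)/(kappa a + 1)^2 *
#'                 tanh^2(e psi0 / (4 k_B T))))
#'
#' Valid (with the linear superposition approximation) only for
#' kappa a < 5; beyond that the Hogg-Healy-Fuerstenau model would be
#' required, which is outside this package's scope. Y carries the sign
#' of psi0; only Y^2 enters the interaction potential.
#'
#' @param zeta Surface (zeta) potential psi0 (V).
#' @param T_K Temperature (K).
#' @param kappa Inverse Debye length (1/m).
#' @param a Particle radius (m).
#' @return Dimensionless reduced potential Y.
#' @export
reduced_surface_potential_Y <- function(zeta, T_K, kappa, a) {
  ka <- kappa * a
  if (ka >= 5) {
    stop(sprintf(
      "kappa*a = %.3g >= 5: linear superposition approximation invalid (Hogg-Healy-Fuerstenau regime, unsupported)",
      ka), call. = FALSE)
  }
  const <- physical_constants()
  th <- tanh(const$e * zeta / (4 * const$k_B * T_K))
  8 * th / (1 + sqrt(1 - (2 * ka + 1) / (ka + 1)^2 * th^2))
}

#' Sphere-sphere electrostatic interaction potential (LSA)
#'
#' Linear superposition approximation for two identical spheres:
#'
#' V_elec = 4 pi eps a^2 Y^2 (k_B T / e)^2 exp(-kappa h) / (h + 2a)
#'
#' Repulsive (>= 0) and exponentially screened with the Debye length.
#'
#' @param h Surface separation (m), >= 0. Vectorised.
#' @param susp A [gnp_suspension()].
#' @param kappa Inverse Debye length (1/m).
#' @param Y Reduced surface potential from
#'   [reduced_surface_potential_Y()].
#' @return Potential (J).
#' @export
electrostatic_potential <- function(h, susp, kappa, Y) {
  stopifnot(inherits(susp, "gnp_suspension"))
  if (any(h < 0)) stop("separation h must be >= 0", call. = FALSE)
  if (kappa * susp$radius >= 5) {
    stop(sprintf(
      "kappa*a = %.3g >= 5: linear superposition approximation invalid",
      kappa * susp$radius), call. = FALSE)
  }
  const <- physical_constants()
  4 * pi * susp$permittivity * susp$radius^2 * Y^2 *
    (const$k_B * susp$temperature / const$e)^2 *
    exp(-kappa * h) / (h + 2 * susp$radius)
}

#' Default separation grid for DLVO curves
#'
#' 2000 log-spaced separations on [0.1, 100] nm.
#'
#' @param h_min,h_max Range (m).
#' @param n Number of points.
#' @return Numeric vector of separations (m), strictly increasing.
#' @export
dlvo_h_grid <- function(h_min = 0.1e-9, h_max = 100e-9, n = 2000) {
  exp(seq(log(h_min), log(h_max), length.out = n))
}

#' Compute the DLVO interaction curve
#'
#' Evaluates the van der Waals, electrostatic, and total DLVO
#' interaction potentials over a separation grid, in joules and in
#' units of k_B T at the suspension's own temperature.
#'
#' @param susp A [gnp_suspension()].
#' @param h Separation grid (m), strictly positive and increasing;
#'   default [dlvo_h_grid()].
#' @return An object of class `dlvo_curve`: data frame `table` with
#'   columns h, x, Vvdw, Velec, Vdlvo (J) and *_kBT counterparts, plus
#'   `kappa`, `Y`, `kBT` (J) and the suspension.
#' @export
compute_curve <- function(susp, h = dlvo_h_grid()) {
  stopifnot(inherits(susp, "gnp_suspension"))
  if (length(h) < 1 || any(h <= 0) || any(diff(h) <= 0)) {
    stop("h grid must be strictly positive and increasing", call. = FALSE)
  }
  const <- physical_constants()
  deb <- inverse_debye_length(susp$ionic_strength, susp$temperature,
                              susp$permittivity)
  Y <- reduced_surface_potential_Y(susp$zeta, susp$temperature,
                                   deb$kappa, susp$radius)
  Vvdw <- vdw_potential(h, susp$radius, susp$hamaker)
  Velec <- electrostatic_potential(h, susp, deb$kappa, Y)
  kBT <- const$k_B * susp$temperature
  tab <- data.frame(
    h = h, x = h / (2 * susp$radius),
    Vvdw = Vvdw, Velec = Velec, Vdlvo = Vvdw + Velec,
    Vvdw_kBT = Vvdw / kBT, Velec_kBT = Velec / kBT,
    Vdlvo_kBT = (Vvdw + Velec) / kBT
  )
  structure(
    list(table = tab, kappa = deb$kappa, lambda_D = deb$lambda_D, Y = Y,
         kBT = kBT, suspension = susp),
    class = "dlvo_curve"
  )
}

#' @export
print.dlvo_curve <- function(x, ...) {
  cat(sprintf("<dlvo_curve> %d separations on [%.3g, %.3g] nm\n",
              nrow(x$table), min(x$table$h) * 1e9, max(x$table$h) * 1e9))
  cat(sprintf("  kappa = %.4g 1/m (lambda_D = %.3g nm), Y = %.4g\n",
              x$kappa, x$lambda_D * 1e9, x$Y))
  cat(sprintf("  max V_DLVO = %.4g kBT\n", max(x$table$Vdlvo_kBT)))
  invisible(x)
}

#' Extract the aggregation energy barrier
#'
#' Global maximum of the total DLVO potential over the curve's
#' separation range, refined by continuous optimisation around the grid
#' argmax (ties broken toward smaller separation). A barrier exists
#' only when the maximum is positive; a curve that is attractive
#' everywhere has no barrier (height 0) and the particles aggregate
#' freely.
#'
#' @param curve A [compute_curve()] result.
#' @return An object of class `dlvo_barrier`: `height` (k_B T units),
#'   `h_star` (m, location), `exists` (logical).
#' @export
find_energy_barrier <- function(curve) {
  stopifnot(inherits(curve, "dlvo_curve"))
  tab <- curve$table
  if (nrow(tab) == 0) stop("empty curve", call. = FALSE)
  i <- which.max(tab$Vdlvo)       # which.max takes the first (smallest h) tie
  susp <- curve$suspension
  vd <- function(h) {
    Yv <- curve$Y
    vdw_potential(h, susp$radius, susp$hamaker) +
      electrostatic_potential(h, susp, curve$kappa, Yv)
  }
  lo <- tab$h[max(1L, i - 1L)]
  hi <- tab$h[min(nrow(tab), i + 1L)]
  if (hi > lo) {
    opt <- stats::optimize(vd, c(lo, hi), maximum = TRUE,
                           tol = .Machine$double.eps^0.5 * lo)
    h_star <- opt$maximum
    vmax <- opt$objective
    # never report less than the grid value
    if (vmax < tab$Vdlvo[i]) { h_star <- tab$h[i]; vmax <- tab$Vdlvo[i] }
  } else {
    h_star <- tab$h[i]
    vmax <- tab$Vdlvo[i]
  }
  exists <- vmax > 0
  structure(
    list(height = if (exists) vmax / curve$kBT else 0,
         h_star = h_star, exists = exists),
    class = "dlvo_barrier"
  )
}

#' @export
print.dlvo_barrier <- function(x, ...) {
  if (x$exists) {
    cat(sprintf("<dlvo_barrier> %.4g kBT at h = %.4g nm\n",
                x$height, x$h_star * 1e9))
  } else {
    cat("<dlvo_barrier> no barrier (total potential <= 0 everywhere)\n")
  }
  invisible(x)
}

#' Percent change between two magnitudes
#'
#' 100 (|before| - |after|) / |before|; positive when the magnitude
#' decreased. Used for the barrier and zeta-potential changes across
#' the LIPUS exposure.
#'
#' @param before,after Values on the same scale; `before` nonzero.
#' @return Percent change.
#' @examples
#' percent_change(1.36, 0.24)  # 82.35
#' @export
percent_change <- function(before, after) {
  if (before == 0) stop("baseline value must be nonzero", call. = FALSE)
  100 * (abs(before) - abs(after)) / abs(before)
}

#' Predict drug release from the barrier height
#'
#' Release is predicted when the aggregation energy barrier is at or
#' below the calibrated threshold (default 0.24 k_B T, the after-
#' exposure barrier at which release was experimentally confirmed);
#' thermal motion then suffices to drive aggregation and release the
#' payload.
#'
#' @param barrier A [find_energy_barrier()] result, or a numeric
#'   barrier height in k_B T units.
#' @param threshold Release threshold (k_B T), > 0; default 0.24.
#' @return Logical: release predicted.
#' @export
predict_release <- function(barrier, threshold = 0.24) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  height <- if (inherits(barrier, "dlvo_barrier")) barrier$height
  else as.numeric(barrier)
  height <= threshold
}

#' Calibrate the release threshold
#'
#' Sets the release threshold to the after-exposure barrier height at
#' which release was experimentally observed. Idempotent by
#' construction.
#'
#' @param barrier_at_release Barrier height (k_B T) at confirmed
#'   release, > 0.
#' @return Threshold (k_B T).
#' @export
calibrate_threshold <- function(barrier_at_release) {
  if (!is.numeric(barrier_at_release) || barrier_at_release <= 0) {
    stop("barrier at release must be a positive number", call. = FALSE)
  }
  barrier_at_release
}
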