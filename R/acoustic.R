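#' Piston source pressure amplitude
#'
#' Plane-piston boundary amplitude p0 = rho c omega d for an element
#' oscillating with displacement amplitude d into a medium of
#' characteristic impedance rho c. Used as the magnitude of the
#' normal-velocity boundary condition on the element face.
#'
#' @param medium The [medium()] in contact with the element face.
#' @param omega Angular frequency (rad/s).
#' @param displacement Element displacement amplitude (m).
#' @return Pressure amplitude (Pa).
#' @examples
#' water <- medium("water", 994.23, 1520.6, 0.0022, 0.62, 4178)
#' source_pressure_amplitude(water, 2 * pi * 1e6, 24.944e-9)  # ~0.237 MPa
#' @export
source_pressure_amplitude <- function(medium, omega, displacement) {
  stopifnot(inherits(medium, "medium"))
  if (omega <= 0 || displacement < 0) {
    stop("omega must be > 0 and displacement >= 0", call. = FALSE)
  }
  medium$density * medium$sound_speed * omega * displacement
}

#' On-axis pressure of a baffled circular piston
#'
#' Closed-form on-axis solution of the Rayleigh integral for a uniform
#' circular piston of radius a_t in a rigid baffle radiating into a
#' lossless half-space:
#'
#' |p(z)| = 2 p0 |sin( (k/2) (sqrt(z^2 + a_t^2) - z) )|
#'
#' Serves as the independent analytic oracle for the discrete Helmholtz
#' solver in a uniform lossless medium.
#'
#' @param z On-axis distance from the piston face (m), >= 0. Vectorised.
#' @param p0 Plane-wave source amplitude rho c omega d (Pa).
#' @param k Wavenumber (rad/m).
#' @param element_radius Piston radius a_t (m).
#' @return On-axis pressure magnitude (Pa).
#' @export
onaxis_piston_reference <- function(z, p0, k, element_radius) {
  if (any(z < 0)) stop("z must be >= 0", call. = FALSE)
  2 * p0 * abs(sin(k / 2 * (sqrt(z^2 + element_radius^2) - z)))
}

# PML complex coordinate stretching: s(x) = 1 + 1i * strength * ((x-x0)/L)^2
# inside the layer, 1 elsewhere; the stretched coordinate is its integral.
pml_stretch <- function(x, x0, L, strength) {
  xi <- pmax(0, (x - x0) / L)
  s <- 1 + 1i * strength * xi^2
  xt <- x + 1i * strength * L * xi^3 / 3
  list(s = s, xt = xt)
}

#' Solve the axisymmetric Helmholtz equation
#'
#' Frequency-domain acoustic pressure on the (r, z) grid for a baffled
#' piston source, using second-order finite volumes on the cylindrical
#' Laplacian in the variable-density form
#' div((1/rho) grad p) + (omega/c)^2 p / rho = 0, with absorption folded
#' into the complex wavenumber k = omega/c + i alpha. Boundary
#' conditions: symmetry at r = 0 (the axis node uses the regularised
#' 4 (p1 - p0)/dr^2 radial term), a normal-displacement piston of radius
#' element_diameter/2 in a rigid baffle on the top boundary, and
#' quadratic complex-coordinate-stretching PMLs on the outer radial and
#' bottom boundaries terminated by p = 0.
#'
#' @param grid A [build_grid()] grid.
#' @param media Named list of [medium()] objects: water, tissue, chamber.
#' @param setting A [transducer_setting()].
#' @param pml_strength Maximum imaginary stretch of the PML profile
#'   (dimensionless, default 2).
#' @param dispersion_correction Replace k^2 in the mass term by the
#'   modified wavenumber (4/dz^2) sin^2(k dz/2), which makes the
#'   second-order stencil dispersion-free for axial plane waves and
#'   sharply reduces the accumulated phase error of the
#'   predominantly axial piston beam at moderate points-per-wavelength
#'   (default TRUE).
#' @return An object of class `pressure_field`: complex matrix `p`
#'   (nr x nz, Pa), `omega`, the grid, and the source amplitude `p0`.
#' @export
solve_helmholtz <- function(grid, media, setting, pml_strength = 2,
                            dispersion_correction = TRUE) {
  stopifnot(inherits(grid, "sim_grid"), inherits(setting, "transducer_setting"))
  omega <- 2 * pi * setting$frequency
  mats <- media_arrays(grid, media, setting$frequency)
  lambda_min <- min(mats$c) / setting$frequency
  if (max(grid$dr, grid$dz) > lambda_min / 2) {
    stop("grid spacing too coarse for the slowest medium", call. = FALSE)
  }
  nr <- grid$nr; nz <- grid$nz; dr <- grid$dr; dz <- grid$dz
  geom <- grid$geometry
  n <- nr * nz
  if (n < 4L) stop("zero-measure domain", call. = FALSE)

  # stretched coordinates at nodes and faces
  str_r <- pml_stretch(grid$r, geom$water_radius, geom$pml_thickness,
                       pml_strength)
  str_z <- pml_stretch(grid$z, geom$interior_depth, geom$pml_thickness,
                       pml_strength)
  rf <- grid$r[-nr] + dr / 2                     # radial faces i+1/2
  zf <- grid$z[-nz] + dz / 2
  str_rf <- pml_stretch(rf, geom$water_radius, geom$pml_thickness,
                        pml_strength)
  str_zf <- pml_stretch(zf, geom$interior_depth, geom$pml_thickness,
                        pml_strength)

  beta <- 1 / mats$rho
  kc <- omega / mats$c + 1i * mats$alpha        # complex wavenumber
  kc2 <- if (dispersion_correction) {
    (2 / dz * sin(kc * dz / 2))^2               # modified wavenumber
  } else {
    kc^2
  }

  idx <- function(i, j) i + (j - 1L) * nr

  ii <- integer(0); jj <- integer(0); vv <- complex(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }

  # radial couplings: nodes i = 1..nr-1 to E neighbour i+1 (all j)
  i_w <- rep(seq_len(nr - 1L), nz)              # west node of each face
  j_all <- rep(seq_len(nz), each = nr - 1L)
  bW <- beta[cbind(i_w, j_all)]
  bE <- beta[cbind(i_w + 1L, j_all)]
  bf <- 2 * bW * bE / (bW + bE)                 # harmonic mean of 1/rho
  rtf <- str_rf$xt[i_w]; srf <- str_rf$s[i_w]
  # paraxial diffraction correction: with the axial modified wavenumber,
  # scaling the radial couplings by sin(k dz)/(k dz) makes the discrete
  # dispersion relation exact to O(kr^4) for near-axial waves
  gam <- if (dispersion_correction) {
    kf <- (kc[cbind(i_w, j_all)] + kc[cbind(i_w + 1L, j_all)]) / 2
    sin(kf * dz) / (kf * dz)
  } else 1
  # flux weight of face (i, i+1): from the west node's equation
  wfac <- gam * rtf * bf / (dr^2 * srf)
  # coefficient in west node's row: wfac / (s_r,node * rt_node); axis special
  den_w <- str_r$s[i_w] * str_r$xt[i_w]
  cEW <- ifelse(i_w == 1L, 4 * gam * bf / dr^2, wfac / den_w)
  den_e <- str_r$s[i_w + 1L] * str_r$xt[i_w + 1L]
  # outer radial boundary row is a half cell
  cWE <- ifelse(i_w + 1L == nr, 2, 1) * wfac / den_e  # east node's row
  add(idx(i_w, j_all), idx(i_w + 1L, j_all), cEW)
  add(idx(i_w + 1L, j_all), idx(i_w, j_all), cWE)
  add(idx(i_w, j_all), idx(i_w, j_all), -cEW)
  add(idx(i_w + 1L, j_all), idx(i_w + 1L, j_all), -cWE)

  # axial couplings: faces between j and j+1 (all i)
  i_all <- rep(seq_len(nr), nz - 1L)
  j_n <- rep(seq_len(nz - 1L), each = nr)
  bN <- beta[cbind(i_all, j_n)]
  bS <- beta[cbind(i_all, j_n + 1L)]
  bfz <- 2 * bN * bS / (bN + bS)
  wz <- bfz / (dz^2 * str_zf$s[j_n])
  # boundary rows are half cells: their flux balance divides by dz/2
  hfacN <- ifelse(j_n == 1L, 2, 1)
  hfacS <- ifelse(j_n + 1L == nz, 2, 1)
  cSN <- hfacN * wz / str_z$s[j_n]               # north node's row
  cNS <- hfacS * wz / str_z$s[j_n + 1L]          # south node's row
  add(idx(i_all, j_n), idx(i_all, j_n + 1L), cSN)
  add(idx(i_all, j_n + 1L), idx(i_all, j_n), cNS)
  add(idx(i_all, j_n), idx(i_all, j_n), -cSN)
  add(idx(i_all, j_n + 1L), idx(i_all, j_n + 1L), -cNS)

  # mass term k^2 p / rho on every node
  all_i <- rep(seq_len(nr), nz)
  all_j <- rep(seq_len(nz), each = nr)
  add(idx(all_i, all_j), idx(all_i, all_j),
      as.vector(kc2 * beta))

  # piston forcing on the top boundary. The source row is normalised so
  # that the discrete outgoing plane wave has amplitude exactly
  # p0 = rho c omega d (consistent with the flux BC beta dp/dz = i w^2 d
  # as dz -> 0, but free of the O((k dz)^2) amplitude error of the raw
  # one-sided flux). The rim node is area-weighted over its annular face
  # cell so the effective piston radius is not quantised to whole cells.
  b <- complex(n)
  a_t <- setting$element_diameter / 2
  cell_lo <- pmax(grid$r - dr / 2, 0)
  cell_hi <- pmin(grid$r + dr / 2, grid$r[nr])
  cov_hi <- pmin(cell_hi, a_t)
  cover <- ifelse(cov_hi > cell_lo,
                  (cov_hi^2 - cell_lo^2) / (cell_hi^2 - cell_lo^2), 0)
  kc_top <- kc[, 1L]
  k_eff <- if (dispersion_correction) kc_top else 2 / dz * asin(kc_top * dz / 2)
  p0_top <- mats$rho[, 1L] * mats$c[, 1L] * omega * setting$displacement
  b[idx(seq_len(nr), 1L)] <- cover * beta[, 1L] * p0_top *
    (2 * (exp(1i * k_eff * dz) - 1) / dz^2 + kc2[, 1L])

  # assemble complex system as the equivalent 2n real system
  A <- Matrix::sparseMatrix(
    i = c(ii, ii, ii + n, ii + n),
    j = c(jj, jj + n, jj, jj + n),
    x = c(Re(vv), -Im(vv), Im(vv), Re(vv)),
    dims = c(2L * n, 2L * n)
  )
  rhs <- c(Re(b), Im(b))
  sol <- tryCatch(
    as.vector(Matrix::solve(A, rhs)),
    error = function(e) stop("Helmholtz solve failed (singular system?): ",
                             conditionMessage(e), call. = FALSE)
  )
  p <- matrix(complex(real = sol[seq_len(n)], imaginary = sol[n + seq_len(n)]),
              nr, nz)
  if (any(!is.finite(Re(p)) | !is.finite(Im(p)))) {
    stop("Helmholtz solution is not finite", call. = FALSE)
  }
  structure(
    list(p = p, omega = omega, grid = grid,
         p0 = source_pressure_amplitude(media$water, omega,
                                        setting$displacement),
         setting = setting),
    class = "pressure_field"
  )
}

#' @export
print.pressure_field <- function(x, ...) {
  cham <- x$grid$mask == "chamber"
  cat(sprintf("<pressure_field> %d x %d, f = %g MHz\n",
              x$grid$nr, x$grid$nz, x$omega / (2 * pi * 1e6)))
  cat(sprintf("  max |p| = %.4g MPa (domain), %.4g MPa (chamber)\n",
              max(Mod(x$p)) / 1e6,
              if (any(cham)) max(Mod(x$p)[cham]) / 1e6 else NA_real_))
  invisible(x)
}

#' Time-averaged acoustic intensity from the pressure field
#'
#' I = |p|^2 / (2 rho c) per node, optionally scaled by the duty cycle.
#' When `duty` is NULL the pulsing is deferred to the heat-source stage
#' (the `duty_folded` flag records which convention was used, so the
#' heat source cannot double-count the duty factor).
#'
#' @param field A [solve_helmholtz()] result.
#' @param media Named list of [medium()] objects as used for the solve.
#' @param duty Duty-cycle fraction to fold in, or NULL to defer.
#' @return An object of class `intensity_field`: matrix `I` (W/m^2) and
#'   flag `duty_folded`.
#' @export
intensity_from_pressure <- function(field, media, duty = NULL) {
  stopifnot(inherits(field, "pressure_field"))
  mats <- media_arrays(field$grid, media, field$omega / (2 * pi))
  I <- Mod(field$p)^2 / (2 * mats$rho * mats$c)
  folded <- !is.null(duty)
  if (folded) {
    if (duty <= 0 || duty > 1) stop("duty must lie in (0, 1]", call. = FALSE)
    I <- I * duty
  }
  structure(
    list(I = I, grid = field$grid, duty_folded = folded,
         duty = if (folded) duty else NA_real_,
         frequency = field$omega / (2 * pi)),
    class = "intensity_field"
  )
}

#' @export
print.intensity_field <- function(x, ...) {
  cat(sprintf("<intensity_field> max I = %.4g W/cm^2 (duty %s)\n",
              max(x$I) / 1e4,
              if (x$duty_folded) sprintf("%.2f folded", x$duty) else "deferred"))
  invisible(x)
}

#' Export a pressure/intensity field as a delimited table
#'
#' Writes one row per node: r, z (m), Re p, Im p, |p| (Pa) and I (W/m^2).
#'
#' @param field A `pressure_field`.
#' @param intensity Matching `intensity_field`.
#' @param path Output file (tab-separated).
#' @return The path, invisibly.
#' @export
export_field <- function(field, intensity, path) {
  if (!identical(dim(field$p), dim(intensity$I))) {
    stop("pressure and intensity grids do not match", call. = FALSE)
  }
  g <- field$grid
  df <- data.frame(
    r_m = rep(g$r, g$nz),
    z_m = rep(g$z, each = g$nr),
    re_p = as.vector(Re(field$p)),
    im_p = as.vector(Im(field$p)),
    abs_p = as.vector(Mod(field$p)),
    I_w_m2 = as.vector(intensity$I)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
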