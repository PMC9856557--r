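#' Pulse schedule for the LIPUS exposure
#'
#' Describes the Rect(t) pulsing of the source: a fixed repetition
#' period with a given on-time, applied for a total insonation time.
#' Two modes are supported: `"explicit"` resolves the on/off windows in
#' time (exact per-step on-fractions), `"averaged"` pre-multiplies the
#' heat source by on_time/period, which is the thermally equivalent
#' cycle-averaged drive for periods much shorter than the thermal
#' response time.
#'
#' @param on_time On-time per period (s).
#' @param period Pulse repetition period (s), default 1 ms.
#' @param total_time Total exposure (s), default 300 s.
#' @param mode `"averaged"` or `"explicit"`.
#' @return An object of class `pulse_schedule`.
#' @export
pulse_schedule <- function(on_time, period = 1e-3, total_time = 300,
                           mode = c("averaged", "explicit")) {
  mode <- match.arg(mode)
  if (!(on_time > 0 && on_time <= period)) {
    stop("need 0 < on_time <= period", call. = FALSE)
  }
  if (total_time <= 0) stop("total_time must be > 0", call. = FALSE)
  structure(list(on_time = on_time, period = period,
                 total_time = total_time, mode = mode),
            class = "pulse_schedule")
}

# fraction of [t0, t1] overlapping the on-windows of the schedule
on_fraction <- function(t0, t1, period, on_time) {
  if (on_time >= period) return(1)
  f <- function(t) {
    # integral of Rect over [0, t]
    n <- floor(t / period)
    n * on_time + pmin(t - n * period, on_time)
  }
  (f(t1) - f(t0)) / (t1 - t0)
}

#' Absorbed acoustic power density
#'
#' The external heat source of the bioheat equation,
#' Qext = 2 alpha I, from the time-averaged intensity field and the
#' per-medium absorption coefficient, with the duty-cycle pulsing
#' applied either explicitly in time (Rect) or as a pre-multiplied
#' average. The duty factor must be counted exactly once: an intensity
#' field that already folded the duty cannot be combined with explicit
#' pulsing, and in averaged mode its duty must match the schedule's.
#'
#' @param intensity An [intensity_from_pressure()] result.
#' @param media Named list of [medium()] objects.
#' @param schedule A [pulse_schedule()].
#' @return An object of class `heat_source`: matrix `Q` (W/m^3; the
#'   on-amplitude in explicit mode, the cycle-average in averaged mode)
#'   and the schedule.
#' @export
heat_source <- function(intensity, media, schedule) {
  stopifnot(inherits(intensity, "intensity_field"),
            inherits(schedule, "pulse_schedule"))
  mats <- media_arrays(intensity$grid, media, intensity$frequency)
  duty <- schedule$on_time / schedule$period
  Q <- 2 * mats$alpha * intensity$I
  if (schedule$mode == "explicit") {
    if (intensity$duty_folded) {
      stop("duty already folded into the intensity; explicit Rect pulsing would double-count it",
           call. = FALSE)
    }
  } else {
    if (intensity$duty_folded) {
      if (abs(intensity$duty - duty) > 1e-12) {
        stop("intensity duty and schedule duty disagree", call. = FALSE)
      }
    } else {
      Q <- Q * duty
    }
  }
  structure(list(Q = Q, grid = intensity$grid, schedule = schedule),
            class = "heat_source")
}

# symmetric finite-volume conduction operator and capacity vector.
# Returns conductances assembled into a sparse matrix K (positive
# semi-definite) and the per-node heat capacity rho*C*V.
assemble_thermal <- function(grid, mats) {
  nr <- grid$nr; nz <- grid$nz; dr <- grid$dr; dz <- grid$dz
  idx <- function(i, j) i + (j - 1L) * nr
  # cell extents: half cells at domain edges
  wr <- grid$r * dr
  wr[1] <- dr^2 / 8
  wr[nr] <- (grid$r[nr]^2 - (grid$r[nr] - dr / 2)^2) / 2
  hz <- rep(dz, nz); hz[c(1L, nz)] <- dz / 2
  rf <- grid$r[-nr] + dr / 2

  # radial faces
  i_w <- rep(seq_len(nr - 1L), nz)
  j_all <- rep(seq_len(nz), each = nr - 1L)
  kW <- mats$k[cbind(i_w, j_all)]
  kE <- mats$k[cbind(i_w + 1L, j_all)]
  Gr <- (2 * kW * kE / (kW + kE)) * rf[i_w] * hz[j_all] / dr
  # axial faces
  i_all <- rep(seq_len(nr), nz - 1L)
  j_n <- rep(seq_len(nz - 1L), each = nr)
  kN <- mats$k[cbind(i_all, j_n)]
  kS <- mats$k[cbind(i_all, j_n + 1L)]
  Gz <- (2 * kN * kS / (kN + kS)) * wr[i_all] / dz

  rows <- c(idx(i_w, j_all), idx(i_w + 1L, j_all),
            idx(i_w, j_all), idx(i_w + 1L, j_all),
            idx(i_all, j_n), idx(i_all, j_n + 1L),
            idx(i_all, j_n), idx(i_all, j_n + 1L))
  cols <- c(idx(i_w + 1L, j_all), idx(i_w, j_all),
            idx(i_w, j_all), idx(i_w + 1L, j_all),
            idx(i_all, j_n + 1L), idx(i_all, j_n),
            idx(i_all, j_n), idx(i_all, j_n + 1L))
  vals <- c(-Gr, -Gr, Gr, Gr, -Gz, -Gz, Gz, Gz)
  K <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(nr * nz, nr * nz))
  vol <- as.vector(outer(wr, hz))
  list(K = K, capacity = as.vector(mats$rho * mats$Cp) * vol, vol = vol)
}

#' Transient Pennes bioheat solve
#'
#' Integrates rho C dT/dt = div(k grad T) + Qext on the axisymmetric
#' grid with zero perfusion and metabolic terms (ex vivo mode), starting
#' from a uniform initial temperature. The stepper is implicit Euler
#' (unconditionally stable; the system matrix is factorised once and
#' reused), with the Rect(t) pulsing entering through the exact on-
#' fraction of each step in explicit mode. The outer boundaries (tank
#' wall, bottom, and the top surface) are held at the bath temperature;
#' `boundary = "insulated"` replaces this by zero-flux boundaries (used
#' for conservation checks). Symmetry at r = 0 always.
#'
#' @param grid A [build_grid()] grid.
#' @param media Named list of [medium()] objects.
#' @param source A [heat_source()].
#' @param dt Time step (s); default 0.5 s (averaged mode).
#' @param boundary `"bath"` (Dirichlet at the bath temperature) or
#'   `"insulated"`.
#' @param bath_temperature Bath/boundary temperature (deg C), default 37.
#' @param initial_temperature Uniform initial temperature (deg C).
#' @return An object of class `thermal_field`: final temperature matrix
#'   `T_final` (deg C), per-step times and chamber-mean series, the
#'   volume-integrated source power, and the grid.
#' @export
solve_bht <- function(grid, media, source, dt = 0.5,
                      boundary = c("bath", "insulated"),
                      bath_temperature = 37.0,
                      initial_temperature = 37.0) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(grid, "sim_grid"), inherits(source, "heat_source"))
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  sched <- source$schedule
  mats <- media_arrays(grid, media, frequency = 1e6)  # k, rho, Cp only
  th <- assemble_thermal(grid, mats)
  nr <- grid$nr; nz <- grid$nz; n <- nr * nz

  bmask <- matrix(FALSE, nr, nz)
  if (boundary == "bath") {
    bmask[nr, ] <- TRUE
    bmask[, 1L] <- TRUE
    bmask[, nz] <- TRUE
  }
  fixed <- which(as.vector(bmask))
  free <- setdiff(seq_len(n), fixed)

  Kff <- th$K[free, free, drop = FALSE]
  A <- Kff + Matrix::Diagonal(length(free), th$capacity[free] / dt)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  # constant boundary contribution
  b_bc <- if (length(fixed)) {
    -as.vector(th$K[free, fixed, drop = FALSE] %*%
                 rep(bath_temperature, length(fixed)))
  } else 0
  Qv <- as.vector(source$Q) * th$vol   # W per node (per radian)

  nstep <- max(1L, ceiling(sched$total_time / dt))
  dt_last <- sched$total_time - (nstep - 1L) * dt
  Tvec <- rep(initial_temperature, n)
  Tvec[fixed] <- bath_temperature
  times <- numeric(nstep)
  cham <- as.vector(grid$mask == "chamber")
  wc <- th$vol[cham]
  chamber_mean <- numeric(nstep)
  absorbed <- 0  # time-integrated source power (J per radian)
  t_now <- 0
  for (s in seq_len(nstep)) {
    h <- if (s == nstep && dt_last > 1e-12) dt_last else dt
    fr <- if (sched$mode == "explicit") {
      on_fraction(t_now, t_now + h, sched$period, sched$on_time)
    } else 1
    if (abs(h - dt) > 1e-12) {
      Ah <- Kff + Matrix::Diagonal(length(free), th$capacity[free] / h)
      chh <- Matrix::Cholesky(Matrix::forceSymmetric(Ah), LDL = FALSE)
    } else chh <- ch
    rhs <- th$capacity[free] / h * Tvec[free] + fr * Qv[free] + b_bc
    Tvec[free] <- as.vector(Matrix::solve(chh, rhs))
    if (any(!is.finite(Tvec))) {
      stop(sprintf("bioheat solve became non-finite at t = %.4g s (dt = %g s)",
                   t_now + h, dt), call. = FALSE)
    }
    absorbed <- absorbed + fr * sum(Qv) * h
    t_now <- t_now + h
    times[s] <- t_now
    chamber_mean[s] <- sum(Tvec[cham] * wc) / sum(wc)
  }
  structure(
    list(T_final = matrix(Tvec, nr, nz), times = times,
         chamber_mean = chamber_mean, grid = grid,
         absorbed_energy = absorbed * 2 * pi,   # J (full revolution)
         boundary = boundary, dt = dt,
         initial_temperature = initial_temperature,
         bath_temperature = bath_temperature),
    class = "thermal_field"
  )
}

#' @export
print.thermal_field <- function(x, ...) {
  cat(sprintf("<thermal_field> t = %.4g s in %d steps (dt = %g s)\n",
              max(x$times), length(x$times), x$dt))
  cat(sprintf("  final chamber mean = %.3f C, domain max = %.3f C\n",
              utils::tail(x$chamber_mean, 1), max(x$T_final)))
  invisible(x)
}

#' Volume-averaged chamber temperature
#'
#' Volume-weighted mean over the GNP-chamber nodes (axisymmetric 2 pi r
#' weights) of the final saved temperature field.
#'
#' @param field A [solve_bht()] result, or a temperature matrix.
#' @param grid Required when `field` is a bare matrix.
#' @return Mean chamber temperature (deg C).
#' @export
chamber_mean_temperature <- function(field, grid = NULL) {
  if (inherits(field, "thermal_field")) {
    Tm <- field$T_final
    grid <- field$grid
  } else {
    Tm <- field
    if (is.null(grid)) stop("grid required for a bare matrix", call. = FALSE)
  }
  cham <- grid$mask == "chamber"
  if (!any(cham)) stop("chamber region is empty", call. = FALSE)
  w <- grid$vol[cham]
  sum(Tm[cham] * w) / sum(w)
}

#' Total enthalpy of a temperature field relative to a reference
#'
#' sum over nodes of rho C (T - T_ref) dV for the full revolution; used
#' for energy-conservation checks in insulated domains.
#'
#' @param field A `thermal_field`.
#' @param media Named list of [medium()] objects.
#' @param reference Reference temperature (deg C).
#' @return Enthalpy difference (J).
#' @export
enthalpy_gain <- function(field, media, reference = NULL) {
  stopifnot(inherits(field, "thermal_field"))
  if (is.null(reference)) reference <- field$initial_temperature
  grid <- field$grid
  mats <- media_arrays(grid, media, frequency = 1e6)
  th <- assemble_thermal(grid, mats)
  2 * pi * sum(th$capacity * as.vector(field$T_final - reference))
}
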