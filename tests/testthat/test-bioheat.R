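test_that("pulse schedule validates its window and Rect on-fractions are exact", {
  expect_error(pulse_schedule(on_time = 2e-3, period = 1e-3), "on_time")
  expect_error(pulse_schedule(on_time = 0, period = 1e-3), "on_time")
  sch <- pulse_schedule(on_time = 0.5e-3, period = 1e-3, total_time = 1)
  expect_equal(sch$mode, "averaged")
  # exact on-fraction bookkeeping over awkward step boundaries
  f <- lipusdlvo:::on_fraction
  expect_equal(f(0, 1e-3, 1e-3, 0.5e-3), 0.5)
  expect_equal(f(0, 0.25e-3, 1e-3, 0.5e-3), 1)
  expect_equal(f(0.75e-3, 1.25e-3, 1e-3, 0.5e-3), 0.5)
  expect_equal(f(0, 10e-3, 1e-3, 0.4e-3), 0.4)
})

test_that("heat source is 2 alpha I with duty counted exactly once", {
  grid <- coarse_grid()
  media <- baseline_media()
  # alpha = 8.98 Np/m, I = 2.72e4 W/m2 -> 4.885e5 W/m3 continuous-wave
  intens <- uniform_intensity(grid, I = 2.72e4)
  cw <- heat_source(intens, media,
                    pulse_schedule(1e-3, 1e-3, 60, "averaged"))
  expect_equal(max(cw$Q[grid$mask == "tissue"]), 4.885e5, tolerance = 1e-3)
  # zero attenuation -> zero source
  wat <- all_water_media(0)
  expect_equal(max(heat_source(intens, wat,
                               pulse_schedule(1e-3, 1e-3, 60))$Q), 0)
  # averaged 50% duty halves the CW source everywhere
  half <- heat_source(intens, media,
                      pulse_schedule(0.5e-3, 1e-3, 60, "averaged"))
  expect_equal(half$Q, cw$Q * 0.5)
  # double-counting guards
  folded <- uniform_intensity(grid, I = 1.36e4, duty_folded = TRUE, duty = 0.5)
  expect_error(heat_source(folded, media,
                           pulse_schedule(0.5e-3, 1e-3, 60, "explicit")),
               "double-count")
  expect_error(heat_source(folded, media,
                           pulse_schedule(0.4e-3, 1e-3, 60, "averaged")),
               "disagree")
  same <- heat_source(folded, media,
                      pulse_schedule(0.5e-3, 1e-3, 60, "averaged"))
  expect_equal(max(same$Q[grid$mask == "tissue"]), 4.885e5 / 2,
               tolerance = 1e-3)
})

test_that("zero source stays at equilibrium and positive source obeys the maximum principle", {
  grid <- coarse_grid()
  media <- baseline_media()
  sch <- pulse_schedule(0.5e-3, 1e-3, 10, "averaged")
  zero <- heat_source(uniform_intensity(grid, I = 0), media, sch)
  th <- solve_bht(grid, media, zero, dt = 1)
  expect_equal(max(abs(th$T_final - 37)), 0)
  expect_equal(chamber_mean_temperature(th), 37)
  hot <- heat_source(uniform_intensity(grid, I = 5e4), media, sch)
  th2 <- solve_bht(grid, media, hot, dt = 1)
  expect_gte(min(th2$T_final), 37)
  expect_gt(chamber_mean_temperature(th2), 37)
})

test_that("insulated uniform heating matches the adiabatic closed form and conserves energy", {
  grid <- coarse_grid()
  media <- all_water_media()
  sch <- pulse_schedule(1e-3, 1e-3, 60, "averaged")
  src <- heat_source(uniform_intensity(grid), media, sch)
  src$Q <- matrix(1e5, grid$nr, grid$nz)    # uniform synthetic source
  th <- solve_bht(grid, media, src, dt = 0.5, boundary = "insulated")
  dT_exact <- 1e5 * 60 / (994.23 * 4178)    # Q t / (rho C) = 1.4444 C
  expect_equal(range(th$T_final - 37), rep(dT_exact, 2), tolerance = 1e-6)
  # energy conservation for a non-uniform source
  set.seed(7)
  src$Q <- matrix(runif(grid$nr * grid$nz, 0, 2e5), grid$nr, grid$nz)
  th2 <- solve_bht(grid, media, src, dt = 0.5, boundary = "insulated")
  expect_equal(enthalpy_gain(th2, media) / th2$absorbed_energy, 1,
               tolerance = 5e-3)
})

test_that("explicit Rect pulsing and the duty-averaged source agree on chamber mean", {
  grid <- coarse_grid(4)
  media <- baseline_media()
  I <- uniform_intensity(grid, I = 5e5)
  ex <- solve_bht(grid, media,
                  heat_source(I, media,
                              pulse_schedule(0.5e-3, 1e-3, 1, "explicit")),
                  dt = 1e-4)
  av <- solve_bht(grid, media,
                  heat_source(I, media,
                              pulse_schedule(0.5e-3, 1e-3, 1, "averaged")),
                  dt = 0.05)
  expect_gt(chamber_mean_temperature(av), 37.01)  # non-trivial heating
  expect_lt(abs(chamber_mean_temperature(ex) - chamber_mean_temperature(av)),
            0.05)
})

test_that("chamber average is the exact volume-weighted mean", {
  grid <- coarse_grid()
  Tm <- matrix(37, grid$nr, grid$nz)
  expect_equal(chamber_mean_temperature(Tm, grid), 37)
  # linear-in-z field: cylinder average is the value at the mid-plane
  Tm <- matrix(rep(30 + 500 * grid$z, each = grid$nr), grid$nr, grid$nz)
  z_mid <- mean(grid$geometry$chamber_z)
  # grid snapping moves the sampled chamber slab by at most half a cell
  expect_equal(chamber_mean_temperature(Tm, grid), 30 + 500 * z_mid,
               tolerance = 500 * grid$dz / 2 / (30 + 500 * z_mid))
  empty <- grid
  empty$mask[empty$mask == "chamber"] <- "water"
  expect_error(chamber_mean_temperature(Tm, empty), "empty")
})
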