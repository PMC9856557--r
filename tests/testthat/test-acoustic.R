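test_that("piston source amplitude is rho c omega d", {
  water <- water_medium()
  p0 <- source_pressure_amplitude(water, 2 * pi * 1e6, 24.944e-9)
  expect_equal(p0 / 1e6, 0.23695, tolerance = 1e-4)
  expect_equal(source_pressure_amplitude(water, 2 * pi * 1e6, 0), 0)
  expect_equal(source_pressure_amplitude(water, 2 * pi * 1e6, 2 * 24.944e-9),
               2 * p0)
})

test_that("on-axis piston reference has the closed-form limits", {
  p0 <- 1e5
  a_t <- 6e-3
  k <- 2 * pi / 1.5206e-3
  # face value by direct substitution
  expect_equal(onaxis_piston_reference(0, p0, k, a_t),
               2 * p0 * abs(sin(k * a_t / 2)))
  # last axial maximum reaches 2 p0
  z_star <- (a_t^2 - (pi / k)^2) / (2 * pi / k)  # sqrt(z^2+a^2)-z = lambda/2
  expect_equal(onaxis_piston_reference(z_star, p0, k, a_t), 2 * p0,
               tolerance = 1e-10)
  # far-field decay toward p0 k a^2 / (2 z)
  z <- 5    # 5 m >> a^2/lambda
  expect_equal(onaxis_piston_reference(z, p0, k, a_t),
               p0 * k * a_t^2 / (2 * z), tolerance = 1e-3)
  expect_error(onaxis_piston_reference(-1e-3, p0, k, a_t), "z")
})

test_that("a full-width piston in uniform water radiates a unit-amplitude plane wave", {
  media <- all_water_media()
  grid <- coarse_grid()
  # element wider than the domain: plane-piston limit
  set <- transducer_setting(1e6, 40e-3, 24.944e-9, 8.4, 0.5)
  f <- solve_helmholtz(grid, media, set)
  p0 <- source_pressure_amplitude(media$water, 2 * pi * 1e6, set$displacement)
  interior <- grid$z <= grid$geometry$interior_depth - 2e-3
  ratios <- Mod(f$p[1, interior]) / p0
  expect_true(all(abs(ratios - 1) < 0.01))
})

test_that("zero displacement gives an identically zero field", {
  media <- all_water_media()
  grid <- coarse_grid()
  set <- transducer_setting(1e6, 10e-3, 0, 0, 0.5)
  f <- solve_helmholtz(grid, media, set)
  expect_equal(max(Mod(f$p)), 0)
})

test_that("on-axis field matches the Rayleigh closed form in lossless water", {
  # smooth (post-null) window at moderate resolution; the sharp near-field
  # nulls converge more slowly and are covered by the acceptance suite
  media <- all_water_media(attenuation = 0)
  geom <- axisym_geometry(water_radius = 18e-3, standoff = 5e-3,
                          tissue_radius = 6e-3, tissue_height = 5e-3,
                          chamber_radius = 2e-3, chamber_height = 2e-3,
                          water_below = 15e-3, pml_thickness = 3e-3)
  lam <- 1520.6 / 1e6
  grid <- build_grid(geom, lam, 10)
  a_t <- 3e-3
  set <- transducer_setting(1e6, 2 * a_t, 24.944e-9, 8.4, 1)
  f <- solve_helmholtz(grid, media, set)
  p0 <- source_pressure_amplitude(media$water, 2 * pi * 1e6, set$displacement)
  k <- 2 * pi / lam
  win <- which(grid$z >= a_t^2 / (2 * lam) & grid$z <= geom$interior_depth)
  ref <- onaxis_piston_reference(grid$z[win], p0, k, a_t)
  num <- Mod(f$p[1, win])
  expect_lt(max(abs(num - ref)) / max(ref), 0.08)
  # on-axis peak amplitude is accurate to 2%
  expect_equal(max(num), max(ref), tolerance = 0.02)
})

test_that("intensity is |p|^2/(2 rho c) with single-counted duty folding", {
  media <- all_water_media()
  grid <- coarse_grid()
  set <- transducer_setting(1e6, 40e-3, 24.944e-9, 8.4, 0.5)
  f <- solve_helmholtz(grid, media, set)
  # hand value: 0.32 MPa in water -> 3.39 W/cm^2
  f2 <- f
  f2$p[] <- 0.32e6
  I_def <- intensity_from_pressure(f2, media)
  expect_false(I_def$duty_folded)
  expect_equal(I_def$I[1, 1] / 1e4, 3.3866, tolerance = 1e-4)
  # duty folding halves every node
  I_fold <- intensity_from_pressure(f2, media, duty = 0.5)
  expect_true(I_fold$duty_folded)
  expect_equal(I_fold$I, I_def$I * 0.5)
  # zero pressure -> zero intensity
  f2$p[] <- 0
  expect_equal(max(intensity_from_pressure(f2, media)$I), 0)
  expect_true(all(I_def$I >= 0))
})

test_that("field export writes one finite row per node", {
  media <- all_water_media()
  grid <- coarse_grid(4)
  set <- transducer_setting(1e6, 10e-3, 24.944e-9, 8.4, 0.5)
  f <- solve_helmholtz(grid, media, set)
  intens <- intensity_from_pressure(f, media)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_field(f, intens, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), grid$nr * grid$nz)
  expect_true(all(is.finite(tab$abs_p)))
  expect_equal(tab$abs_p, sqrt(tab$re_p^2 + tab$im_p^2), tolerance = 1e-12)
})
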