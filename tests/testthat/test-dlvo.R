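test_that("water permittivity polynomial matches handbook values and decreases with T", {
  expect_equal(water_relative_permittivity(298.15), 78.303, tolerance = 1e-4)
  expect_equal(water_relative_permittivity(310.15), 74.152, tolerance = 1e-4)
  ts <- seq(274, 372, by = 1)
  expect_true(all(diff(water_relative_permittivity(ts)) < 0))
  expect_error(water_relative_permittivity(273.15), "range")
  expect_error(water_relative_permittivity(400), "range")
})

test_that("Debye length reproduces the suspension value and scales as 1/sqrt(I)", {
  eps <- water_relative_permittivity(310.15) * physical_constants()$eps0
  d <- inverse_debye_length(0.4052, 310.15, eps)
  expect_equal(d$lambda_D * 1e9, 14.98, tolerance = 1e-3)
  expect_equal(d$kappa * 3.7e-9, 0.247, tolerance = 1e-2)  # passes ka < 5
  d4 <- inverse_debye_length(4 * 0.4052, 310.15, eps)
  expect_equal(d4$lambda_D, d$lambda_D / 2)
  expect_error(inverse_debye_length(-1, 310.15, eps), "> 0")
})

test_that("van der Waals potential matches the hand-evaluated bracket and its limits", {
  a <- 3.7e-9
  AH <- 2.5e-19
  # x = 0.5 -> bracket 0.0689, V = -1.435e-21 J
  expect_equal(vdw_potential(a, a, AH), -1.4348e-21, tolerance = 1e-4)
  # attractive everywhere, monotone toward zero from below
  h <- dlvo_h_grid(0.1e-9, 500e-9, 3000)
  V <- vdw_potential(h, a, AH)
  expect_true(all(V < 0))
  expect_true(all(diff(V) > 0))
  expect_equal(vdw_potential(500e-9, a, AH), 0, tolerance = 1e-25)
  # linear in the Hamaker constant
  expect_equal(vdw_potential(h, a, 2 * AH), 2 * V)
  expect_error(vdw_potential(0, a, AH), "singularity")
})

test_that("reduced surface potential Y matches direct evaluation and its limits", {
  const <- physical_constants()
  T_K <- 310.15
  kappa <- 0.247 / 3.7e-9
  expect_equal(reduced_surface_potential_Y(0, T_K, kappa, 3.7e-9), 0)
  Y <- reduced_surface_potential_Y(-30.29e-3, T_K, kappa, 3.7e-9)
  expect_equal(abs(Y), 1.1249, tolerance = 1e-3)
  expect_lt(Y, 0)  # carries the sign of zeta
  # small-potential limit: Y -> e psi0 / (kB T)
  psi <- -1e-5
  expect_equal(reduced_surface_potential_Y(psi, T_K, kappa, 3.7e-9),
               const$e * psi / (const$k_B * T_K), tolerance = 1e-4)
  expect_error(reduced_surface_potential_Y(-30e-3, T_K, 2e9, 3.7e-9),
               "kappa")
})

test_that("electrostatic potential is screened, repulsive, and zero without charge", {
  susp <- baseline_suspension(zeta = -30.29e-3)
  deb <- inverse_debye_length(susp$ionic_strength, susp$temperature,
                              susp$permittivity)
  Y <- reduced_surface_potential_Y(susp$zeta, susp$temperature, deb$kappa,
                                   susp$radius)
  kBT <- physical_constants()$k_B * susp$temperature
  expect_equal(electrostatic_potential(5e-9, susp, deb$kappa, Y) / kBT,
               1.377, tolerance = 1e-3)
  expect_equal(electrostatic_potential(500e-9, susp, deb$kappa, Y), 0,
               tolerance = 1e-25)
  expect_equal(electrostatic_potential(5e-9, susp, deb$kappa, 0), 0)
  h <- dlvo_h_grid()
  V <- electrostatic_potential(h, susp, deb$kappa, Y)
  expect_true(all(V >= 0))
  expect_true(all(diff(V) < 0))
})

test_that("curve components keep their signs, sum pointwise, and vanish at infinity", {
  for (zeta in c(-30.3e-3, -15.8e-3, -40e-3)) {
    susp <- baseline_suspension(zeta = zeta)
    cur <- compute_curve(susp)
    tab <- cur$table
    expect_true(all(tab$Vvdw <= 0))
    expect_true(all(diff(tab$Vvdw) > 0))
    expect_true(all(tab$Velec >= 0))
    expect_true(all(diff(tab$Velec) <= 0))
    expect_equal(tab$Vdlvo, tab$Vvdw + tab$Velec)
    expect_equal(tab$Vdlvo_kBT, tab$Vdlvo / cur$kBT)
    expect_lt(abs(tab$Vdlvo_kBT[nrow(tab)]), 1e-3)
  }
  # no interactions at all: identically zero total
  susp0 <- gnp_suspension(3.7e-9, 1e-30, 0, 0.4052, 37)
  cur0 <- compute_curve(susp0)
  expect_lt(max(abs(cur0$table$Vdlvo_kBT)), 1e-9)
  expect_error(compute_curve(baseline_suspension(), h = c(2e-9, 1e-9)),
               "increasing")
})

test_that("barrier finder agrees with a dense brute-force grid on random suspensions", {
  set.seed(42)
  h_dense <- seq(0.1e-9, 100e-9, length.out = 1e6)
  for (i in 1:20) {
    susp <- gnp_suspension(runif(1, 2e-9, 8e-9), runif(1, 1e-19, 4e-19),
                           -runif(1, 5e-3, 45e-3), runif(1, 0.1, 2),
                           runif(1, 20, 60))
    cur <- compute_curve(susp)
    expect_lt(cur$kappa * susp$radius, 5)
    bar <- find_energy_barrier(cur)
    dense <- max(vdw_potential(h_dense, susp$radius, susp$hamaker) +
                   electrostatic_potential(h_dense, susp, cur$kappa, cur$Y))
    expect_lt(abs(max(dense, 0) / cur$kBT - bar$height), 1e-3)
  }
})

test_that("an uncharged suspension has no barrier", {
  susp <- baseline_suspension(zeta = 0)
  bar <- find_energy_barrier(compute_curve(susp))
  expect_false(bar$exists)
  expect_equal(bar$height, 0)
  expect_true(predict_release(bar))
})

test_that("percent change and release threshold behave as defined", {
  expect_equal(percent_change(1.36, 0.24), 82.353, tolerance = 1e-4)
  expect_equal(percent_change(-30.29e-3, -15.79e-3), 47.871, tolerance = 1e-4)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "nonzero")
  # boundary inclusive: barrier equal to the threshold releases
  expect_true(predict_release(0.24, threshold = 0.24))
  expect_false(predict_release(1.36, threshold = 0.24))
  expect_true(predict_release(0))
  expect_error(predict_release(0.2, threshold = 0), "threshold")
  # calibration is the identity on the observed release barrier
  expect_equal(calibrate_threshold(0.24), 0.24)
  expect_equal(calibrate_threshold(calibrate_threshold(0.24)), 0.24)
})

test_that("permittivity override is honoured and flagged", {
  susp <- gnp_suspension(3.7e-9, 2.5e-19, -30.3e-3, 0.4052, 37,
                         permittivity = 1.26e-9)
  expect_true(susp$permittivity_overridden)
  expect_equal(susp$permittivity, 1.26e-9)
  auto <- baseline_suspension()
  expect_false(auto$permittivity_overridden)
  expect_equal(auto$permittivity,
               water_relative_permittivity(310.15) * physical_constants()$eps0)
})
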