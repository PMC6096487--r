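# Core model types, unit conversions and cell mathematics.

test_that("electron wavelength matches the relativistic closed form", {
  # printed instrument value
  expect_equal(wavelength_from_kv(200), 0.02508, tolerance = 5e-5 / 0.02508)
  # independent evaluation of the closed form (CODATA constants, coded here
  # without reference to the implementation)
  lam_ref <- function(kv) {
    h <- 6.62607015e-34; m0 <- 9.1093837015e-31
    e <- 1.602176634e-19; c <- 299792458
    V <- kv * 1e3
    1e10 * h / sqrt(2 * m0 * e * V * (1 + e * V / (2 * m0 * c^2)))
  }
  for (kv in c(100, 200, 300))
    expect_equal(wavelength_from_kv(kv), lam_ref(kv), tolerance = 1e-6)
  # strictly decreasing with accelerating voltage
  expect_true(wavelength_from_kv(100) > wavelength_from_kv(200))
  expect_true(wavelength_from_kv(200) > wavelength_from_kv(300))
  expect_error(wavelength_from_kv(-1), "invalid")
})

test_that("X-ray wavelength conversion is hc/(eE)", {
  expect_equal(xray_wavelength_from_kev(12), 1.0332, tolerance = 1e-4)
  expect_equal(xray_wavelength_from_kev(12.398419), 1.0, tolerance = 1e-6)
  expect_equal(xray_wavelength_from_kev(6), 2 * xray_wavelength_from_kev(12))
  expect_error(xray_wavelength_from_kev(0), "invalid")
})

test_that("metrical matrix round-trips the unit cell", {
  expect_equal(metrical_from_cell(c(10, 10, 10, 90, 90, 90)),
               diag(0.01, 3), tolerance = 1e-12)
  g <- metrical_from_cell(c(32, 68, 105, 90, 90, 90))
  expect_equal(diag(g), c(1 / 32^2, 1 / 68^2, 1 / 105^2), tolerance = 1e-12)
  expect_equal(max(abs(g - diag(diag(g)))), 0, tolerance = 1e-18)
  set.seed(101)
  for (i in 1:1000) {
    cell <- random_cell()
    expect_equal(cell_from_metrical(metrical_from_cell(cell)), cell,
                 tolerance = 1e-9)
  }
  expect_error(metrical_from_cell(c(10, 10, 10, 1, 1, 170)), "invalid")
  expect_error(cell_from_metrical(matrix(0, 3, 3)), "invalid")
})

test_that("free metrical elements follow the lattice constraint", {
  expect_equal(free_metrical_elements("orthorhombic"), c("g11", "g22", "g33"))
  expect_length(free_metrical_elements("triclinic"), 6)
  expect_length(free_metrical_elements("cubic"), 1)
  expect_error(free_metrical_elements("rhombic"))
})

test_that("rotation operator is a proper right-handed rotation group", {
  e <- c(0.3, -0.5, 0.81)
  e <- e / sqrt(sum(e^2))
  expect_equal(rotation_about_axis(e, 0), diag(3), tolerance = 1e-14)
  expect_equal(rotation_about_axis(e, 360), diag(3), tolerance = 1e-12)
  A <- rotation_about_axis(e, 37.5) %*% rotation_about_axis(e, 14.2)
  expect_equal(A, rotation_about_axis(e, 51.7), tolerance = 1e-12)
  # right-handed: +90 deg about z maps x to y
  expect_equal(as.numeric(rotation_about_axis(c(0, 0, 1), 90) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  expect_error(rotation_about_axis(c(0, 0, 0), 10), "invalid")
})

test_that("model constructors reject violated invariants", {
  expect_error(beam_model(c(0, 0, 2), 0.02508), "unit")
  expect_error(beam_model(c(0, 0, 1), -1), "invalid")
  expect_error(panel_model(c(0, 0, 100), c(1, 0, 0), c(1, 0, 0),
                           c(0.055, 0.055), c(10, 10)), "orthogonal")
  expect_error(panel_model(c(0, 0, 100), c(1, 0, 0), c(0, 1, 0),
                           c(-1, 1), c(10, 10)), "invalid")
  expect_error(goniometer_model(c(1, 1, 0)), "unit")
  expect_error(scan_model(c(5, 1), c(0, 0.1)), "invalid")
  expect_error(scan_model(c(1, 5), c(0, 0)), "invalid")
  expect_error(crystal_model(2 * diag(3), diag(0.01, 3)), "rotation")
  expect_error(crystal_model(diag(3), -diag(0.01, 3)), "positive definite")
  expect_error(detector_model(list()), "non-empty")
})

test_that("scan-varying states attach to the experiment model", {
  sim <- small_sim("ED")
  res <- refine_geometry(sim$experiment, sim$reflections,
                         fix = c("dist", "tau2", "tau3"), scan_varying = TRUE,
                         max_iterations = 5)
  sv <- res$experiment$scan_varying
  expect_true(all(c("phi1", "phi2", "phi3") %in% names(sv)))
  nz <- sim$experiment$scan$image_range[2]
  for (s in sv) {
    expect_equal(s$positions[1], 0)
    expect_equal(s$positions[s$n_samples], nz)
  }
})
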