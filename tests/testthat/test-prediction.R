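# Ewald construction: scattering angles, crossing angles, centroid
# prediction and reciprocal-space mapping.

test_that("two_theta reproduces the Ewald-construction angles", {
  expect_equal(two_theta(1.0, 1.0332), 62.2, tolerance = 0.05 / 62.2)
  expect_equal(two_theta(1.0, 0.02508), 1.44, tolerance = 0.005 / 1.44)
  expect_equal(two_theta(1.0, 1e-9), 0, tolerance = 1e-6)
  expect_equal(two_theta(1.0, 2.0), 180)
  expect_error(two_theta(1.0, 2.5), "no_solution")
  # strictly increasing in 1/d at fixed lambda, and in lambda at fixed d
  d <- seq(1, 5, by = 0.5)
  expect_true(all(diff(two_theta(rev(d), 1.0332)) > 0))
  lam <- seq(0.01, 1.9, by = 0.1)
  expect_true(all(diff(two_theta(1.0, lam)) > 0))
})

test_that("crossing angles satisfy a brute-force bracketing oracle", {
  set.seed(12)
  beam <- beam_model(c(0, 0, 1), 1.0332)
  gon <- goniometer_model(c(1, 0, 0))
  cry <- crystal_model(rotation_about_axis(c(0.2, 0.5, 0.84), 33),
                       metrical_from_cell(c(11, 17, 23, 90, 101, 90)),
                       "monoclinic")
  s0 <- beam$direction / beam$wavelength
  for (hkl in list(c(1, 0, 0), c(0, 2, 1), c(-2, 1, 3), c(1, -1, -1))) {
    ph <- ewald_crossing_angles(cry, beam, gon, hkl)
    # brute-force scan of the Ewald residual in 0.001-degree steps
    r0 <- edgeom:::ub_matrix(cry) %*% hkl
    grid <- seq(0, 360, by = 0.001)
    f <- function(phi) {
      r <- edgeom:::.rot_cols(matrix(r0, 3, length(phi)), c(1, 0, 0),
                              phi * pi / 180)
      sqrt(colSums((r + s0)^2)) - 1 / beam$wavelength
    }
    vals <- f(grid)
    sgn <- which(diff(sign(vals)) != 0)
    expect_equal(length(ph), length(sgn))
    for (p in ph) {
      k <- which.min(abs(grid[sgn] - p))
      expect_lt(abs(grid[sgn][k] - p), 0.002)
    }
  }
})

test_that("reflections along the rotation axis never cross (blind region)", {
  beam <- beam_model(c(0, 0, 1), 0.02508)
  gon <- goniometer_model(c(1, 0, 0))
  cry <- crystal_model(diag(3), metrical_from_cell(c(10, 10, 10, 90, 90, 90)),
                       "cubic")
  expect_length(ewald_crossing_angles(cry, beam, gon, c(3, 0, 0)), 0)
  expect_error(ewald_crossing_angles(cry, beam, gon, c(0, 0, 0)), "invalid")
})

test_that("crossing-angle differences reproduce the X-ray and ED rows", {
  # X-ray: h = 1 calibrated to 15.0 deg; h = 5 crosses at 27.0 deg
  exx <- row_experiment(1.0332, 100)
  h1 <- min(ewald_crossing_angles(exx$crystal, exx$beam, exx$goniometer,
                                  c(0, 1, 0)))
  h5 <- min(ewald_crossing_angles(exx$crystal, exx$beam, exx$goniometer,
                                  c(0, 5, 0)))
  expect_equal(h1, 15.0, tolerance = 1e-6)
  expect_equal(h5, 27.0, tolerance = 0.05 / 27.0)
  # ED: h = 1 calibrated to 12.1 deg; h = 5 crosses at 12.4 deg
  exe <- row_experiment(0.02508, 2000, first_phi = 12.1)
  e5 <- min(ewald_crossing_angles(exe$crystal, exe$beam, exe$goniometer,
                                  c(0, 5, 0)))
  expect_equal(e5, 12.4, tolerance = 0.05 / 12.4)
})

test_that("crossing-angle differences are invariant under crystal pre-rotation", {
  set.seed(9)
  beam <- beam_model(c(0, 0, 1), 1.0332)
  gon <- goniometer_model(c(1, 0, 0))
  base <- crystal_model(diag(3), metrical_from_cell(c(10, 10, 10, 90, 90, 90)),
                        "cubic")
  ref <- min(ewald_crossing_angles(base, beam, gon, c(0, 5, 0))) -
    min(ewald_crossing_angles(base, beam, gon, c(0, 1, 0)))
  for (i in 1:10) {
    off <- stats::runif(1, 0, 360)
    cry <- crystal_model(rotation_about_axis(c(1, 0, 0), off) %*% base$U,
                         base$g_star, "cubic")
    ph1 <- ewald_crossing_angles(cry, beam, gon, c(0, 1, 0))
    ph5 <- ewald_crossing_angles(cry, beam, gon, c(0, 5, 0))
    # compare the crossing pair with the matching separation
    d <- outer(ph5, ph1, function(a, b) (a - b) %% 360)
    expect_true(any(abs(d - ref) < 1e-6))
  }
})

test_that("predicted centroids satisfy the Ewald condition and geometry checks", {
  sim <- quiet_ed_sim()
  ex <- sim$experiment
  refl <- sim$reflections
  s0 <- ex$beam$direction / ex$beam$wavelength
  r0 <- edgeom:::ub_matrix(ex$crystal) %*% t(as.matrix(refl[, c("h", "k", "l")]))
  r <- edgeom:::.rot_cols(r0, ex$goniometer$rotation_axis,
                          refl$phi_calc * pi / 180)
  resid <- abs(sqrt(colSums((r + s0)^2)) - 1 / ex$beam$wavelength) *
    ex$beam$wavelength
  expect_lt(max(resid), 1e-8)

  # direct-beam test ray lands at the calibrated beam centre pixel
  pan <- ex$detector$panels[[1]]
  hit <- edgeom:::.intersect_panels(ex$detector, matrix(s0, 3, 1))
  expect_equal(c(hit$x, hit$y), pan$n_pixels / 2, tolerance = 1e-9)

  # doubling the effective distance doubles the mm offsets (small angles)
  ex2 <- ex
  pan2 <- pan
  pan2$origin <- pan$origin * c(2, 2, 2)
  pan2$n_pixels <- pan$n_pixels * 2L
  ex2$detector <- detector_model(pan2)
  p1 <- predict_centroids(ex, refl[, c("h", "k", "l")])
  p2 <- predict_centroids(ex2, refl[, c("h", "k", "l")])
  m <- merge(as.data.frame(p1), as.data.frame(p2), by = c("h", "k", "l"))
  off1 <- sqrt((m$x_calc.x - 512)^2 + (m$y_calc.x - 512)^2)
  off2 <- sqrt((m$x_calc.y - 1024)^2 + (m$y_calc.y - 1024)^2)
  expect_lt(max(abs(off2 / off1 - 2)), 0.002)
})

test_that("reciprocal-space mapping distinguishes handedness only for X-rays", {
  # phi = 0 observations are returned unrotated
  sim <- quiet_ed_sim()
  obs1 <- sim$reflections[1:5, ]
  obs1$phi_obs <- 0
  pan <- sim$experiment$detector$panels[[1]]
  mm <- px_to_mm(pan, obs1$x_obs, obs1$y_obs)
  s0 <- sim$experiment$beam$direction / sim$experiment$beam$wavelength
  expected <- t(sapply(seq_len(5), function(i) {
    P <- pan$origin + mm$fast[i] * pan$fast_axis + mm$slow[i] * pan$slow_axis
    P / sqrt(sum(P^2)) / sim$experiment$beam$wavelength - s0
  }))
  expect_equal(map_to_reciprocal_space(obs1, sim$experiment), expected,
               tolerance = 1e-12)

  # collinear row h = 1..5 with standard centroid noise, averaged over
  # seeded realisations: X-ray inversion bends the row (> 10x), ED does
  # not (< 2x)
  ratio <- function(lambda, dist) {
    ex <- row_experiment(lambda, dist)
    pred <- predict_centroids(ex, cbind(0, 1:5, 0))
    fw <- iv <- numeric(20)
    for (s in 1:20) {
      set.seed(s)
      obs <- pred
      obs$x_obs <- obs$x_calc + stats::rnorm(5, 0, 0.3)
      obs$y_obs <- obs$y_calc + stats::rnorm(5, 0, 0.3)
      obs$phi_obs <- obs$phi_calc + stats::rnorm(5, 0, 0.02)
      fw[s] <- rms_from_line(map_to_reciprocal_space(obs, ex, FALSE))
      iv[s] <- rms_from_line(map_to_reciprocal_space(obs, ex, TRUE))
    }
    mean(iv) / mean(fw)
  }
  expect_gt(ratio(1.0332, 100), 10)
  expect_lt(ratio(0.02508, 2000), 2)
})

test_that("nearest-integer index assignment recovers simulation indices", {
  sim <- quiet_ed_sim()
  obs <- sim$reflections
  scrambled <- obs
  scrambled$h <- scrambled$k <- scrambled$l <- 0L
  fixed <- assign_indices(scrambled, sim$experiment)
  expect_equal(fixed$h, obs$h)
  expect_equal(fixed$k, obs$k)
  expect_equal(fixed$l, obs$l)
  expect_lt(attr(fixed, "fractional_rmsd"), 1e-6)
})
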