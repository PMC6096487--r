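# Parameterisation, residuals/Jacobian, restraints, the LM driver and
# outlier rejection.

test_that("default static parameterisation has the standard 13 parameters", {
  sim <- std_ed_sim()
  ps <- build_parameterisation(sim$experiment)
  expect_equal(n_free_parameters(ps), 13)
  expect_setequal(names(free_parameter_vector(ps)),
                  c("dist", "shift1", "shift2", "tau1", "tau2", "tau3",
                    "mu2", "phi1", "phi2", "phi3", "g11", "g22", "g33"))
  # stabilised protocol: fixing dist, tau2, tau3 leaves 10
  ps10 <- build_parameterisation(sim$experiment,
                                 fix = c("dist", "tau2", "tau3"))
  expect_equal(n_free_parameters(ps10), 10)
  # scan-varying counting: each free angle's static value is replaced by
  # its smoother samples; making the default-fixed spindle-axis beam angle
  # scan-varying unfixes it
  expect_equal(n_free_parameters(
    build_parameterisation(sim$experiment, scan_varying = list(mu2 = 2))), 14)
  expect_equal(n_free_parameters(
    build_parameterisation(sim$experiment,
                           scan_varying = list(mu1 = 2, mu2 = 2))), 16)
  expect_error(build_parameterisation(sim$experiment, fix = "tau9"),
               "valid labels")
  expect_error(build_parameterisation(sim$experiment,
                                      scan_varying = list(dist = 2)),
               "scan-varying")
})

test_that("residuals vanish at the simulation truth and Jacobian matches a
           5-point finite-difference oracle", {
  sim <- quiet_ed_sim()
  obs <- sim$reflections[seq(1, nrow(sim$reflections), by = 8), ]
  ps <- build_parameterisation(sim$experiment)
  b <- residuals_and_jacobian(ps, obs)
  expect_lt(max(abs(b$delta_r)), 1e-8)
  expect_equal(nrow(b$J), 3 * nrow(obs))
  expect_equal(unname(sapply(b$block_bounds, length)), rep(nrow(obs), 3))

  # independent 5-point central difference with a different step
  v0 <- free_parameter_vector(ps)
  for (k in c(1, 4, 7, 9, 11)) {
    h <- 5e-4 * edgeom:::parameter_scale(names(v0)[k])
    rs <- lapply(c(-2, -1, 1, 2), function(m) {
      v <- v0; v[k] <- v0[k] + m * h
      r <- edgeom:::.residual_vector(set_free_parameter_vector(ps, v), obs)
      as.numeric(r)
    })
    d5 <- (rs[[1]] - 8 * rs[[2]] + 8 * rs[[3]] - rs[[4]]) / (12 * h)
    expect_lt(sqrt(sum((b$J[, k] - d5)^2)) / sqrt(sum(d5^2)), 1e-5)
  }

  # detector parameters have no effect on the predicted rotation angle
  phiJ <- b$J[b$block_bounds$phi, 1:6]
  expect_equal(max(abs(phiJ)), 0)
  expect_error(residuals_and_jacobian(ps, obs[0, ]), "no usable")
})

test_that("unit-cell restraints add the stated pseudo-observations", {
  sim <- quiet_ed_sim()
  obs <- sim$reflections[1:80, ]
  ps <- build_parameterisation(sim$experiment)
  b <- residuals_and_jacobian(ps, obs)

  cell <- cell_from_metrical(sim$experiment$crystal$g_star)
  # at the target: zero residual (and finite gradient rows)
  spec0 <- restraint_spec(c("a", "b", "c"), cell[1:3], 0.1)
  b0 <- add_restraints(b, ps, spec0)
  expect_equal(max(abs(b0$restraints$r)), 0, tolerance = 1e-9)

  # sigma = 0.1, offset 0.2 A: contributed R_a = (1/0.01) * 0.04 = 4.0
  spec1 <- restraint_spec("a", cell[1] - 0.2, 0.1)
  b1 <- add_restraints(b, ps, spec1)
  expect_equal(sum(b1$restraints$r^2), 4.0, tolerance = 1e-9)

  # orthorhombic: all six requested, only the three lengths survive
  spec6 <- restraint_spec(c("a", "b", "c", "alpha", "beta", "gamma"),
                          c(cell[1:3], 90, 90, 90), 0.1)
  b6 <- add_restraints(b, ps, spec6)
  expect_equal(nrow(b6$restraints$J), 3)
  expect_setequal(b6$restraints$parameters, c("a", "b", "c"))

  # gradient rows match finite differences of R_a
  v0 <- free_parameter_vector(ps)
  for (k in which(grepl("^g", names(v0)))) {
    h <- 2e-4 * edgeom:::parameter_scale(names(v0)[k])
    Ra <- function(v) {
      p <- set_free_parameter_vector(ps, v)
      bb <- add_restraints(b, p, spec1)
      sum(bb$restraints$r^2)
    }
    vp <- v0; vp[k] <- v0[k] + h
    vm <- v0; vm[k] <- v0[k] - h
    fd <- (Ra(vp) - Ra(vm)) / (2 * h)
    analytic <- 2 * sum(b1$restraints$r * b1$restraints$J[, k])
    expect_equal(analytic, fd, tolerance = 1e-6 * max(1, abs(fd)))
  }

  # restraints are rejected for scan-varying cells
  ps_sv <- build_parameterisation(sim$experiment,
                                  scan_varying = list(g11 = 2, g22 = 2, g33 = 2))
  b_sv <- residuals_and_jacobian(ps_sv, obs)
  expect_error(add_restraints(b_sv, ps_sv, spec1), "static")
})

test_that("LM terminates immediately at a zero-residual start", {
  sim <- quiet_ed_sim()
  obs <- sim$reflections[1:150, ]
  ps <- build_parameterisation(sim$experiment)
  fit <- levenberg_marquardt(function(p) residuals_and_jacobian(p, obs), ps)
  expect_true(fit$converged)
  expect_equal(fit$n_iterations, 0)
  expect_equal(free_parameter_vector(fit$params), free_parameter_vector(ps))
  # the iteration cap defaults to 100
  expect_equal(eval(formals(levenberg_marquardt)$max_iterations), 100)
  expect_error(levenberg_marquardt(identity, ps, max_iterations = 0), "invalid")
})

test_that("noise-free refinement recovers perturbed parameters exactly", {
  sim <- quiet_ed_sim()
  ps_true <- build_parameterisation(sim$experiment,
                                    fix = c("dist", "tau2", "tau3"))
  v_true <- free_parameter_vector(ps_true)
  v0 <- v_true
  v0[c("phi1", "phi2", "phi3")] <- v_true[c("phi1", "phi2", "phi3")] + 2
  v0["mu2"] <- v_true["mu2"] + 1
  v0[c("g11", "g22", "g33")] <- v_true[c("g11", "g22", "g33")] / 1.002^2
  fit <- levenberg_marquardt(
    function(p) residuals_and_jacobian(p, sim$reflections),
    set_free_parameter_vector(ps_true, v0))
  expect_true(fit$converged)
  vf <- free_parameter_vector(fit$params)
  scales <- sapply(names(v_true), edgeom:::parameter_scale)
  expect_lt(max(abs(vf - v_true) / scales), 1e-4)
  # the weighted cost never increased on an accepted step
  acc <- fit$report[which(fit$report$accepted), "cost"]
  expect_true(all(diff(c(fit$report$cost[1], acc)) <= 0))
})

test_that("static refinement is unbiased over noise realisations", {
  truth <- NULL
  res <- matrix(NA_real_, 20, 10)
  for (i in seq_len(nrow(res))) {
    sim <- simulate_reflections(simulation_spec("ED", d_min = 4, n_images = 25,
                                                seed = 100 + i))
    ps <- build_parameterisation(sim$experiment,
                                 fix = c("dist", "tau2", "tau3"))
    if (is.null(truth)) truth <- free_parameter_vector(ps)
    fit <- levenberg_marquardt(
      function(p) residuals_and_jacobian(p, sim$reflections), ps)
    res[i, ] <- free_parameter_vector(fit$params)
  }
  bias <- colMeans(res) - truth
  se_mean <- apply(res, 2, stats::sd) / sqrt(nrow(res))
  expect_true(all(abs(bias) <= 3 * se_mean + 1e-12))
})

test_that("Tukey outlier rejection flags gross outliers and little else", {
  set.seed(77)
  refl <- reflection_table(data.frame(h = 1:1000, k = 0, l = 0, panel = 0))
  resid <- cbind(stats::rnorm(1000), stats::rnorm(1000), stats::rnorm(1000))
  resid[500, ] <- c(20, 0, 0)  # single gross outlier
  out <- reject_outliers(refl, resid)
  expect_true(has_flag(out, "outlier")[500])
  expect_false(has_flag(out, "used_in_refinement")[500])
  expect_lt(mean(has_flag(out, "outlier")), 0.02)
  # idempotent on unchanged residuals
  out2 <- reject_outliers(out, resid)
  expect_identical(out2$flags, out$flags)
})

test_that("cell and distance are degenerate for ED but not for X-rays", {
  # jointly scaling the detector distance and all cell lengths by 1.01
  joint_shift <- function(preset, d_min, dist = NULL) {
    sp <- simulation_spec(preset, d_min = d_min, sigma_px = 0, sigma_phi = 0,
                          seed = 2, distance_mm = dist,
                          cell = if (preset == "MX") c(10, 10, 10, 90, 90, 90)
                                 else c(32, 68, 105, 90, 90, 90),
                          lattice = if (preset == "MX") "cubic"
                                    else "orthorhombic")
    sim <- simulate_reflections(sp)
    ex <- sim$experiment
    hkl <- sim$reflections[, c("h", "k", "l")]
    p0 <- predict_centroids(ex, hkl)
    ex2 <- ex
    pan <- ex$detector$panels[[1]]
    pan$origin <- pan$origin + c(0, 0, 0.01) * pan$origin[3]
    ex2$detector <- detector_model(pan)
    cell <- cell_from_metrical(ex$crystal$g_star)
    cell[1:3] <- cell[1:3] * 1.01
    ex2$crystal <- crystal_model(ex$crystal$U, metrical_from_cell(cell),
                                 ex$crystal$lattice_constraint)
    p1 <- predict_centroids(ex2, hkl)
    m <- merge(as.data.frame(p0), as.data.frame(p1), by = c("h", "k", "l"))
    ctr <- pan$n_pixels / 2
    list(d = sqrt((m$x_calc.x - m$x_calc.y)^2 + (m$y_calc.x - m$y_calc.y)^2),
         r = sqrt((m$x_calc.x - ctr[1])^2 + (m$y_calc.x - ctr[2])^2))
  }
  ed <- joint_shift("ED", 3.0)                 # 2theta_max < 2 degrees
  expect_lt(max(ed$d), 0.05)
  mx <- joint_shift("MX", 1.2, dist = 30)      # 2theta_max ~ 51 degrees
  expect_gt(max(mx$d[mx$r > 0.8 * max(mx$r)]), 1)
})
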