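# Shared fixtures, built lazily and cached for the session. All fixtures are
# generated in code from fixed seeds.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# The standard simulated ED/MX pair: identical crystal, scan, detector pixel
# grid and seed; only wavelength and detector distance differ.
std_ed_sim <- function() fixture("ed", function()
  simulate_reflections(simulation_spec("ED", seed = 3)))
std_mx_sim <- function() fixture("mx", function()
  simulate_reflections(simulation_spec("MX", seed = 3)))

# Noise-free ED simulation (unit weights) for self-consistency checks.
quiet_ed_sim <- function() fixture("ed0", function()
  simulate_reflections(simulation_spec("ED", sigma_px = 0, sigma_phi = 0,
                                       seed = 11)))

# Small noise-free sims for refinement-heavy tests.
small_sim <- function(preset, ...) {
  key <- paste0("small_", preset, "_", paste(c(...), collapse = "_"))
  fixture(key, function()
    simulate_reflections(simulation_spec(preset, sigma_px = 0, sigma_phi = 0,
                                         seed = 5, d_min = 4, ...)))
}

# Jacobian bundles at the simulation truth for the standard pair.
std_ed_bundle <- function() fixture("bE", function() {
  s <- std_ed_sim()
  residuals_and_jacobian(build_parameterisation(s$experiment), s$reflections)
})
std_mx_bundle <- function() fixture("bX", function() {
  s <- std_mx_sim()
  residuals_and_jacobian(build_parameterisation(s$experiment), s$reflections)
})

# Fig-3-style single-row experiment: cubic a = 10 A crystal, rotation axis
# along x perpendicular to the beam, reflections (0, h, 0) rotating through
# the Ewald sphere; crystal calibrated so h = 1 crosses at `first_phi`.
row_experiment <- function(lambda, dist, first_phi = 15, n_px = 3000,
                           px = 0.1) {
  beam <- beam_model(c(0, 0, 1), lambda)
  gon <- goniometer_model(c(1, 0, 0))
  cry <- crystal_model(diag(3), metrical_from_cell(c(10, 10, 10, 90, 90, 90)),
                       "cubic")
  cry <- calibrate_crossing(cry, beam, gon, c(0, 1, 0), first_phi)
  pan <- panel_model(c(-n_px / 2 * px, -n_px / 2 * px, dist),
                     c(1, 0, 0), c(0, 1, 0), c(px, px), c(n_px, n_px))
  experiment_model(beam, detector_model(pan), gon,
                   scan_model(c(1, 60), c(0, 0.5)), cry)
}

# Synthetic frame with a flat Poisson background and 25 planted Gaussian
# spots (peak ~100 counts, sigma 1.5 px). Returns list(frame, centres).
planted_spot_frame <- function(seed = 42, n = 256, bg = 5, peak = 100,
                               sigma = 1.5) {
  set.seed(seed)
  frame <- matrix(stats::rpois(n * n, bg), n, n)
  centres <- expand.grid(x = seq(30, n - 26, by = 50),
                         y = seq(30, n - 26, by = 50))
  centres$x <- centres$x + stats::runif(nrow(centres), -0.5, 0.5)
  centres$y <- centres$y + stats::runif(nrow(centres), -0.5, 0.5)
  for (i in seq_len(nrow(centres))) {
    i0 <- round(centres$x[i]) - 5; j0 <- round(centres$y[i]) - 5
    ii <- i0:(i0 + 10); jj <- j0:(j0 + 10)
    lam <- peak * outer(exp(-((ii + 0.5 - centres$x[i])^2) / (2 * sigma^2)),
                        exp(-((jj + 0.5 - centres$y[i])^2) / (2 * sigma^2)))
    frame[ii + 1, jj + 1] <- frame[ii + 1, jj + 1] +
      matrix(stats::rpois(length(lam), lam), length(ii))
  }
  list(frame = frame, centres = centres)
}

# r.m.s. deviation of 3-D points from their best-fit (total least squares)
# line.
rms_from_line <- function(pts) {
  ctr <- colMeans(pts)
  p <- sweep(pts, 2, ctr)
  v <- svd(p)$v[, 1]
  sqrt(mean(rowSums((p - outer(as.numeric(p %*% v), v))^2)))
}

# Random valid unit cell (used by round-trip property tests).
random_cell <- function() {
  repeat {
    cell <- c(stats::runif(3, 3, 150), stats::runif(3, 60, 120))
    ok <- tryCatch({ metrical_from_cell(cell); TRUE },
                   error = function(e) FALSE)
    if (ok) return(cell)
  }
}
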