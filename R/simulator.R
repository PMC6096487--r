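# Synthetic rotation-diffraction experiments with known ground truth.
#
# The two presets share an identical orthorhombic lysozyme-like crystal
# (a = 32, b = 68, c = 105 Angstrom, short axis nearest the rotation axis),
# scan and detector pixel grid, and differ only in wavelength and effective
# detector distance:
#   ED: lambda = 0.02508 A (200 kV electrons), distance 2000 mm;
#   MX: lambda = 1.0332 A (12 keV X-rays), distance chosen so the same
#       resolution limit meets the panel edge.
# This isolates the effect of the diffraction geometry when comparing
# refinement conditioning between the two.

.preset_cell <- c(32, 68, 105, 90, 90, 90)

#' Specify a synthetic rotation-diffraction experiment
#'
#' @param preset "ED" (electron) or "MX" (X-ray) geometry.
#' @param d_min Resolution limit in Angstrom for reflection enumeration.
#' @param n_images,delta_phi,phi_start Scan: number of images, image width
#'   (deg/image) and start angle. The default 50 x 0.2 deg is a narrow
#'   10-degree wedge typical of electron diffraction.
#' @param sigma_px Gaussian centroid noise sigma for X and Y, pixels.
#' @param sigma_phi Gaussian centroid noise sigma for phi, degrees.
#' @param drift_mrad Total smooth beam drift over the scan, mrad (half-cosine
#'   ramp about the drift axis; 0 = stable beam).
#' @param drift_axis Unit lab vector the beam drifts about (default the
#'   rotation axis).
#' @param distortion Optional list \code{(centre, scale_major, scale_minor,
#'   axis_angle)} describing an elliptical lens distortion applied to the
#'   detector panel.
#' @param seed Integer random seed; the same spec and seed reproduce the
#'   simulation bitwise.
#' @param n_pixels,pixel_size_mm,distance_mm Detector overrides; the default
#'   detector is a single 1024x1024 panel of 55 micron pixels, beam centre
#'   at the panel centre. \code{distance_mm = NULL} takes the preset value
#'   (2000 mm for ED; panel-edge matching for MX).
#' @param cell,lattice Crystal overrides (defaults: the preset cell,
#'   orthorhombic).
#' @param misset_deg Fixed crystal pre-orientation (rotations about lab
#'   x, y, z in degrees) defining U at phi = 0.
#' @return An object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(preset = c("ED", "MX"), d_min = 3.0,
                            n_images = 50, delta_phi = 0.2, phi_start = 0,
                            sigma_px = 0.3, sigma_phi = 0.02,
                            drift_mrad = 0, drift_axis = c(1, 0, 0),
                            distortion = NULL, seed = 1,
                            n_pixels = c(1024, 1024), pixel_size_mm = 0.055,
                            distance_mm = NULL, cell = .preset_cell,
                            lattice = "orthorhombic",
                            misset_deg = c(3, 5, 10)) {
  preset <- match.arg(preset)
  lambda <- if (preset == "ED") 0.02508 else 1.0332
  if (d_min <= lambda / 2)
    stop("edgeom_invalid_argument: d_min must exceed lambda/2")
  if (sigma_px < 0 || sigma_phi < 0 || drift_mrad < 0)
    stop("edgeom_invalid_argument: noise and drift must be >= 0")
  if (is.null(distance_mm)) {
    half <- min(n_pixels) / 2 * pixel_size_mm
    distance_mm <- if (preset == "ED") 2000
      else half / tan(deg2rad(two_theta(d_min, lambda)))
  }
  structure(list(preset = preset, lambda = lambda, d_min = d_min,
                 n_images = as.integer(n_images), delta_phi = delta_phi,
                 phi_start = phi_start, sigma_px = sigma_px,
                 sigma_phi = sigma_phi, drift_mrad = drift_mrad,
                 drift_axis = .unit(drift_axis), distortion = distortion,
                 seed = as.integer(seed), n_pixels = as.integer(n_pixels),
                 pixel_size_mm = pixel_size_mm, distance_mm = distance_mm,
                 cell = cell, lattice = lattice, misset_deg = misset_deg),
            class = "simulation_spec")
}

# Ground-truth experiment model for a spec.
simulation_experiment <- function(spec) {
  beam <- beam_model(c(0, 0, 1), spec$lambda)
  half_f <- spec$n_pixels[1] / 2 * spec$pixel_size_mm
  half_s <- spec$n_pixels[2] / 2 * spec$pixel_size_mm
  panel <- panel_model(origin = c(-half_f, -half_s, spec$distance_mm),
                       fast_axis = c(1, 0, 0), slow_axis = c(0, 1, 0),
                       pixel_size = rep(spec$pixel_size_mm, 2),
                       n_pixels = spec$n_pixels, gain = 1)
  if (!is.null(spec$distortion)) {
    d <- spec$distortion
    maps <- generate_elliptical_distortion_maps(panel, d$centre,
                                                d$scale_major, d$scale_minor,
                                                d$axis_angle %||% 0)
    panel$distortion <- maps
  }
  U0 <- rotation_about_axis(c(0, 0, 1), spec$misset_deg[3]) %*%
    rotation_about_axis(c(0, 1, 0), spec$misset_deg[2]) %*%
    rotation_about_axis(c(1, 0, 0), spec$misset_deg[1])
  crystal <- crystal_model(U0, metrical_from_cell(spec$cell), spec$lattice)
  experiment_model(beam, detector_model(panel), goniometer_model(c(1, 0, 0)),
                   scan_model(c(1, spec$n_images),
                              c(spec$phi_start, spec$delta_phi)),
                   crystal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run fn with a deterministic local RNG state, restoring the caller's state.
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Enumerate all hkl with d >= d_min for the crystal cell.
.enumerate_hkl <- function(g_star, d_min) {
  cell <- cell_from_metrical(g_star)
  hmax <- floor(cell[1:3] / d_min) + 1L
  grid <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                      l = -hmax[3]:hmax[3])
  grid <- grid[!(grid$h == 0 & grid$k == 0 & grid$l == 0), ]
  H <- as.matrix(grid)
  d2inv <- rowSums((H %*% g_star) * H)  # |r|^2 = h g* h
  grid[d2inv <= 1 / d_min^2, ]
}

#' Simulate a rotation-diffraction data set
#'
#' Enumerates all reflections to the spec's resolution limit, keeps the
#' Ewald crossings falling inside the scan and on the detector, computes
#' noiseless centroids from the ground-truth geometry, optionally bakes in a
#' smooth beam drift, and adds seeded Gaussian centroid noise. Observed
#' variances record the true noise variances (left NA for noise-free
#' simulations, giving unit refinement weights).
#'
#' @param spec \code{simulation_spec}.
#' @return List: \code{reflections} (a \code{reflection_table}; observed =
#'   predicted + noise, flags observed/indexed/used_in_refinement set),
#'   \code{experiment} (ground-truth model), \code{truth} (per-image beam
#'   directions and the spec, for recovery tests).
#' @export
simulate_reflections <- function(spec) {
  exper <- simulation_experiment(spec)
  hkl <- .enumerate_hkl(exper$crystal$g_star, spec$d_min)
  pred <- predict_centroids(exper, hkl)
  if (!nrow(pred))
    stop("edgeom_empty_prediction: no reflections cross the scan; widen the scan or lower d_min")

  beam_dirs <- NULL
  if (spec$drift_mrad > 0) {
    drifted <- apply_beam_drift(spec, exper, pred)
    pred <- drifted$pred
    beam_dirs <- drifted$beam_dirs
  }

  refl <- .with_seed(spec$seed, function() {
    n <- nrow(pred)
    df <- data.frame(
      h = pred$h, k = pred$k, l = pred$l, panel = pred$panel,
      x_obs = pred$x_calc + if (spec$sigma_px > 0) stats::rnorm(n, 0, spec$sigma_px) else 0,
      y_obs = pred$y_calc + if (spec$sigma_px > 0) stats::rnorm(n, 0, spec$sigma_px) else 0,
      phi_obs = pred$phi_calc + if (spec$sigma_phi > 0) stats::rnorm(n, 0, spec$sigma_phi) else 0,
      var_x = if (spec$sigma_px > 0) spec$sigma_px^2 else NA_real_,
      var_y = if (spec$sigma_px > 0) spec$sigma_px^2 else NA_real_,
      var_phi = if (spec$sigma_phi > 0) spec$sigma_phi^2 else NA_real_,
      x_calc = pred$x_calc, y_calc = pred$y_calc, phi_calc = pred$phi_calc)
    reflection_table(df)
  })
  refl <- set_flag(refl, "observed")
  refl <- set_flag(refl, "predicted")
  refl <- set_flag(refl, "indexed")
  refl <- set_flag(refl, "used_in_refinement")
  list(reflections = refl, experiment = exper,
       truth = list(spec = spec, beam_dirs = beam_dirs))
}

# Half-cosine drift profile: 0 at the scan start, spec$drift_mrad at the end.
.drift_angle_mrad <- function(spec, z) {
  frac <- pmin(pmax(z / spec$n_images, 0), 1)
  spec$drift_mrad * (1 - cos(pi * frac)) / 2
}

#' Apply smooth beam drift to simulated observations
#'
#' Recomputes each reflection's centroid with the beam direction rotated by
#' a half-cosine ramp from 0 to the spec's total drift angle across the
#' scan (instrument instability appears as gradual drift of the direct-beam
#' position). The per-image ground-truth beam directions are returned for
#' recovery tests. With zero drift this is the identity.
#'
#' @param spec \code{simulation_spec}.
#' @param experiment Ground-truth \code{experiment_model}.
#' @param pred Predicted reflection table (no-drift centroids).
#' @return List: \code{pred} (updated table), \code{beam_dirs} (n_images x 3
#'   matrix of true per-image beam directions).
#' @export
apply_beam_drift <- function(spec, experiment, pred) {
  e <- experiment$goniometer$rotation_axis
  lam <- experiment$beam$wavelength
  dir0 <- experiment$beam$direction
  pan <- experiment$detector$panels[[1]]
  UB <- ub_matrix(experiment$crystal)
  r0 <- UB %*% t(as.matrix(pred[, c("h", "k", "l")]))
  phi <- pred$phi_calc
  # two fixed-point passes: drift depends on z = z(phi), which moves phi a little
  for (pass in 1:2) {
    z <- scan_phi_to_z(experiment$scan, phi)
    alpha <- .drift_angle_mrad(spec, z) * 1e-3
    s0 <- .rot_cols(matrix(dir0, 3, length(phi)), spec$drift_axis, alpha) / lam
    epar <- colSums(r0 * e)
    rperp <- r0 - outer(e, epar)
    exr <- rbind(e[2] * rperp[3, ] - e[3] * rperp[2, ],
                 e[3] * rperp[1, ] - e[1] * rperp[3, ],
                 e[1] * rperp[2, ] - e[2] * rperp[1, ])
    A <- colSums(rperp * s0)
    B2 <- colSums(exr * s0)
    C <- -colSums(r0 * r0) / 2 - epar * colSums(s0 * e)
    R <- sqrt(A^2 + B2^2)
    dphi <- acos(pmin(1, pmax(-1, C / pmax(R, .Machine$double.xmin))))
    base <- atan2(B2, A)
    cand <- cbind(rad2deg(base - dphi), rad2deg(base + dphi))
    dd <- ((cand - phi + 180) %% 360) - 180
    pick <- ifelse(abs(dd[, 1]) <= abs(dd[, 2]), dd[, 1], dd[, 2])
    phi <- phi + pick
  }
  s1 <- s0 + .rot_cols(r0, e, deg2rad(phi))
  nrm <- panel_normal(pan)
  tt <- sum(pan$origin * nrm) / colSums(s1 * nrm)
  L <- s1 * rep(tt, each = 3)
  dx <- L - pan$origin
  px <- mm_to_px(pan, colSums(dx * pan$fast_axis), colSums(dx * pan$slow_axis))
  pred$x_calc <- px$x
  pred$y_calc <- px$y
  pred$phi_calc <- phi
  zi <- seq_len(spec$n_images) - 0.5
  beam_dirs <- t(.rot_cols(matrix(dir0, 3, spec$n_images), spec$drift_axis,
                           .drift_angle_mrad(spec, zi) * 1e-3))
  list(pred = pred, beam_dirs = beam_dirs)
}

#' Render synthetic detector frames for a simulated data set
#'
#' One frame per image: Poisson background plus 2-D Gaussian spots centred
#' at each reflection's (raw, panel-local) pixel position, for reflections
#' whose rotation centroid falls in the image's range. Counts are Poisson
#' samples of background + spot intensity, seeded from the spec.
#'
#' @param sim Result of \code{\link{simulate_reflections}} (single-panel
#'   detectors only).
#' @param background_mean Poisson background mean per pixel (default 5).
#' @param peak Peak spot intensity above background, counts (default 100).
#' @param spot_sigma Gaussian spot width, pixels (default 1.5).
#' @return List of integer matrices (fast x slow), one per scan image.
#' @export
render_frames <- function(sim, background_mean = 5, peak = 100,
                          spot_sigma = 1.5) {
  spec <- sim$truth$spec
  exper <- sim$experiment
  if (length(exper$detector$panels) != 1)
    stop("edgeom_invalid_argument: frame rendering supports single-panel detectors")
  pan <- exper$detector$panels[[1]]
  refl <- sim$reflections
  nf <- pan$n_pixels[1]; ns <- pan$n_pixels[2]
  # raw (distorted) pixel positions of the spots
  mm <- px_to_mm(pan, pmin(pmax(refl$x_obs, 0), nf),
                 pmin(pmax(refl$y_obs, 0), ns))
  rx <- mm$fast / pan$pixel_size[1]
  ry <- mm$slow / pan$pixel_size[2]
  img_of <- floor(scan_phi_to_z(exper$scan, refl$phi_obs)) + 1L
  .with_seed(spec$seed + 1L, function() {
    lapply(seq_len(spec$n_images), function(i) {
      lam <- matrix(background_mean, nf, ns)
      for (r in which(img_of == i)) {
        i0 <- max(1L, floor(rx[r] - 4 * spot_sigma))
        i1 <- min(nf, ceiling(rx[r] + 4 * spot_sigma))
        j0 <- max(1L, floor(ry[r] - 4 * spot_sigma))
        j1 <- min(ns, ceiling(ry[r] + 4 * spot_sigma))
        if (i1 < i0 || j1 < j0) next
        gx <- exp(-((i0:i1) - 0.5 - rx[r])^2 / (2 * spot_sigma^2))
        gy <- exp(-((j0:j1) - 0.5 - ry[r])^2 / (2 * spot_sigma^2))
        lam[i0:i1, j0:j1] <- lam[i0:i1, j0:j1] + peak * outer(gx, gy)
      }
      matrix(stats::rpois(nf * ns, lam), nf, ns)
    })
  })
}
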