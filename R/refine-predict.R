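# Vectorised centroid prediction for refinement: given a parameter set and a
# table of indexed observations, predict (x_calc, y_calc, phi_calc) for each
# observation, choosing the Ewald crossing nearest the observed rotation
# angle and projecting onto the observation's own panel (no bounds check, so
# finite-difference probes remain smooth).
#
# Scan-varying parameters are evaluated at the centre of the image
# containing each observation's phi_obs.

# Rodrigues rotation of the columns of v (3 x n) about the fixed unit axis a
# by per-column angles theta (radians).
.rot_cols <- function(v, a, theta) {
  ct <- cos(theta); st <- sin(theta)
  axv <- rbind(a[2] * v[3, ] - a[3] * v[2, ],
               a[3] * v[1, ] - a[1] * v[3, ],
               a[1] * v[2, ] - a[2] * v[1, ])
  adv <- colSums(v * a)
  v * rep(ct, each = 3) + axv * rep(st, each = 3) +
    outer(a, adv * (1 - ct))
}

# Predict centroids for each observation row under the current parameters.
# Returns data.frame(x_calc, y_calc, phi_calc, crossed).
predict_for_observations <- function(params, obs) {
  ref <- params$ref
  scan <- ref$scan
  n <- nrow(obs)
  nz <- scan$image_range[2] - scan$image_range[1] + 1
  z <- scan_phi_to_z(scan, obs$phi_obs)
  zq <- pmin(pmax(floor(z) + 0.5, 0.5), nz - 0.5)  # image-centre coordinate

  mrad2rad <- 1e-3
  lam <- ref$experiment$beam$wavelength
  e <- ref$experiment$goniometer$rotation_axis

  # beam direction per observation
  mu1 <- param_value_at(params, "mu1", zq) * mrad2rad
  mu2 <- param_value_at(params, "mu2", zq) * mrad2rad
  dir <- matrix(ref$dir0, 3, n)
  dir <- .rot_cols(dir, ref$beam_axis2, mu2)
  dir <- .rot_cols(dir, ref$beam_axis1, mu1)
  s0 <- dir / lam

  # reciprocal-lattice vectors per observation
  hkl <- t(as.matrix(obs[, c("h", "k", "l")]))
  gvals <- vapply(ref$g_labels, function(l) param_value_at(params, l, zq),
                  numeric(n))
  gvals <- matrix(gvals, nrow = n) * 1e-5  # stored unit is 1e-5 A^-2
  q <- matrix(0, 3, n)
  cell_sv <- any(params$n_samples[ref$g_labels] > 1)
  if (!cell_sv) {
    B <- b_matrix(g_star_from_free(gvals[1, ], ref$lattice))
    q <- B %*% hkl
  } else {
    # cell values depend on z only through the image centre: group by image
    grp <- match(zq, unique(zq))
    for (g in unique(grp)) {
      rows <- which(grp == g)
      B <- b_matrix(g_star_from_free(gvals[rows[1], ], ref$lattice))
      q[, rows] <- B %*% hkl[, rows, drop = FALSE]
    }
  }
  p1 <- param_value_at(params, "phi1", zq) * mrad2rad
  p2 <- param_value_at(params, "phi2", zq) * mrad2rad
  p3 <- param_value_at(params, "phi3", zq) * mrad2rad
  r0 <- ref$U0 %*% q
  r0 <- .rot_cols(r0, c(1, 0, 0), p1)
  r0 <- .rot_cols(r0, c(0, 1, 0), p2)
  r0 <- .rot_cols(r0, c(0, 0, 1), p3)

  # Ewald crossing nearest phi_obs (continuous extension beyond-range)
  epar <- colSums(r0 * e)
  rperp <- r0 - outer(e, epar)
  exr <- rbind(e[2] * rperp[3, ] - e[3] * rperp[2, ],
               e[3] * rperp[1, ] - e[1] * rperp[3, ],
               e[1] * rperp[2, ] - e[2] * rperp[1, ])
  A <- colSums(rperp * s0)
  B2 <- colSums(exr * s0)
  C <- -colSums(r0 * r0) / 2 - epar * colSums(s0 * e)
  R <- sqrt(A^2 + B2^2)
  arg <- C / pmax(R, .Machine$double.xmin)
  crossed <- abs(arg) <= 1
  dphi <- acos(pmin(1, pmax(-1, arg)))
  base <- atan2(B2, A)
  cand1 <- rad2deg(base - dphi)
  cand2 <- rad2deg(base + dphi)
  d1 <- ((cand1 - obs$phi_obs + 180) %% 360) - 180
  d2 <- ((cand2 - obs$phi_obs + 180) %% 360) - 180
  delta <- ifelse(abs(d1) <= abs(d2), d1, d2)
  phi_calc <- obs$phi_obs + delta

  # diffracted beam and panel impact
  s1 <- s0 + .rot_cols(r0, e, deg2rad(phi_calc))
  det <- compose_detector(params)
  x_calc <- numeric(n); y_calc <- numeric(n)
  for (p in sort(unique(obs$panel))) {
    pan <- det$panels[[p + 1L]]
    rows <- which(obs$panel == p)
    nrm <- panel_normal(pan)
    D0 <- sum(pan$origin * nrm)
    denom <- colSums(s1[, rows, drop = FALSE] * nrm)
    tt <- D0 / denom
    L <- s1[, rows, drop = FALSE] * rep(tt, each = 3)
    dx <- L - pan$origin
    px <- mm_to_px(pan, colSums(dx * pan$fast_axis), colSums(dx * pan$slow_axis))
    x_calc[rows] <- px$x
    y_calc[rows] <- px$y
  }
  data.frame(x_calc = x_calc, y_calc = y_calc, phi_calc = phi_calc,
             crossed = crossed)
}

# Detector composition only (detector parameters are always static).
compose_detector <- function(params) {
  ref <- params$ref
  mrad <- 180 / pi / 1000
  v <- function(l) params$values[[l]][1]
  tvec <- v("shift1") * ref$f0 + v("shift2") * ref$s0v +
    (v("dist") - ref$dist0) * ref$n0
  R <- rotation_about_axis(ref$n0, v("tau1") * mrad) %*%
    rotation_about_axis(ref$f0, v("tau2") * mrad) %*%
    rotation_about_axis(ref$s0v, v("tau3") * mrad)
  C <- ref$centre0 + tvec
  panels <- lapply(seq_along(ref$experiment$detector$panels), function(i) {
    p <- ref$experiment$detector$panels[[i]]
    org <- C + as.numeric(R %*% (ref$origins0[[i]] + tvec - C))
    panel_model(org, .unit(as.numeric(R %*% p$fast_axis)),
                .unit(as.numeric(R %*% p$slow_axis)),
                p$pixel_size, p$n_pixels, p$gain, p$distortion)
  })
  detector_model(panels)
}
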