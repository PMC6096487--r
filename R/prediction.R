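# Ewald-construction computations: scattering angles, rotation-method
# crossing angles, centroid prediction onto detector panels, and mapping
# observed centroids back into reciprocal space.
#
# A reciprocal-lattice point r = R(phi) U B hkl diffracts when it lies on the
# Ewald sphere: |r + s0| = 1/lambda, with s0 = beam direction / lambda.
# Equivalently |r|^2 + 2 r . s0 = 0.

#' Scattering angle 2-theta for a d-spacing
#'
#' Bragg's law: \eqn{2\theta = 2 \arcsin(\lambda / 2d)}. For 1 Angstrom
#' diffraction this gives 62.2 degrees at a 12 keV X-ray wavelength but only
#' 1.44 degrees at a 200 kV electron wavelength.
#'
#' @param d_spacing Resolution in Angstrom, > 0.
#' @param wavelength Wavelength in Angstrom; must satisfy
#'   \code{wavelength <= 2 * d_spacing} (the limiting sphere).
#' @return Scattering angle in degrees.
#' @export
two_theta <- function(d_spacing, wavelength) {
  if (any(d_spacing <= 0) || any(wavelength <= 0))
    stop("edgeom_invalid_argument: d_spacing and wavelength must be > 0")
  if (any(wavelength > 2 * d_spacing))
    stop("edgeom_no_solution: wavelength > 2 d (beyond the limiting sphere)")
  rad2deg(2 * asin(wavelength / (2 * d_spacing)))
}

# Closed-form rotation-method crossing solver. r0: 3 x n matrix of
# reciprocal-lattice vectors at phi = 0; e: unit rotation axis; s0: incident
# wavevector (direction / lambda). Decompose r0 into components along and
# perpendicular to the axis; the Ewald condition becomes
#   A cos(phi) + B sin(phi) = C
# with A = r_perp . s0, B = (e x r_perp) . s0, C = -|r0|^2/2 - r_par . s0.
# Returns a list of numeric vectors of phi (degrees, in [0, 360)), one per
# column of r0; length 0, 1 or 2.
.crossings <- function(r0, e, s0) {
  r0 <- matrix(r0, nrow = 3)
  n <- ncol(r0)
  epar <- colSums(r0 * e)                   # e . r0
  rpar <- outer(e, epar)                    # component along axis
  rperp <- r0 - rpar
  exr <- rbind(e[2] * rperp[3, ] - e[3] * rperp[2, ],
               e[3] * rperp[1, ] - e[1] * rperp[3, ],
               e[1] * rperp[2, ] - e[2] * rperp[1, ])
  A <- colSums(rperp * s0)
  B <- colSums(exr * s0)
  C <- -colSums(r0 * r0) / 2 - epar * sum(e * s0)
  R <- sqrt(A^2 + B^2)
  phi0 <- atan2(B, A)
  out <- vector("list", n)
  ok <- R > 0 & abs(C) <= R
  dphi <- acos(pmin(1, pmax(-1, C[ok] / R[ok])))
  base <- phi0[ok]
  idx <- which(ok)
  for (k in seq_along(idx)) {
    ph <- rad2deg(c(base[k] - dphi[k], base[k] + dphi[k])) %% 360
    out[[idx[k]]] <- sort(unique(round(ph, 12)))
  }
  out[!ok] <- list(numeric(0))
  out
}

#' Rotation angles at which a reflection crosses the Ewald sphere
#'
#' Solves, in closed form, for all rotation angles phi in [0, 360) at which
#' the reciprocal-lattice point \code{hkl} satisfies the diffraction
#' condition \code{|R(phi) U B hkl + s0| = 1/lambda}. Points in the blind
#' region near the rotation axis (or beyond the limiting sphere) never cross
#' and return an empty vector.
#'
#' @param crystal \code{crystal_model}.
#' @param beam \code{beam_model}.
#' @param gonio \code{goniometer_model}.
#' @param hkl Integer 3-vector, not (0,0,0).
#' @return Numeric vector of crossing angles in degrees (length 0, 1 or 2).
#' @export
ewald_crossing_angles <- function(crystal, beam, gonio, hkl) {
  if (length(hkl) != 3 || all(hkl == 0))
    stop("edgeom_invalid_argument: hkl must be a non-zero integer triple")
  r0 <- ub_matrix(crystal) %*% as.numeric(hkl)
  s0 <- beam$direction / beam$wavelength
  .crossings(r0, gonio$rotation_axis, s0)[[1]]
}

#' Pre-rotate a crystal so a reflection crosses at a chosen angle
#'
#' The absolute crossing angle of any reflection depends on the (arbitrary)
#' crystal orientation at phi = 0; only differences between crossing angles
#' are orientation-free. This helper applies a rotation about the goniometer
#' axis so that the first crossing (smallest angle in [0, 360)) of
#' \code{hkl} occurs at \code{target_phi}, providing the reference needed to
#' compare absolute crossing angles.
#'
#' @param crystal \code{crystal_model}.
#' @param beam \code{beam_model}.
#' @param gonio \code{goniometer_model}.
#' @param hkl Reference reflection.
#' @param target_phi Desired first crossing angle (degrees).
#' @return The rotated \code{crystal_model}.
#' @export
calibrate_crossing <- function(crystal, beam, gonio, hkl, target_phi) {
  ph <- ewald_crossing_angles(crystal, beam, gonio, hkl)
  if (!length(ph))
    stop("edgeom_no_solution: reference reflection never crosses the Ewald sphere")
  delta <- min(ph) - target_phi
  U2 <- rotation_about_axis(gonio$rotation_axis, delta) %*% crystal$U
  # re-orthonormalise against accumulated rounding
  sv <- svd(U2)
  U2 <- sv$u %*% t(sv$v)
  crystal_model(U2, crystal$g_star, crystal$lattice_constraint)
}

# Intersect diffracted rays with detector panels. s1: 3 x n matrix of
# diffracted-beam wavevectors. Returns data.frame(panel, x, y) with NA panel
# where no panel is hit; coordinates are distortion-corrected pixels.
.intersect_panels <- function(detector, s1) {
  n <- ncol(s1)
  panel <- rep(NA_integer_, n)
  X <- rep(NA_real_, n)
  Y <- rep(NA_real_, n)
  todo <- rep(TRUE, n)
  for (p in seq_along(detector$panels)) {
    pan <- detector$panels[[p]]
    nrm <- panel_normal(pan)
    D0 <- sum(pan$origin * nrm)
    denom <- colSums(s1 * nrm)
    tt <- ifelse(abs(denom) < 1e-14, NA_real_, D0 / denom)
    hit <- todo & !is.na(tt) & tt > 0
    if (!any(hit)) next
    L <- s1[, hit, drop = FALSE] * rep(tt[hit], each = 3)
    dx <- L - pan$origin
    mmf <- colSums(dx * pan$fast_axis)
    mms <- colSums(dx * pan$slow_axis)
    px <- mm_to_px(pan, mmf, mms)
    inb <- px$x >= 0 & px$x <= pan$n_pixels[1] &
           px$y >= 0 & px$y <= pan$n_pixels[2]
    ids <- which(hit)[inb]
    panel[ids] <- p - 1L
    X[ids] <- px$x[inb]
    Y[ids] <- px$y[inb]
    todo[ids] <- FALSE
  }
  data.frame(panel = panel, x = X, y = Y)
}

#' Predict reflection centroids for a scan
#'
#' For every reflection in \code{hkl_list}, finds all Ewald-sphere crossings
#' whose rotation angle falls inside the scan (closed interval), forms the
#' diffracted-beam vector \code{s1 = s0 + R(phi) U B hkl} and intersects it
#' with the detector panels. The first panel whose pixel bounds contain the
#' intersection receives the record; panel distortion maps, when attached,
#' are applied in the mm-to-pixel step. Reflections that miss all panels are
#' dropped and counted in the \code{n_dropped} attribute.
#'
#' @param experiment \code{experiment_model}.
#' @param hkl_list Integer matrix (n x 3) or data.frame with columns h, k, l.
#' @return A \code{reflection_table} of predicted centroids (flag
#'   \code{predicted} set), with attribute \code{n_dropped}.
#' @export
predict_centroids <- function(experiment, hkl_list) {
  hkl <- as.matrix(as.data.frame(hkl_list)[, 1:3])
  storage.mode(hkl) <- "double"
  s0 <- experiment$beam$direction / experiment$beam$wavelength
  e <- experiment$goniometer$rotation_axis
  r0 <- ub_matrix(experiment$crystal) %*% t(hkl)
  cross <- .crossings(r0, e, s0)
  rng <- scan_phi_range(experiment$scan)
  # unroll candidate crossings into (reflection index, phi) pairs
  idx <- rep(seq_along(cross), lengths(cross))
  phi <- unlist(cross)
  if (length(phi)) {
    cand_idx <- rep(idx, 3L)
    cand_phi <- c(phi - 360, phi, phi + 360)
    keep <- cand_phi >= rng[1] - 1e-9 & cand_phi <= rng[2] + 1e-9
    idx <- cand_idx[keep]
    phi <- cand_phi[keep]
  }
  if (!length(phi)) {
    out <- reflection_table(data.frame(h = integer(0)))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  # diffracted rays at each crossing
  s1 <- matrix(0, 3, length(phi))
  for (k in seq_along(phi))
    s1[, k] <- s0 + rotation_about_axis(e, phi[k]) %*% r0[, idx[k]]
  pos <- .intersect_panels(experiment$detector, s1)
  ok <- !is.na(pos$panel)
  out <- reflection_table(data.frame(
    h = hkl[idx[ok], 1], k = hkl[idx[ok], 2], l = hkl[idx[ok], 3],
    panel = pos$panel[ok], x_calc = pos$x[ok], y_calc = pos$y[ok],
    phi_calc = phi[ok]))
  out <- set_flag(out, "predicted")
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Assign Miller indices by nearest-integer rounding
#'
#' Plumbing for a known (or hypothesised) model: maps each observation into
#' reciprocal space, converts to fractional indices with the inverse of the
#' setting matrix U B, and rounds to the nearest integers. No basis search
#' is performed. The attribute \code{fractional_rmsd} records the r.m.s.
#' distance of the fractional indices from the assigned integers (a large
#' value means the model does not index the data).
#'
#' @param obs Reflection table with observed centroids.
#' @param experiment \code{experiment_model} defining the lattice.
#' @param invert_axis Use the inverted rotation-axis hypothesis.
#' @return The table with h, k, l replaced by the assigned indices, flag
#'   \code{indexed} set, and attribute \code{fractional_rmsd}.
#' @export
assign_indices <- function(obs, experiment, invert_axis = FALSE) {
  rlp <- map_to_reciprocal_space(obs, experiment, invert_axis)
  frac <- t(solve(ub_matrix(experiment$crystal), t(rlp)))
  hkl <- round(frac)
  obs$h <- as.integer(hkl[, 1]); obs$k <- as.integer(hkl[, 2])
  obs$l <- as.integer(hkl[, 3])
  obs <- set_flag(obs, "indexed")
  attr(obs, "fractional_rmsd") <- sqrt(mean((frac - hkl)^2))
  obs
}

#' Map observed centroids into reciprocal space
#'
#' Each observation's scattering vector \code{s1 - s0} is reconstructed from
#' its panel millimetre position and the wavelength, then rotated by
#' \code{-phi_obs} about the rotation axis (optionally inverted) into the
#' crystal-fixed frame at phi = 0. With X-ray geometry an inverted axis
#' hypothesis produces a distinctly curved reconstructed lattice; with the
#' nearly flat Ewald sphere of electron diffraction both hypotheses give
#' almost straight rows, which is why the handedness of rotation is hard to
#' determine from the reconstruction alone.
#'
#' @param obs Reflection table with observed centroids.
#' @param experiment \code{experiment_model}.
#' @param invert_axis Test the inverted rotation-axis hypothesis.
#' @return n x 3 matrix of reciprocal-space vectors (Angstrom^-1).
#' @export
map_to_reciprocal_space <- function(obs, experiment, invert_axis = FALSE) {
  e <- experiment$goniometer$rotation_axis
  if (invert_axis) e <- -e
  s0 <- experiment$beam$direction / experiment$beam$wavelength
  lam <- experiment$beam$wavelength
  out <- matrix(NA_real_, nrow(obs), 3)
  for (i in seq_len(nrow(obs))) {
    pan <- experiment$detector$panels[[obs$panel[i] + 1L]]
    mm <- px_to_mm(pan, obs$x_obs[i], obs$y_obs[i])
    P <- pan$origin + mm$fast * pan$fast_axis + mm$slow * pan$slow_axis
    s1 <- P / sqrt(sum(P^2)) / lam
    ds <- s1 - s0
    out[i, ] <- rotation_about_axis(e, -obs$phi_obs[i]) %*% ds
  }
  out
}
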