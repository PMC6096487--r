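# Experiment model types.
#
# Laboratory frame convention (used throughout the package):
#   * right-handed orthonormal frame;
#   * the nominal incident beam propagates along +z;
#   * the nominal goniometer rotation axis lies along +x;
#   * the detector plane is nominally perpendicular to the beam.
# Positive rotation angles are right-handed about the rotation axis. An
# inverted-axis hypothesis is represented by negating the axis vector.
# Angles are degrees at the user interface and radians internally.

.unit <- function(v) v / sqrt(sum(v^2))

.check_unit <- function(v, name, tol = 1e-10) {
  if (length(v) != 3 || !all(is.finite(v)))
    stop(sprintf("edgeom_invalid_argument: %s must be a finite 3-vector", name))
  if (abs(sqrt(sum(v^2)) - 1) > tol)
    stop(sprintf("edgeom_invalid_argument: %s must be a unit vector", name))
  invisible(v)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Beam model
#'
#' Direction is the unit vector along which the incident beam propagates, in
#' the lab frame; the incident wavevector is \code{s0 = direction /
#' wavelength} (Angstrom^-1). The Ewald sphere has radius \code{1 /
#' wavelength}, so the short electron wavelength implies a very large, almost
#' flat sphere.
#'
#' @param direction Unit 3-vector, lab frame.
#' @param wavelength Wavelength in Angstrom, > 0.
#' @return An object of class \code{beam_model}.
#' @export
beam_model <- function(direction = c(0, 0, 1), wavelength) {
  .check_unit(direction, "direction")
  if (!is.numeric(wavelength) || length(wavelength) != 1 || wavelength <= 0)
    stop("edgeom_invalid_argument: wavelength must be a positive scalar")
  structure(list(direction = as.numeric(direction),
                 wavelength = as.numeric(wavelength)),
            class = "beam_model")
}

#' Detector panel model
#'
#' A panel is a rectangular grid of pixels with an origin at the outer corner
#' of pixel (0,0) (position in mm, lab frame) and orthonormal fast/slow axis
#' unit vectors. Continuous pixel coordinates are 0-based, so the centre of
#' pixel (i, j) is at continuous coordinate (i + 0.5, j + 0.5) and maps to
#' lab position \code{origin + X*px_fast*fast_axis + Y*px_slow*slow_axis}.
#'
#' @param origin Lab position (mm) of the outer corner of pixel (0,0).
#' @param fast_axis,slow_axis Orthonormal unit 3-vectors.
#' @param pixel_size Pixel pitch (fast, slow) in mm.
#' @param n_pixels Integer pixel counts (fast, slow).
#' @param gain Detector gain, counts per quantum, > 0.
#' @param distortion Optional \code{distortion_map_pair} attached to this
#'   panel (see \code{\link{generate_elliptical_distortion_maps}}).
#' @return An object of class \code{panel_model}.
#' @export
panel_model <- function(origin, fast_axis, slow_axis, pixel_size, n_pixels,
                        gain = 1, distortion = NULL) {
  .check_unit(fast_axis, "fast_axis")
  .check_unit(slow_axis, "slow_axis")
  if (abs(sum(fast_axis * slow_axis)) >= 1e-8)
    stop("edgeom_invalid_argument: fast_axis and slow_axis must be orthogonal")
  if (length(origin) != 3 || !all(is.finite(origin)))
    stop("edgeom_invalid_argument: origin must be a finite 3-vector")
  if (length(pixel_size) != 2 || any(pixel_size <= 0))
    stop("edgeom_invalid_argument: pixel_size components must be > 0")
  if (length(n_pixels) != 2 || any(n_pixels < 1))
    stop("edgeom_invalid_argument: n_pixels components must be >= 1")
  if (!is.numeric(gain) || gain <= 0)
    stop("edgeom_invalid_argument: gain must be > 0")
  if (!is.null(distortion)) .check_distortion(distortion, n_pixels)
  structure(list(origin = as.numeric(origin),
                 fast_axis = as.numeric(fast_axis),
                 slow_axis = as.numeric(slow_axis),
                 pixel_size = as.numeric(pixel_size),
                 n_pixels = as.integer(n_pixels),
                 gain = as.numeric(gain),
                 distortion = distortion),
            class = "panel_model")
}

panel_normal <- function(panel) .unit(crossprod3(panel$fast_axis, panel$slow_axis))

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Detector model: an ordered list of panels
#'
#' Panel ids are 0-based list positions, matching the 0-based pixel
#' convention of the reflection table.
#'
#' @param panels A list of \code{panel_model} objects (or a single panel).
#' @return An object of class \code{detector_model}.
#' @export
detector_model <- function(panels) {
  if (inherits(panels, "panel_model")) panels <- list(panels)
  if (!length(panels) || !all(vapply(panels, inherits, TRUE, "panel_model")))
    stop("edgeom_invalid_argument: panels must be a non-empty list of panel_model")
  structure(list(panels = panels), class = "detector_model")
}

#' Goniometer model
#'
#' @param rotation_axis Unit 3-vector, lab frame; positive rotation is
#'   right-handed about it.
#' @return An object of class \code{goniometer_model}.
#' @export
goniometer_model <- function(rotation_axis = c(1, 0, 0)) {
  .check_unit(rotation_axis, "rotation_axis")
  structure(list(rotation_axis = as.numeric(rotation_axis)),
            class = "goniometer_model")
}

#' Scan model
#'
#' The rotation range per image is assumed constant: image i (1-based within
#' \code{image_range}) covers rotation angles
#' \code{[phi_start + (i - image_range[1]) * delta_phi, ... + delta_phi]}.
#'
#' @param image_range Pair of ints, 1-based inclusive.
#' @param oscillation \code{c(phi_start, delta_phi)} in degrees;
#'   \code{delta_phi > 0}.
#' @return An object of class \code{scan_model}.
#' @export
scan_model <- function(image_range, oscillation) {
  if (length(image_range) != 2 || image_range[2] < image_range[1])
    stop("edgeom_invalid_argument: image_range must be increasing pair")
  if (length(oscillation) != 2 || oscillation[2] <= 0)
    stop("edgeom_invalid_argument: oscillation delta_phi must be > 0")
  structure(list(image_range = as.integer(image_range),
                 oscillation = as.numeric(oscillation)),
            class = "scan_model")
}

scan_phi_range <- function(scan) {
  n <- scan$image_range[2] - scan$image_range[1] + 1
  c(scan$oscillation[1], scan$oscillation[1] + n * scan$oscillation[2])
}

# Fractional image coordinate (z) of a rotation angle phi (deg): z = 0 at the
# start of the scan, z = n_images at the end.
scan_phi_to_z <- function(scan, phi) {
  (phi - scan$oscillation[1]) / scan$oscillation[2]
}

#' Crystal model
#'
#' The crystal is described by a proper rotation \code{U} (orientation of the
#' reciprocal basis in the lab frame at rotation angle zero) and the
#' reciprocal metrical matrix \code{g_star = B \%*\% t(B)} where B is the
#' reciprocal-basis matrix; \code{g_star} carries the unit-cell information
#' and its independent elements are the cell parameters used in refinement.
#'
#' @param U 3x3 proper rotation matrix.
#' @param g_star 3x3 symmetric positive-definite matrix, Angstrom^-2.
#' @param lattice_constraint One of "triclinic", "monoclinic", "orthorhombic",
#'   "tetragonal", "hexagonal", "cubic".
#' @return An object of class \code{crystal_model}.
#' @export
crystal_model <- function(U = diag(3), g_star,
                          lattice_constraint = "triclinic") {
  U <- as.matrix(U)
  if (!all(dim(U) == c(3, 3)) || abs(det(U) - 1) > 1e-9 ||
      max(abs(t(U) %*% U - diag(3))) > 1e-9)
    stop("edgeom_invalid_argument: U must be a proper rotation (det 1, orthonormal)")
  g_star <- as.matrix(g_star)
  .check_spd(g_star)
  lattice_constraint <- match.arg(lattice_constraint, names(.lattice_free))
  structure(list(U = U, g_star = (g_star + t(g_star)) / 2,
                 lattice_constraint = lattice_constraint),
            class = "crystal_model")
}

.check_spd <- function(g) {
  if (!all(dim(g) == c(3, 3)) || max(abs(g - t(g))) > 1e-12 * max(abs(g)))
    stop("edgeom_invalid_argument: g_star must be symmetric 3x3")
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("edgeom_invalid_argument: g_star must be positive definite")
  invisible(g)
}

# Reciprocal-basis matrix (columns a*, b*, c* in the crystal frame) such that
# B %*% t(B) = g_star. Standard choice: transposed Cholesky factor (lower
# triangular), which places c* along z of the crystal frame; any B with
# B Bt = g_star differs only by a rotation absorbed into U.
b_matrix <- function(g_star) {
  R <- chol(g_star)  # upper triangular, t(R) %*% R = g_star
  t(R)
}

# Reciprocal-lattice vector(s) in the crystal setting frame at phi = 0:
# r0 = U %*% B %*% hkl. hkl may be a 3-vector or a 3 x n matrix.
ub_matrix <- function(crystal) crystal$U %*% b_matrix(crystal$g_star)

#' Reciprocal metrical matrix from real-space unit cell
#'
#' Builds \code{g_star = B \%*\% t(B)} for the standard reciprocal basis B of
#' the cell \code{(a, b, c, alpha, beta, gamma)}.
#'
#' @param cell Numeric 6-vector: a, b, c in Angstrom; alpha, beta, gamma in
#'   degrees.
#' @return 3x3 symmetric positive-definite matrix in Angstrom^-2.
#' @examples
#' metrical_from_cell(c(10, 10, 10, 90, 90, 90))  # diag(0.01, 0.01, 0.01)
#' @export
metrical_from_cell <- function(cell) {
  if (length(cell) != 6 || any(!is.finite(cell)))
    stop("edgeom_invalid_cell: cell must be 6 finite numbers")
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  if (any(cell[1:3] <= 0) || any(cell[4:6] <= 0) || any(cell[4:6] >= 180))
    stop("edgeom_invalid_cell: lengths must be > 0 and angles in (0, 180)")
  al <- deg2rad(cell[4]); be <- deg2rad(cell[5]); ga <- deg2rad(cell[6])
  ca <- cos(al); cb <- cos(be); cg <- cos(ga)
  vol2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vol2 <= 0) stop("edgeom_invalid_cell: degenerate cell (volume <= 0)")
  # real-space metric tensor, then invert: g* = g^-1
  g <- matrix(c(a * a,      a * b * cg, a * cc * cb,
                a * b * cg, b * b,      b * cc * ca,
                a * cc * cb, b * cc * ca, cc * cc), 3, 3)
  gs <- solve(g)
  (gs + t(gs)) / 2
}

#' Real-space unit cell from the reciprocal metrical matrix
#'
#' Inverse of \code{\link{metrical_from_cell}}.
#'
#' @param g_star 3x3 symmetric positive-definite matrix, Angstrom^-2.
#' @return Numeric 6-vector (a, b, c, alpha, beta, gamma), Angstrom / degrees.
#' @export
cell_from_metrical <- function(g_star) {
  .check_spd(as.matrix(g_star))
  g <- solve(g_star)  # real-space metric tensor
  a <- sqrt(g[1, 1]); b <- sqrt(g[2, 2]); cc <- sqrt(g[3, 3])
  al <- acos(g[2, 3] / (b * cc))
  be <- acos(g[1, 3] / (a * cc))
  ga <- acos(g[1, 2] / (a * b))
  c(a, b, cc, rad2deg(al), rad2deg(be), rad2deg(ga))
}

.lattice_free <- list(
  triclinic    = c("g11", "g22", "g33", "g12", "g13", "g23"),
  monoclinic   = c("g11", "g22", "g33", "g13"),  # unique axis b
  orthorhombic = c("g11", "g22", "g33"),
  tetragonal   = c("g11", "g33"),
  hexagonal    = c("g11", "g33"),
  cubic        = "g11"
)

#' Independent reciprocal metrical matrix elements for a lattice symmetry
#'
#' Returns the labels of the independent elements of \code{g_star} for a
#' Bravais constraint; all other elements are tied to these or fixed at zero.
#' For an orthorhombic lattice these are the three diagonal elements; a
#' triclinic lattice has all six, a cubic lattice a single scale.
#'
#' @param lattice_constraint Lattice system name.
#' @return Character vector of element labels ("g11", "g22", ...).
#' @export
free_metrical_elements <- function(lattice_constraint) {
  lattice_constraint <- match.arg(lattice_constraint, names(.lattice_free))
  .lattice_free[[lattice_constraint]]
}

# Indices (i, j) into g_star for an element label.
.g_index <- function(label) {
  i <- as.integer(substr(label, 2, 2))
  j <- as.integer(substr(label, 3, 3))
  c(i, j)
}

# Rebuild a full g_star matrix from the free-element values for a given
# lattice constraint. Tied elements (tetragonal/hexagonal/cubic) follow the
# first diagonal value; hexagonal additionally sets g12 = g11 / 2.
g_star_from_free <- function(values, lattice_constraint) {
  labels <- .lattice_free[[lattice_constraint]]
  stopifnot(length(values) == length(labels))
  g <- matrix(0, 3, 3)
  for (k in seq_along(labels)) {
    ij <- .g_index(labels[k])
    g[ij[1], ij[2]] <- values[k]
    g[ij[2], ij[1]] <- values[k]
  }
  if (lattice_constraint == "cubic") g[2, 2] <- g[3, 3] <- g[1, 1]
  if (lattice_constraint %in% c("tetragonal", "hexagonal")) g[2, 2] <- g[1, 1]
  if (lattice_constraint == "hexagonal") g[1, 2] <- g[2, 1] <- g[1, 1] / 2
  g
}

g_star_free_values <- function(g_star, lattice_constraint) {
  labels <- .lattice_free[[lattice_constraint]]
  vapply(labels, function(l) { ij <- .g_index(l); g_star[ij[1], ij[2]] }, 0)
}

#' Rotation matrix about an axis
#'
#' Proper right-handed rotation by \code{angle} degrees about a unit
#' \code{axis} (Rodrigues formula). This is the rotation-method operator
#' R(phi) applied to reciprocal-lattice vectors during the scan.
#'
#' @param axis Unit 3-vector.
#' @param angle Rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  if (length(axis) != 3 || sqrt(sum(axis^2)) < 1e-12)
    stop("edgeom_invalid_argument: axis must be a non-zero 3-vector")
  e <- .unit(axis)
  th <- deg2rad(angle)
  K <- matrix(c(0, e[3], -e[2],
                -e[3], 0, e[1],
                e[2], -e[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Experiment model
#'
#' Bundles the beam, detector, goniometer, scan and crystal models. The
#' optional \code{scan_varying} element holds per-sample states produced by
#' scan-varying refinement (see \code{\link{refine_geometry}}): smoother
#' sample values for crystal orientation angles, cell elements and beam
#' direction angles spanning the scan's image range.
#'
#' @param beam \code{beam_model}.
#' @param detector \code{detector_model} (a bare \code{panel_model} is
#'   wrapped).
#' @param goniometer \code{goniometer_model}.
#' @param scan \code{scan_model}.
#' @param crystal \code{crystal_model}.
#' @param scan_varying Optional named list of \code{gaussian_smoother}
#'   objects keyed by parameter label.
#' @return An object of class \code{experiment_model}.
#' @export
experiment_model <- function(beam, detector, goniometer, scan, crystal,
                             scan_varying = NULL) {
  if (inherits(detector, "panel_model")) detector <- detector_model(detector)
  stopifnot(inherits(beam, "beam_model"), inherits(detector, "detector_model"),
            inherits(goniometer, "goniometer_model"),
            inherits(scan, "scan_model"), inherits(crystal, "crystal_model"))
  structure(list(beam = beam, detector = detector, goniometer = goniometer,
                 scan = scan, crystal = crystal, scan_varying = scan_varying),
            class = "experiment_model")
}

#' @export
print.experiment_model <- function(x, ...) {
  cell <- cell_from_metrical(x$crystal$g_star)
  cat("Experiment model\n")
  cat(sprintf("  beam:    lambda = %.6g A, direction = (%s)\n",
              x$beam$wavelength,
              paste(sprintf("%.4f", x$beam$direction), collapse = ", ")))
  cat(sprintf("  crystal: %s, cell = %.3f %.3f %.3f A, %.2f %.2f %.2f deg\n",
              x$crystal$lattice_constraint, cell[1], cell[2], cell[3],
              cell[4], cell[5], cell[6]))
  cat(sprintf("  scan:    images %d..%d, phi %.3f..%.3f deg\n",
              x$scan$image_range[1], x$scan$image_range[2],
              scan_phi_range(x$scan)[1], scan_phi_range(x$scan)[2]))
  cat(sprintf("  detector: %d panel(s)\n", length(x$detector$panels)))
  if (!is.null(x$scan_varying))
    cat(sprintf("  scan-varying: %s\n",
                paste(names(x$scan_varying), collapse = ", ")))
  invisible(x)
}
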