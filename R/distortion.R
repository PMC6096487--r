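# Detector distortion maps and pixel <-> millimetre transforms.
#
# A distortion map pair encodes, for every pixel of a panel, the offset (in
# pixels) between the corrected and the raw pixel coordinate, separately for
# the fast and slow directions:
#
#   corrected = raw + offset(raw)       (sign convention: corrected - raw)
#
# Worked example: a constant fast offset of +2 px means the true (corrected)
# position of the count recorded in raw pixel column 10 is column 12, so
# px_to_mm(12, .) first recovers raw = 12 - 2 = 10 and returns 10 * pitch.
# Lookups are nearest-neighbour; no interpolation is performed, so a round
# trip is exact only to the local variation of the map over one pixel.

#' Construct a distortion map pair
#'
#' @param offset_fast,offset_slow Numeric matrices of per-pixel offsets in
#'   pixels, dimensions equal to the panel's \code{n_pixels} (fast, slow).
#' @return An object of class \code{distortion_map_pair}.
#' @export
distortion_map_pair <- function(offset_fast, offset_slow) {
  offset_fast <- as.matrix(offset_fast)
  offset_slow <- as.matrix(offset_slow)
  if (!all(dim(offset_fast) == dim(offset_slow)))
    stop("edgeom_invalid_argument: offset maps must share dimensions")
  if (!all(is.finite(offset_fast)) || !all(is.finite(offset_slow)))
    stop("edgeom_invalid_argument: offset maps must be finite")
  structure(list(offset_fast = offset_fast, offset_slow = offset_slow),
            class = "distortion_map_pair")
}

.check_distortion <- function(d, n_pixels) {
  if (!inherits(d, "distortion_map_pair"))
    stop("edgeom_invalid_argument: distortion must be a distortion_map_pair")
  if (!all(dim(d$offset_fast) == n_pixels))
    stop("edgeom_invalid_argument: distortion map shape must match n_pixels")
  invisible(d)
}

#' Generate distortion maps for an elliptical lens distortion
#'
#' Models anisotropic magnification that turns a circular powder ring into an
#' ellipse: the recorded pattern is the ideal pattern scaled by
#' \code{scale_major} along the direction \code{axis_angle} (degrees,
#' from the fast axis) and \code{scale_minor} perpendicular to it, about
#' \code{centre}. The stored offsets take each raw pixel centre to its
#' position under the INVERSE scaling, so that applying the correction
#' restores circular symmetry.
#'
#' @param panel \code{panel_model} defining the pixel grid.
#' @param centre \code{c(x, y)} distortion centre in pixels.
#' @param scale_major,scale_minor Scale factors, > 0.
#' @param axis_angle Major-axis direction in degrees.
#' @return A \code{distortion_map_pair}.
#' @export
generate_elliptical_distortion_maps <- function(panel, centre, scale_major,
                                                scale_minor, axis_angle = 0) {
  if (scale_major <= 0 || scale_minor <= 0)
    stop("edgeom_invalid_argument: scales must be > 0")
  nf <- panel$n_pixels[1]; ns <- panel$n_pixels[2]
  px <- matrix(seq_len(nf) - 0.5, nf, ns)         # pixel-centre x
  py <- matrix(rep(seq_len(ns) - 0.5, each = nf), nf, ns)
  dx <- px - centre[1]; dy <- py - centre[2]
  a <- deg2rad(axis_angle)
  u <- c(cos(a), sin(a)); v <- c(-sin(a), cos(a))
  du <- dx * u[1] + dy * u[2]
  dv <- dx * v[1] + dy * v[2]
  du2 <- du / scale_major
  dv2 <- dv / scale_minor
  ox <- du2 * u[1] + dv2 * v[1] - dx
  oy <- du2 * u[2] + dv2 * v[2] - dy
  distortion_map_pair(ox, oy)
}

# Nearest-neighbour map lookup at continuous pixel coordinates (x, y):
# the value stored for the pixel containing the point.
.map_lookup <- function(map, x, y) {
  i <- pmin(pmax(floor(x) + 1L, 1L), nrow(map))
  j <- pmin(pmax(floor(y) + 1L, 1L), ncol(map))
  map[cbind(i, j)]
}

#' Corrected pixel coordinates to millimetres
#'
#' When a distortion map pair is attached to the panel, the reverse
#' correction is applied first (recovering the raw pixel coordinate by
#' fixed-point iteration on the nearest-neighbour lookup, at most 5
#' iterations, tolerance 0.01 px) and the millimetre coordinate is computed
#' from the raw coordinate. Without maps the transform is simply
#' \code{mm = pixel * pixel_size}.
#'
#' @param panel \code{panel_model}.
#' @param x,y Corrected continuous pixel coordinates (0-based), vectorised.
#' @return List with components \code{fast}, \code{slow} in mm.
#' @export
px_to_mm <- function(panel, x, y) {
  nf <- panel$n_pixels[1]; ns <- panel$n_pixels[2]
  if (any(x < -1e-9 | x > nf + 1e-9 | y < -1e-9 | y > ns + 1e-9))
    stop("edgeom_out_of_range: pixel coordinate outside panel bounds")
  d <- panel$distortion
  if (!is.null(d)) {
    rx <- x; ry <- y
    for (it in 1:5) {
      nx <- x - .map_lookup(d$offset_fast, rx, ry)
      ny <- y - .map_lookup(d$offset_slow, rx, ry)
      if (max(abs(nx - rx), abs(ny - ry)) < 0.01) { rx <- nx; ry <- ny; break }
      rx <- nx; ry <- ny
    }
    x <- rx; y <- ry
  }
  list(fast = x * panel$pixel_size[1], slow = y * panel$pixel_size[2])
}

#' Millimetres to corrected pixel coordinates
#'
#' The uncorrected (raw) pixel coordinate is calculated first and the
#' distortion correction, when present, is then applied to obtain the
#' corrected pixel coordinate (nearest-neighbour lookup at the raw
#' position).
#'
#' @param panel \code{panel_model}.
#' @param mm_fast,mm_slow Millimetre coordinates, vectorised.
#' @return List with components \code{x}, \code{y} (corrected pixels).
#' @export
mm_to_px <- function(panel, mm_fast, mm_slow) {
  x <- mm_fast / panel$pixel_size[1]
  y <- mm_slow / panel$pixel_size[2]
  d <- panel$distortion
  if (!is.null(d)) {
    x2 <- x + .map_lookup(d$offset_fast, x, y)
    y2 <- y + .map_lookup(d$offset_slow, x, y)
    x <- x2; y <- y2
  }
  list(x = x, y = y)
}
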