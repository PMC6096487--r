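# Gaussian smoother for scan-varying parameters. Sample points are evenly
# spaced across the scan (endpoints included) in fractional image
# coordinates z (z = 0 at the scan start, z = n_images at the end); the
# value at any position is a normalised Gaussian-weighted average of the
# nearest three samples.

#' Construct a Gaussian smoother
#'
#' @param n_samples Number of sample points (>= 2), evenly spaced over the
#'   scan including the endpoints.
#' @param values Sample values (length \code{n_samples}).
#' @param sigma Smoothing width in sample-spacing units (default 0.65).
#' @param scan \code{scan_model} defining the image range the samples span.
#' @return An object of class \code{gaussian_smoother}.
#' @export
gaussian_smoother <- function(n_samples, values = rep(0, n_samples),
                              sigma = 0.65, scan) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 2) stop("edgeom_invalid_argument: n_samples must be >= 2")
  if (length(values) != n_samples)
    stop("edgeom_invalid_argument: values length must equal n_samples")
  if (sigma <= 0) stop("edgeom_invalid_argument: sigma must be > 0")
  nz <- scan$image_range[2] - scan$image_range[1] + 1
  structure(list(n_samples = n_samples, values = as.numeric(values),
                 sigma = sigma, positions = seq(0, nz, length.out = n_samples),
                 spacing = nz / (n_samples - 1)),
            class = "gaussian_smoother")
}

#' Interpolate a scan-varying parameter value
#'
#' \deqn{v(z) = \sum_i w_i v_i / \sum_i w_i,\quad
#'       w_i = \exp(-\Delta_i^2/\sigma_s^2)}
#' where \eqn{\Delta_i} is the distance from \code{position} to sample i in
#' sample-spacing units. Only the nearest three samples contribute (all of
#' them when \code{n_samples <= 3}), so the weights are non-negative and sum
#' to one by construction.
#'
#' @param smoother \code{gaussian_smoother}.
#' @param position Fractional image coordinate(s) z; vectorised.
#' @return Interpolated value(s).
#' @export
smoother_value <- function(smoother, position) {
  W <- .smoother_weights(smoother, position)
  as.numeric(W %*% smoother$values)
}

# Normalised weight matrix (length(position) x n_samples).
.smoother_weights <- function(smoother, position) {
  d <- outer(position, smoother$positions, "-") / smoother$spacing
  w <- exp(-d^2 / smoother$sigma^2)
  if (smoother$n_samples > 3) {
    # keep only the nearest three samples per position
    rk <- t(apply(abs(d), 1, rank, ties.method = "first"))
    w[rk > 3] <- 0
  }
  w / rowSums(w)
}
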