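# Parameterisation of the diffraction geometry for least-squares refinement.
#
# Parameter labels and units (values are stored in these units):
#   dist          effective detector distance along the initial panel-group
#                 normal, mm (absolute)
#   shift1/shift2 detector translation along the initial fast/slow axes, mm
#   tau1          detector rotation about the panel-group normal, mrad
#   tau2/tau3     detector rotations about the initial fast/slow axes, mrad
#                 (the tilt/twist analogues); rotations pivot about the
#                 panel-group centre
#   mu1           beam rotation about the goniometer rotation axis, mrad
#                 (FIXED by default: with a single rotation axis this angle
#                 is poorly determined and the conventional static beam
#                 parameterisation exposes a single orientation angle)
#   mu2           beam rotation about axis (rotation_axis x beam), mrad
#   phi1/phi2/phi3 crystal orientation misset angles about lab x, y, z, mrad
#   g11, g22, ... free reciprocal metrical matrix elements in units of
#                 1e-5 Angstrom^-2 (the conventional scaling, which brings
#                 these columns to the same magnitude as the geometric
#                 parameters); the set depends on the lattice constraint
#
# This gives the standard 13-parameter static problem for a single-panel
# orthorhombic experiment: 6 detector + 1 beam + 3 orientation + 3 cell.

.detector_labels <- c("dist", "shift1", "shift2", "tau1", "tau2", "tau3")
.beam_labels <- c("mu1", "mu2")
.orient_labels <- c("phi1", "phi2", "phi3")

#' Build a parameter set for geometry refinement
#'
#' Captures the current experiment as the reference state and exposes the
#' refinable parameters listed above. \code{mu1} (beam rotation about the
#' spindle axis) is fixed unless explicitly made scan-varying. Requesting
#' scan-varying behaviour for a label replaces its single static value by
#' \code{n} Gaussian-smoother sample values evenly spaced over the scan, and
#' unfixes the label.
#'
#' @param experiment \code{experiment_model} (reference state).
#' @param fix Character vector of labels to hold fixed. The stabilised
#'   protocol for electron diffraction fixes \code{c("dist", "tau2",
#'   "tau3")}.
#' @param scan_varying Named list/vector mapping labels to the number of
#'   smoother samples (>= 2), e.g. \code{list(phi1 = 3, mu2 = 2)}.
#' @param smoother_sigma Gaussian smoother width in sample-spacing units.
#' @return An object of class \code{parameter_set}.
#' @export
build_parameterisation <- function(experiment, fix = character(0),
                                   scan_varying = list(),
                                   smoother_sigma = 0.65) {
  cry <- experiment$crystal
  g_labels <- free_metrical_elements(cry$lattice_constraint)
  labels <- c(.detector_labels, .beam_labels, .orient_labels, g_labels)
  bad <- setdiff(c(fix, names(scan_varying)), labels)
  if (length(bad))
    stop(sprintf("edgeom_invalid_argument: unknown parameter label(s) %s; valid labels: %s",
                 paste(bad, collapse = ", "), paste(labels, collapse = ", ")))
  if (any(names(scan_varying) %in% .detector_labels))
    stop("edgeom_invalid_argument: detector parameters cannot be scan-varying")

  pan1 <- experiment$detector$panels[[1]]
  n0 <- panel_normal(pan1)
  centre0 <- pan1$origin +
    pan1$n_pixels[1] / 2 * pan1$pixel_size[1] * pan1$fast_axis +
    pan1$n_pixels[2] / 2 * pan1$pixel_size[2] * pan1$slow_axis
  dist0 <- sum(pan1$origin * n0)

  e <- experiment$goniometer$rotation_axis
  dir0 <- experiment$beam$direction
  b2 <- crossprod3(e, dir0)
  if (sqrt(sum(b2^2)) < 1e-8) b2 <- crossprod3(c(0, 1, 0), dir0)
  b2 <- .unit(b2)

  values <- stats::setNames(vector("list", length(labels)), labels)
  for (l in labels) values[[l]] <- 0
  values[["dist"]] <- dist0
  gfree <- g_star_free_values(cry$g_star, cry$lattice_constraint)
  for (k in seq_along(g_labels))
    values[[g_labels[k]]] <- unname(gfree[k]) * 1e5  # stored in 1e-5 A^-2

  fixed <- stats::setNames(labels %in% fix, labels)
  fixed[["mu1"]] <- fixed[["mu1"]] || !("mu1" %in% names(scan_varying))
  if ("mu1" %in% fix) fixed[["mu1"]] <- TRUE

  n_samples <- stats::setNames(rep(1L, length(labels)), labels)
  for (l in names(scan_varying)) {
    ns <- as.integer(scan_varying[[l]])
    if (ns < 2) stop("edgeom_invalid_argument: scan_varying sample count must be >= 2")
    if (fixed[[l]] && !(l %in% fix)) fixed[[l]] <- FALSE  # explicit request unfixes mu1
    if (!fixed[[l]]) {
      n_samples[[l]] <- ns
      values[[l]] <- rep(values[[l]], ns)
    }
  }
  if (!any(!fixed)) stop("edgeom_invalid_argument: at least one parameter must be free")

  structure(list(
    labels = labels, values = values, fixed = fixed, n_samples = n_samples,
    ref = list(experiment = experiment, U0 = cry$U, dir0 = dir0,
               beam_axis1 = e, beam_axis2 = b2,
               f0 = pan1$fast_axis, s0v = pan1$slow_axis, n0 = n0,
               centre0 = centre0, dist0 = dist0,
               origins0 = lapply(experiment$detector$panels, `[[`, "origin"),
               g_labels = g_labels,
               lattice = cry$lattice_constraint,
               scan = experiment$scan),
    smoother_sigma = smoother_sigma), class = "parameter_set")
}

#' Number of free parameters in a parameter set
#' @param params \code{parameter_set}.
#' @return Integer count (scan-varying samples counted individually).
#' @export
n_free_parameters <- function(params) length(free_parameter_vector(params))

#' Free parameter vector
#'
#' Concatenates the values of all unfixed parameters; scan-varying labels
#' contribute one entry per smoother sample, named \code{label@k}.
#'
#' @param params \code{parameter_set}.
#' @return Named numeric vector.
#' @export
free_parameter_vector <- function(params) {
  out <- numeric(0)
  for (l in params$labels) {
    if (params$fixed[[l]]) next
    v <- params$values[[l]]
    names(v) <- if (length(v) == 1) l else paste0(l, "@", seq_along(v))
    out <- c(out, v)
  }
  out
}

#' Replace the free parameter vector
#' @param params \code{parameter_set}.
#' @param vec Numeric vector as returned by
#'   \code{\link{free_parameter_vector}}.
#' @return Updated \code{parameter_set}.
#' @export
set_free_parameter_vector <- function(params, vec) {
  k <- 0L
  for (l in params$labels) {
    if (params$fixed[[l]]) next
    n <- length(params$values[[l]])
    params$values[[l]] <- as.numeric(vec[k + seq_len(n)])
    k <- k + n
  }
  stopifnot(k == length(vec))
  params
}

# Characteristic scale (units of the stored value) per parameter, used for
# finite-difference steps: 1 mrad for angles, 1e-6 A^-2 for metrical
# elements, 0.01 mm for detector distances.
parameter_scale <- function(label) {
  base <- sub("@.*", "", label)
  if (base %in% c("dist", "shift1", "shift2")) return(0.01)
  if (grepl("^g[0-9][0-9]$", base)) return(0.1)  # 1e-6 A^-2 in stored units
  1  # angles, mrad
}

# Evaluate the (possibly scan-varying) value of a label at image coordinates
# z (vectorised). Static labels return a constant.
param_value_at <- function(params, label, z) {
  v <- params$values[[label]]
  if (length(v) == 1) return(rep(v, length(z)))
  smoother_value(gaussian_smoother(length(v), v, params$smoother_sigma,
                                   scan = params$ref$scan), z)
}

# Compose a static experiment model from the parameter set, evaluating any
# scan-varying parameters at image coordinate z (scalar). Used for model
# export and per-image composition.
compose_experiment <- function(params, z = NULL) {
  ref <- params$ref
  if (is.null(z)) {
    rng <- ref$scan$image_range
    z <- (rng[2] - rng[1] + 1) / 2
  }
  val <- function(l) param_value_at(params, l, z)

  # beam
  mrad <- 180 / pi / 1000
  dir <- rotation_about_axis(ref$beam_axis1, val("mu1") * mrad) %*%
    rotation_about_axis(ref$beam_axis2, val("mu2") * mrad) %*% ref$dir0
  beam <- beam_model(.unit(as.numeric(dir)), ref$experiment$beam$wavelength)

  # crystal
  U <- rotation_about_axis(c(0, 0, 1), val("phi3") * mrad) %*%
    rotation_about_axis(c(0, 1, 0), val("phi2") * mrad) %*%
    rotation_about_axis(c(1, 0, 0), val("phi1") * mrad) %*% ref$U0
  gv <- vapply(ref$g_labels, val, 0) * 1e-5
  g <- g_star_from_free(gv, ref$lattice)
  crystal <- crystal_model(U, g, ref$lattice)

  # detector (rigid panel group; always static)
  detector <- compose_detector(params)
  sv <- NULL
  sv_labels <- params$labels[params$n_samples[params$labels] > 1]
  if (length(sv_labels)) {
    sv <- lapply(stats::setNames(sv_labels, sv_labels), function(l)
      gaussian_smoother(params$n_samples[[l]], params$values[[l]],
                        params$smoother_sigma, ref$scan))
  }
  experiment_model(beam, detector, ref$experiment$goniometer, ref$scan,
                   crystal, scan_varying = sv)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("Parameter set: %d free value(s)\n", n_free_parameters(x)))
  for (l in x$labels) {
    tag <- if (x$fixed[[l]]) "fixed" else if (x$n_samples[[l]] > 1)
      sprintf("scan-varying (%d samples)", x$n_samples[[l]]) else "free"
    cat(sprintf("  %-7s %-24s %s\n", l, tag,
                paste(signif(x$values[[l]], 6), collapse = " ")))
  }
  invisible(x)
}
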