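# Top-level refinement protocol: static refinement with optional restraints
# and outlier rejection, followed by optional scan-varying refinement of the
# crystal orientation, cell and beam direction with the detector held at its
# statically refined geometry.

#' Refine the diffraction geometry against observed centroids
#'
#' Runs the standard protocol: (1) static Levenberg-Marquardt refinement of
#' beam, crystal and detector parameters (subject to \code{fix}); (2) Tukey
#' outlier rejection on the static residuals followed by a second static
#' pass; (3) optionally, scan-varying refinement in which the crystal
#' orientation angles (default 3 smoother samples each), and optionally the
#' cell elements and the beam direction angles (default 2 samples each -
#' the simplest smoothed model), vary across the scan while all detector
#' parameters are fixed at their static values.
#'
#' @param experiment Initial \code{experiment_model}.
#' @param obs Reflection table with indexed observations.
#' @param fix Labels to fix throughout (e.g. \code{c("dist", "tau2",
#'   "tau3")}, the stabilised ED protocol).
#' @param restraints Optional \code{restraint_spec} applied during static
#'   refinement.
#' @param scan_varying Enable the scan-varying stage (default FALSE).
#' @param sv_orientation_samples Smoother samples per crystal orientation
#'   angle (default 3).
#' @param sv_beam Also refine the beam direction angles mu1 and mu2
#'   scan-varying (default FALSE).
#' @param sv_beam_samples Samples per beam angle (default 2).
#' @param sv_cell Also refine the free cell elements scan-varying (default
#'   FALSE; incompatible with restraints).
#' @param sv_cell_samples Samples per cell element (default 3).
#' @param outlier_rejection Reject outliers between static passes (default
#'   TRUE).
#' @param max_iterations LM iteration cap per pass (default 100).
#' @return List with \code{experiment} (refined; scan-varying smoothers
#'   attached when fitted), \code{obs} (flags updated), \code{static}
#'   and \code{scan_varying} LM results, and \code{rmsd} (final r.m.s.d.s).
#' @export
refine_geometry <- function(experiment, obs, fix = character(0),
                            restraints = NULL, scan_varying = FALSE,
                            sv_orientation_samples = 3, sv_beam = FALSE,
                            sv_beam_samples = 2, sv_cell = FALSE,
                            sv_cell_samples = 3, outlier_rejection = TRUE,
                            max_iterations = 100) {
  if (!any(has_flag(obs, "used_in_refinement")))
    obs <- set_flag(obs, "used_in_refinement", TRUE)

  factory <- function(p) {
    b <- residuals_and_jacobian(p, obs)
    if (!is.null(restraints)) b <- add_restraints(b, p, restraints)
    b
  }
  ps <- build_parameterisation(experiment, fix = fix)
  fit <- levenberg_marquardt(factory, ps, max_iterations)

  if (outlier_rejection) {
    b <- fit$bundle
    obs2 <- reject_outliers(obs, b$raw_residuals, b$used_rows)
    if (!identical(obs2$flags, obs$flags)) {
      obs <- obs2
      fit <- levenberg_marquardt(factory, fit$params, max_iterations)
    }
  }
  static_fit <- fit
  refined <- compose_experiment(fit$params)
  sv_fit <- NULL

  if (scan_varying) {
    svmap <- list(phi1 = sv_orientation_samples, phi2 = sv_orientation_samples,
                  phi3 = sv_orientation_samples)
    if (sv_beam) {
      svmap$mu1 <- sv_beam_samples
      svmap$mu2 <- sv_beam_samples
    }
    g_labels <- free_metrical_elements(experiment$crystal$lattice_constraint)
    if (sv_cell)
      for (l in g_labels) svmap[[l]] <- sv_cell_samples
    # the detector maintains the geometry from the static refinement step
    ps_sv <- build_parameterisation(refined, fix = .detector_labels,
                                    scan_varying = svmap)
    factory_sv <- function(p) residuals_and_jacobian(p, obs)
    sv_fit <- levenberg_marquardt(factory_sv, ps_sv, max_iterations)
    refined <- compose_experiment(sv_fit$params)
  }

  final <- if (is.null(sv_fit)) static_fit else sv_fit
  rms <- sqrt(colMeans(final$bundle$raw_residuals^2))
  list(experiment = refined, obs = obs, static = static_fit,
       scan_varying = sv_fit,
       rmsd = c(x_px = unname(rms[1]), y_px = unname(rms[2]),
                phi_deg = unname(rms[3])))
}

#' Per-image beam directions of a refined scan-varying model
#'
#' Convenience accessor: evaluates the refined beam direction at each image
#' centre of the scan.
#'
#' @param fit A scan-varying LM result (\code{$scan_varying} of
#'   \code{\link{refine_geometry}}).
#' @return Matrix (n_images x 3) of unit beam directions.
#' @export
beam_track <- function(fit) {
  ps <- fit$params
  nz <- ps$ref$scan$image_range[2] - ps$ref$scan$image_range[1] + 1
  z <- seq_len(nz) - 0.5
  mrad <- 1e-3
  mu1 <- param_value_at(ps, "mu1", z) * mrad
  mu2 <- param_value_at(ps, "mu2", z) * mrad
  dir <- matrix(ps$ref$dir0, 3, nz)
  dir <- .rot_cols(dir, ps$ref$beam_axis2, mu2)
  dir <- .rot_cols(dir, ps$ref$beam_axis1, mu1)
  t(dir)
}
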