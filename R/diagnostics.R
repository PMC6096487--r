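# Diagnostics for problematic diffraction geometry refinement: per-block
# parameter corrgrams, the Jacobian condition number, and the
# rotation-handedness comparison test.
#
# Both diagnostics act on the Jacobian WITHOUT any restraint
# pseudo-observation rows, so they describe the degeneracy inherent in the
# geometry itself, not modifications introduced to stabilise the procedure.
# They use the unweighted Jacobian with residuals in physical units
# (mm, mm, rad): centroid-variance weights belong to the estimator, not to
# the geometry, and the physical-unit convention is the one under which the
# characteristic ED-vs-MX conditioning contrast appears.

# Unweighted physical-unit (mm/mm/rad) Jacobian of a bundle.
.diag_jacobian <- function(bundle) {
  bundle$J / bundle$weights * bundle$row_scale_mm_rad
}

#' Per-block Jacobian correlation matrices (corrgrams)
#'
#' For each residual block (X, Y, phi), computes the Pearson correlation
#' between every pair of Jacobian columns restricted to that block's rows.
#' Columns whose norm within a block is below 1e-12 of the largest column
#' norm in that block (e.g. the detector parameters in the phi block, which
#' have no effect on predicted rotation angles) are omitted from that
#' block's matrix and listed in the \code{omitted} attribute.
#'
#' @param bundle \code{jacobian_bundle} (restraint rows, if any, are
#'   ignored).
#' @return Named list of three correlation matrices (\code{x}, \code{y},
#'   \code{phi}), each with an \code{omitted} attribute.
#' @export
corrgram_blocks <- function(bundle) {
  Jd <- .diag_jacobian(bundle)
  out <- lapply(bundle$block_bounds, function(rows) {
    Jb <- Jd[rows, , drop = FALSE]
    colnames(Jb) <- bundle$labels
    nrm <- sqrt(colSums(Jb^2))
    keep <- nrm >= 1e-12 * max(nrm)
    omitted <- bundle$labels[!keep]
    if (sum(keep) < 2) {
      m <- matrix(numeric(0), 0, 0)
      attr(m, "omitted") <- omitted
      attr(m, "note") <- "fewer than 2 usable columns"
      return(m)
    }
    m <- stats::cor(Jb[, keep, drop = FALSE])
    attr(m, "omitted") <- omitted
    m
  })
  names(out) <- names(bundle$block_bounds)
  out
}

#' Condition number of the refinement Jacobian
#'
#' kappa(J) = sigma_max / sigma_min from the singular value decomposition of
#' the physical-unit Jacobian (restraint rows excluded). Returns \code{Inf} when
#' the smallest singular value is below 1e-14 of the largest: an infinite
#' condition number means J is singular, while a finite value bounds the
#' attainable accuracy of the linearised subproblem. Large values are the
#' quantitative signature of the ill-posed refinement produced by the
#' nearly flat Ewald sphere of electron diffraction.
#'
#' @param bundle \code{jacobian_bundle}, or a plain matrix.
#' @return The condition number (possibly \code{Inf}).
#' @export
condition_number <- function(bundle) {
  J <- if (inherits(bundle, "jacobian_bundle")) .diag_jacobian(bundle)
    else as.matrix(bundle)
  if (!length(J)) stop("edgeom_invalid_argument: empty Jacobian")
  sv <- svd(J, nu = 0, nv = 0)$d
  if (sv[length(sv)] < 1e-14 * sv[1]) return(Inf)
  sv[1] / sv[length(sv)]
}

#' Rotation-handedness comparison test
#'
#' Tests both rotation-axis hypotheses (as modelled, and inverted) the way
#' a processing pipeline would: under each hypothesis the observations are
#' re-indexed by nearest-integer assignment (for the inverted hypothesis the
#' crystal is first given the compensating orientation that aligns the
#' inverted reconstruction with the lattice), the crystal orientation angles
#' are refined with everything else fixed, and the r.m.s.d.s of the angular
#' residuals are compared. The correct sense of rotation gives the lower phi
#' r.m.s.d.; with the nearly flat Ewald sphere of electron diffraction both
#' hypotheses can index and fit the centroids, so the r.m.s.d.s are close
#' and the verdict is marked \code{"ambiguous"} when they differ by less
#' than 10\%.
#'
#' @param experiment \code{experiment_model}.
#' @param obs Reflection table with indexed observations.
#' @param max_iterations LM cap per hypothesis (default 30).
#' @return List: \code{forward_rmsd_phi}, \code{inverted_rmsd_phi} (degrees;
#'   NA on refinement failure, with the error recorded in \code{errors}),
#'   \code{verdict} ("forward", "inverted" or "ambiguous").
#' @export
handedness_test <- function(experiment, obs, max_iterations = 30) {
  if (!any(has_flag(obs, "used_in_refinement")))
    obs <- set_flag(obs, "used_in_refinement", TRUE)
  fix_all_but_orientation <- c(.detector_labels, .beam_labels,
    free_metrical_elements(experiment$crystal$lattice_constraint))
  run <- function(exp2, invert) {
    if (invert) {
      # Compensating model for the inverted hypothesis: in the flat-sphere
      # limit the inverted-axis reconstruction is the mirror image of the
      # lattice through the plane perpendicular to the beam. Mirroring the
      # setting matrix and negating one basis vector (a pure re-indexing)
      # restores a proper rotation, which is how indexing would "succeed
      # either way".
      s0d <- exp2$beam$direction
      M <- diag(3) - 2 * tcrossprod(s0d)
      B <- b_matrix(exp2$crystal$g_star)
      A <- M %*% exp2$crystal$U %*% B %*% diag(c(1, 1, -1)) %*% solve(B)
      sv <- svd(A)
      U2 <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
      exp2$crystal <- crystal_model(U2, exp2$crystal$g_star,
                                    exp2$crystal$lattice_constraint)
    }
    obs2 <- assign_indices(obs, exp2)
    ps <- build_parameterisation(exp2, fix = fix_all_but_orientation)
    fit <- levenberg_marquardt(function(p) residuals_and_jacobian(p, obs2),
                               ps, max_iterations)
    sqrt(mean(fit$bundle$raw_residuals[, 3]^2))
  }
  errors <- list()
  fwd <- tryCatch(run(experiment, FALSE), error = function(e) {
    errors$forward <<- conditionMessage(e); NA_real_ })
  inv_exp <- experiment
  inv_exp$goniometer <- goniometer_model(-experiment$goniometer$rotation_axis)
  inv <- tryCatch(run(inv_exp, TRUE), error = function(e) {
    errors$inverted <<- conditionMessage(e); NA_real_ })
  n_img <- experiment$scan$image_range[2] - experiment$scan$image_range[1] + 1
  verdict <- if (n_img < 2) "ambiguous"  # a single image carries no rotation sense
  else if (is.na(fwd) || is.na(inv)) "ambiguous"
  else if (max(fwd, inv) < 1e-6) "ambiguous"  # both fit to numerical noise
  else if (abs(fwd - inv) < 0.1 * max(fwd, inv)) "ambiguous"
  else if (fwd < inv) "forward" else "inverted"
  list(forward_rmsd_phi = fwd, inverted_rmsd_phi = inv, verdict = verdict,
       errors = errors)
}
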