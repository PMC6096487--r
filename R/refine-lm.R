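# Residuals, Jacobian, unit-cell restraints and the Levenberg-Marquardt
# driver for geometry refinement.
#
# Each step of the nonlinear least-squares problem is linearised as
# J dp ~ dr, where the residual vector dr contains first the (X - X_o)
# components, then the (Y - Y_o) components and finally the (phi - phi_o)
# values, and J holds the partial derivatives of those residuals with
# respect to each free parameter, in matching blocks. Rows are weighted by
# the inverse standard deviation of each centroid coordinate (unit weights
# where variances are absent). Restraint pseudo-observations are carried as
# a separate appended block that never enters the diagnostics.

.obs_weights <- function(obs) {
  w <- function(v) ifelse(is.na(v) | v <= 0, 1, 1 / sqrt(v))
  list(x = w(obs$var_x), y = w(obs$var_y), phi = w(obs$var_phi))
}

.residual_vector <- function(params, obs) {
  pr <- predict_for_observations(params, obs)
  cbind(x = pr$x_calc - obs$x_obs,
        y = pr$y_calc - obs$y_obs,
        phi = pr$phi_calc - obs$phi_obs)
}

#' Residuals and Jacobian for the current model
#'
#' Computes the weighted residual vector and Jacobian for all observations
#' flagged \code{used_in_refinement} (all rows when none are flagged).
#' Derivatives are central finite differences with a step of 1e-4 of each
#' parameter's characteristic scale (1 mrad for angles, 1e-6 Angstrom^-2
#' for metrical elements, 0.01 mm for detector distances). Residual units
#' are pixels (X, Y) and degrees (phi).
#'
#' @param params \code{parameter_set}.
#' @param obs Reflection table with observed centroids and Miller indices.
#' @return An object of class \code{jacobian_bundle}: weighted Jacobian
#'   \code{J} (rows ordered X block, Y block, phi block), weighted residuals
#'   \code{delta_r}, \code{weights}, \code{block_bounds}, column
#'   \code{labels}, unweighted per-reflection \code{raw_residuals}, and a
#'   \code{restraints} slot (NULL until \code{\link{add_restraints}}).
#' @export
residuals_and_jacobian <- function(params, obs) {
  use <- has_flag(obs, "used_in_refinement")
  if (!any(use)) use <- rep(TRUE, nrow(obs))
  obs <- obs[use, , drop = FALSE]
  if (!nrow(obs)) stop("edgeom_refinement_error: no usable reflections")
  n <- nrow(obs)
  w <- .obs_weights(obs)
  wvec <- c(w$x, w$y, w$phi)

  res0 <- .residual_vector(params, obs)
  v0 <- free_parameter_vector(params)
  J <- matrix(0, 3 * n, length(v0))
  for (k in seq_along(v0)) {
    h <- 1e-4 * parameter_scale(names(v0)[k])
    vp <- v0; vp[k] <- v0[k] + h
    vm <- v0; vm[k] <- v0[k] - h
    rp <- .residual_vector(set_free_parameter_vector(params, vp), obs)
    rm <- .residual_vector(set_free_parameter_vector(params, vm), obs)
    J[, k] <- as.numeric((rp - rm) / (2 * h))
  }
  J <- J * wvec
  # per-row conversion from the px/deg residual units to mm/rad, used by the
  # diagnostics (which analyse the unweighted physical-unit Jacobian)
  panels <- compose_detector(params)$panels
  pxf <- vapply(panels, function(p) p$pixel_size[1], 0)[obs$panel + 1L]
  pxs <- vapply(panels, function(p) p$pixel_size[2], 0)[obs$panel + 1L]
  structure(list(J = J,
                 delta_r = as.numeric(res0) * wvec,
                 weights = wvec,
                 row_scale_mm_rad = c(pxf, pxs, rep(pi / 180, n)),
                 block_bounds = list(x = seq_len(n), y = n + seq_len(n),
                                     phi = 2 * n + seq_len(n)),
                 labels = names(v0),
                 raw_residuals = res0,
                 n_refl = n,
                 used_rows = which(use),
                 restraints = NULL),
            class = "jacobian_bundle")
}

# Real-space cell parameters free to vary under each lattice constraint;
# restraints on the others are dropped as already constrained by symmetry.
.cell_free <- list(
  triclinic    = c("a", "b", "c", "alpha", "beta", "gamma"),
  monoclinic   = c("a", "b", "c", "beta"),
  orthorhombic = c("a", "b", "c"),
  tetragonal   = c("a", "c"),
  hexagonal    = c("a", "c"),
  cubic        = "a"
)

#' Specify unit-cell restraints
#'
#' Each restraint ties one real-space cell parameter toward a target value
#' \code{a_t} with weight \code{w = 1/sigma^2}, contributing a
#' pseudo-observation with squared residual \code{w (a - a_t)^2} to the
#' least squares. Guidance: sigma around 0.001 gives a qualitatively
#' "strong" restraint and sigma around 0.1 a "weak" one; even weak
#' restraints help prevent the cell and detector distance drifting jointly
#' in electron-diffraction refinement.
#'
#' @param parameter Character vector from a, b, c, alpha, beta, gamma.
#' @param target Target values (Angstrom or degrees).
#' @param sigma Restraint standard deviations (> 0), recycled.
#' @return A \code{restraint_spec} data.frame.
#' @export
restraint_spec <- function(parameter, target, sigma) {
  parameter <- match.arg(parameter, c("a", "b", "c", "alpha", "beta", "gamma"),
                         several.ok = TRUE)
  if (any(sigma <= 0)) stop("edgeom_invalid_argument: sigma must be > 0")
  structure(data.frame(parameter = parameter, target = as.numeric(target),
                       sigma = rep_len(as.numeric(sigma), length(parameter))),
            class = c("restraint_spec", "data.frame"))
}

#' Append unit-cell restraint pseudo-observations to a Jacobian bundle
#'
#' Adds one row per active restraint: residual \code{sqrt(w) (a - a_t)} and
#' gradient \code{sqrt(w) da/dp} (finite differences with respect to the
#' free metrical elements), so the summed squares gain \code{w (a - a_t)^2}.
#' Restraints on cell parameters already constrained by the lattice symmetry
#' are dropped (e.g. the angle restraints of an orthorhombic cell). The
#' appended block is tagged separately and never enters the corrgram or
#' condition-number diagnostics. Restraints require a static cell.
#'
#' @param bundle \code{jacobian_bundle}.
#' @param params \code{parameter_set}.
#' @param spec \code{restraint_spec}.
#' @return The bundle with a populated \code{restraints} slot.
#' @export
add_restraints <- function(bundle, params, spec) {
  ref <- params$ref
  if (any(params$n_samples[ref$g_labels] > 1))
    stop("edgeom_unsupported: cell restraints are available for static cell models only")
  active <- spec[spec$parameter %in% .cell_free[[ref$lattice]], , drop = FALSE]
  if (!nrow(active)) {
    bundle$restraints <- list(J = matrix(0, 0, length(bundle$labels)),
                              r = numeric(0), parameters = character(0))
    return(bundle)
  }
  cell_idx <- match(active$parameter, c("a", "b", "c", "alpha", "beta", "gamma"))
  cell_of <- function(p) {
    gv <- vapply(ref$g_labels, function(l) p$values[[l]][1], 0) * 1e-5
    cell_from_metrical(g_star_from_free(gv, ref$lattice))
  }
  v0 <- free_parameter_vector(params)
  cur <- cell_of(params)[cell_idx]
  sw <- 1 / active$sigma
  Jr <- matrix(0, nrow(active), length(v0),
               dimnames = list(NULL, names(v0)))
  for (k in seq_along(v0)) {
    if (!grepl("^g[0-9][0-9]", names(v0)[k])) next
    h <- 1e-4 * parameter_scale(names(v0)[k])
    vp <- v0; vp[k] <- v0[k] + h
    vm <- v0; vm[k] <- v0[k] - h
    cp <- cell_of(set_free_parameter_vector(params, vp))[cell_idx]
    cm <- cell_of(set_free_parameter_vector(params, vm))[cell_idx]
    Jr[, k] <- sw * (cp - cm) / (2 * h)
  }
  bundle$restraints <- list(J = Jr, r = sw * (cur - active$target),
                            parameters = active$parameter)
  bundle
}

#' Levenberg-Marquardt refinement driver
#'
#' Minimises the weighted sum of squared residuals (including any restraint
#' pseudo-observations) over the free parameters. Damping starts at
#' \code{1e-3 * max(diag(JtJ))}, is multiplied by 10 on a rejected step and
#' divided by 10 on an accepted one. Refinement terminates when the r.m.s.d.
#' of every residual dimension improves by less than 0.01\% over an accepted
#' step (negligible further reduction), when all r.m.s.d.s are numerically
#' zero, or after \code{max_iterations} steps (default 100).
#'
#' @param bundle_factory Function(parameter_set) -> \code{jacobian_bundle}
#'   (with restraints already appended if used).
#' @param params Initial \code{parameter_set}.
#' @param max_iterations Iteration cap, >= 1 (default 100).
#' @return List: \code{params} (refined), \code{report} (data.frame of
#'   per-iteration r.m.s.d.s in X/Y px and phi deg, cost, damping, step
#'   acceptance), \code{converged}, \code{n_iterations}, \code{bundle} (the
#'   final-step Jacobian bundle, for diagnostics).
#' @export
levenberg_marquardt <- function(bundle_factory, params, max_iterations = 100) {
  if (max_iterations < 1)
    stop("edgeom_invalid_argument: max_iterations must be >= 1")
  full <- function(b) {
    if (is.null(b$restraints)) list(J = b$J, r = b$delta_r)
    else list(J = rbind(b$J, b$restraints$J), r = c(b$delta_r, b$restraints$r))
  }
  rmsds <- function(b) sqrt(colMeans(b$raw_residuals^2))
  cost <- function(b) { f <- full(b); sum(f$r^2) }

  b <- bundle_factory(params)
  if (any(!is.finite(b$delta_r)))
    stop("edgeom_refinement_error: non-finite residuals at start; parameters: ",
         paste(sprintf("%s=%.6g", b$labels, free_parameter_vector(params)),
               collapse = ", "))
  rm0 <- rmsds(b)
  hist <- data.frame(iteration = 0L, rmsd_x = rm0[1], rmsd_y = rm0[2],
                     rmsd_phi = rm0[3], cost = cost(b), lambda = NA,
                     accepted = NA)
  if (all(rm0 < 1e-12)) {
    return(list(params = params, report = hist, converged = TRUE,
                n_iterations = 0L, bundle = b))
  }
  f <- full(b)
  JtJ <- crossprod(f$J)
  lam <- 1e-3 * max(diag(JtJ))
  c0 <- cost(b)
  converged <- FALSE
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    g <- crossprod(f$J, f$r)
    step <- tryCatch(solve(JtJ + lam * diag(nrow(JtJ)), -g),
                     error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step)) {
      trial <- set_free_parameter_vector(params,
                                         free_parameter_vector(params) + as.numeric(step))
      bt <- tryCatch(bundle_factory(trial), error = function(e) NULL)
      if (!is.null(bt) && all(is.finite(bt$delta_r)) && cost(bt) < c0) {
        accepted <- TRUE
        rm_old <- rmsds(b)
        params <- trial; b <- bt; f <- full(b); JtJ <- crossprod(f$J)
        c0 <- cost(b)
        rm_new <- rmsds(b)
        lam <- lam / 10
        improve <- (rm_old - rm_new) / pmax(rm_old, .Machine$double.xmin)
        if (all(improve < 1e-4) || all(rm_new < 1e-10)) converged <- TRUE
      }
    }
    if (!accepted) {
      lam <- lam * 10
      if (lam > 1e16 * max(diag(JtJ))) converged <- TRUE  # stalled
    }
    rm_now <- rmsds(b)
    hist <- rbind(hist, data.frame(iteration = it, rmsd_x = rm_now[1],
                                   rmsd_y = rm_now[2], rmsd_phi = rm_now[3],
                                   cost = c0, lambda = lam,
                                   accepted = accepted))
    if (converged) break
  }
  list(params = params, report = hist, converged = converged,
       n_iterations = it, bundle = b)
}

#' Flag residual outliers with Tukey fences
#'
#' A reflection is flagged as an outlier when any of its residual dimensions
#' (X, Y, phi) lies more than 3 interquartile ranges beyond the quartiles of
#' that dimension. Outliers get the \code{outlier} flag set and their
#' \code{used_in_refinement} flag cleared; nothing is deleted, and the flags
#' are idempotent under repeated application to unchanged residuals.
#'
#' @param obs Reflection table.
#' @param residuals Matrix (n x 3) of residuals for the rows in \code{rows}.
#' @param rows Row indices of \code{obs} that \code{residuals} refer to
#'   (default all rows).
#' @return The updated reflection table.
#' @export
reject_outliers <- function(obs, residuals, rows = seq_len(nrow(obs))) {
  residuals <- as.matrix(residuals)
  bad <- rep(FALSE, nrow(residuals))
  for (j in seq_len(ncol(residuals))) {
    q <- stats::quantile(residuals[, j], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    bad <- bad | residuals[, j] < q[1] - 3 * iqr | residuals[, j] > q[2] + 3 * iqr
  }
  obs <- set_flag(obs, "outlier", bad, rows)
  obs <- set_flag(obs, "used_in_refinement", !bad, rows)
  obs
}
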