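# Reflection table: observed and predicted centroids with variances, indices,
# panel ids and status flags. A plain data.frame subclass so the usual
# subsetting/merging idioms apply.

#' Reflection flag bit values
#'
#' Bitset values used in the \code{flags} column of a reflection table.
#' @export
reflection_flags <- c(observed = 1L, predicted = 2L, indexed = 4L,
                      outlier = 8L, used_in_refinement = 16L)

#' Construct a reflection table
#'
#' Columns: Miller indices \code{h, k, l}; 0-based \code{panel} id; observed
#' centroid \code{x_obs, y_obs} (pixels), \code{phi_obs} (degrees) with
#' variances \code{var_x, var_y} (px^2) and \code{var_phi} (deg^2); predicted
#' centroid \code{x_calc, y_calc, phi_calc}; integer \code{flags} (see
#' \code{\link{reflection_flags}}). Missing columns are filled with NA (0 for
#' flags).
#'
#' @param df A data.frame holding any subset of the columns above.
#' @return A data.frame of class \code{reflection_table}.
#' @export
reflection_table <- function(df = data.frame()) {
  cols <- c("h", "k", "l", "panel", "x_obs", "y_obs", "phi_obs",
            "var_x", "var_y", "var_phi", "x_calc", "y_calc", "phi_calc",
            "flags")
  df <- as.data.frame(df)
  for (col in cols) {
    if (is.null(df[[col]]))
      df[[col]] <- if (col == "flags") rep(0L, nrow(df)) else rep(NA_real_, nrow(df))
  }
  vr <- c(df$var_x, df$var_y, df$var_phi)
  if (any(!is.na(vr) & vr < 0))
    stop("edgeom_invalid_argument: variances must be >= 0")
  df <- df[cols]
  class(df) <- c("reflection_table", "data.frame")
  df
}

#' Test reflection flags
#'
#' @param refl A reflection table.
#' @param flag Flag name (see \code{\link{reflection_flags}}).
#' @return Logical vector.
#' @export
has_flag <- function(refl, flag) {
  bit <- reflection_flags[[flag]]
  bitwAnd(refl$flags, bit) != 0L
}

#' Set or clear reflection flags
#'
#' @param refl A reflection table.
#' @param flag Flag name.
#' @param value Logical (recycled) - set where TRUE, clear where FALSE.
#' @param rows Optional row subset (default all).
#' @return The modified reflection table.
#' @export
set_flag <- function(refl, flag, value = TRUE, rows = seq_len(nrow(refl))) {
  bit <- reflection_flags[[flag]]
  value <- rep_len(value, length(rows))
  f <- refl$flags[rows]
  f[value] <- bitwOr(f[value], bit)
  f[!value] <- bitwAnd(f[!value], bitwNot(bit))
  refl$flags[rows] <- f
  refl
}
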