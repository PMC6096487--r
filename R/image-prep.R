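# Detector-image handling: Timepix quad expansion, gain estimation,
# dispersion-threshold spot finding and rotation-axis azimuth estimation.
#
# Frames are integer/numeric matrices with the FIRST index running along the
# detector fast axis (x) and the second along the slow axis (y). Continuous
# pixel coordinates are 0-based, so the centre of the 1-based matrix element
# [i, j] is at continuous coordinate (i - 0.5, j - 0.5).

#' Expand a 512x512 Timepix quad into a gain-corrected 516x516 frame
#'
#' A Timepix quad is four abutting 256x256 ASICs. The pixels at the ASIC
#' boundaries (1-based x and/or y coordinate 256 or 257) have roughly three
#' times the pitch of ordinary pixels, so they collect about three times the
#' counts. Each such row/column is split into three ordinary-width
#' rows/columns, each REPLICATING the full original count, giving 516x516
#' frames with a six-pixel-wide cross of ~3x gain. The non-uniformity is then
#' removed by multiplying all pixels outside the cross by three, so the whole
#' corrected frame behaves as a Poisson detector with a multiplicative gain
#' of 3.0.
#'
#' @param raw_quad Integer matrix, exactly 512x512.
#' @return List with \code{frame} (516x516 integer matrix), \code{cross_mask}
#'   (logical 516x516, TRUE on the six-wide cross) and \code{gain} (3.0, the
#'   effective multiplicative gain of the corrected frame).
#' @export
timepix_expand <- function(raw_quad) {
  raw_quad <- as.matrix(raw_quad)
  if (!all(dim(raw_quad) == c(512, 512)))
    stop("edgeom_invalid_argument: raw_quad must be exactly 512x512")
  map <- c(1:255, rep(256L, 3), rep(257L, 3), 258:512)  # length 516
  out <- raw_quad[map, map]
  cross_idx <- 256:261
  mask <- matrix(FALSE, 516, 516)
  mask[cross_idx, ] <- TRUE
  mask[, cross_idx] <- TRUE
  out[!mask] <- out[!mask] * 3L
  list(frame = out, cross_mask = mask, gain = 3.0)
}

#' Estimate detector gain from a region of interest
#'
#' Gain is estimated as the index of dispersion (variance / mean) of the
#' counts in a flat region: a Poisson detector has var = mean, so the ratio
#' is the multiplicative gain. The estimate is biased low when the detector
#' has a significant point spread.
#'
#' @param frame Count matrix.
#' @param roi 1-based inclusive rectangle \code{c(x0, x1, y0, y1)} in matrix
#'   indices (fast, slow). At least 100 pixels are recommended.
#' @return Estimated gain (scalar). A constant ROI returns 0 with a warning.
#' @export
estimate_gain <- function(frame, roi) {
  if (length(roi) != 4 || roi[2] < roi[1] || roi[4] < roi[3])
    stop("edgeom_invalid_argument: roi must be c(x0, x1, y0, y1), non-empty")
  px <- as.numeric(frame[roi[1]:roi[2], roi[3]:roi[4]])
  if (length(px) < 2) stop("edgeom_invalid_argument: roi too small")
  m <- mean(px)
  if (m <= 0) stop("edgeom_undefined_gain: ROI mean <= 0")
  v <- stats::var(px)
  if (v == 0) {
    warning("constant ROI: gain undefined, returning 0")
    return(0)
  }
  v / m
}

# Box-filter local sums over a k x k window (k odd), clipped at the frame
# borders, via a padded summed-area table. Returns a matrix of the same size.
.box_sum <- function(mat, k) {
  r <- (k - 1L) %/% 2L
  nf <- nrow(mat); ns <- ncol(mat)
  S <- matrix(0, nf + 1, ns + 1)
  S[-1, -1] <- apply(apply(mat, 2, cumsum), 1, cumsum) |> t()
  i0 <- pmax(seq_len(nf) - r - 1L, 0L); i1 <- pmin(seq_len(nf) + r, nf)
  j0 <- pmax(seq_len(ns) - r - 1L, 0L); j1 <- pmin(seq_len(ns) + r, ns)
  S[i1 + 1, j1 + 1] - S[i0 + 1, j1 + 1] - S[i1 + 1, j0 + 1] + S[i0 + 1, j0 + 1]
}

#' Dispersion-threshold spot finding
#'
#' Classifies pixels as "strong" using the index-of-dispersion criterion:
#' a pixel is strong iff, over its local \code{kernel} x \code{kernel} window
#' (masked pixels excluded),
#' \enumerate{
#'   \item \code{var/mean > gain * (1 + sigma_b * sqrt(2/(n-1)))} (the local
#'     counts are overdispersed relative to a Poisson background),
#'   \item \code{count - mean > sigma_strong * sqrt(gain * mean)} (the pixel
#'     itself stands above the local background), and
#'   \item \code{count > global_threshold}.
#' }
#' Strong pixels are merged by 8-connectivity; components smaller than
#' \code{min_spot_size} are discarded; centroids are intensity-weighted.
#'
#' @param frame Count matrix (fast x slow).
#' @param panel Optional \code{panel_model} (0-based panel id recorded from
#'   its position is the caller's concern; here only used for bookkeeping).
#' @param gain Detector gain used by the threshold (acts multiplicatively).
#' @param sigma_b Background dispersion significance (default 6).
#' @param sigma_strong Pixel significance above local mean (default 3).
#' @param global_threshold Absolute minimum count (default 0).
#' @param kernel Odd local-window size (default 7, i.e. a kernel half-width
#'   of 3 pixels; the window must be larger than the spots' core for the
#'   local mean to represent background).
#' @param min_spot_size Minimum pixels per spot (default 2).
#' @param mask Optional logical matrix, TRUE = masked (excluded).
#' @param panel_id Panel id recorded in the spot list (default 0).
#' @return A \code{spot_list} data.frame: panel, x, y (0-based continuous
#'   pixel centroid), total counts, n_pixels, bounding box columns
#'   \code{x0, x1, y0, y1} (0-based, half-open).
#' @export
dispersion_find_spots <- function(frame, panel = NULL, gain = 1,
                                  sigma_b = 6, sigma_strong = 3,
                                  global_threshold = 0, kernel = 7,
                                  min_spot_size = 2, mask = NULL,
                                  panel_id = 0L) {
  if (kernel < 3 || kernel %% 2 == 0)
    stop("edgeom_invalid_argument: kernel must be odd and >= 3")
  if (gain <= 0 || sigma_b <= 0 || sigma_strong <= 0 || global_threshold < 0)
    stop("edgeom_invalid_argument: bad spot-finding parameters")
  frame <- as.matrix(frame)
  valid <- if (is.null(mask)) matrix(TRUE, nrow(frame), ncol(frame)) else !mask
  if (!any(valid)) return(.empty_spot_list())
  f <- frame * valid
  n <- .box_sum(valid * 1, kernel)
  s1 <- .box_sum(f, kernel)
  s2 <- .box_sum(f * f, kernel)
  m <- ifelse(n > 0, s1 / n, 0)
  v <- ifelse(n > 1, pmax(0, (s2 - n * m^2) / (n - 1)), 0)
  disp_ok <- n > 1 & m > 0 &
    v / pmax(m, .Machine$double.eps) > gain * (1 + sigma_b * sqrt(2 / pmax(n - 1, 1)))
  strong <- valid & disp_ok &
    (frame - m) > sigma_strong * sqrt(gain * pmax(m, 0)) &
    frame > global_threshold
  .label_spots(frame, strong, min_spot_size, panel_id)
}

.empty_spot_list <- function() {
  structure(data.frame(panel = integer(0), x = numeric(0), y = numeric(0),
                       total = numeric(0), n_pixels = integer(0),
                       x0 = numeric(0), x1 = numeric(0),
                       y0 = numeric(0), y1 = numeric(0)),
            class = c("spot_list", "data.frame"))
}

# 8-connected component labelling of strong pixels and centroid extraction.
.label_spots <- function(frame, strong, min_spot_size, panel_id) {
  idx <- which(strong, arr.ind = TRUE)
  if (!nrow(idx)) return(.empty_spot_list())
  nf <- nrow(frame)
  key <- (idx[, 2] - 1L) * nf + idx[, 1]  # linear index
  pos <- integer(nf * ncol(frame))
  pos[key] <- seq_along(key)
  # edges to the 4 forward neighbours (8-connectivity, undirected)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  edges <- NULL
  for (o in offs) {
    ni <- idx[, 1] + o[1]; nj <- idx[, 2] + o[2]
    ok <- ni >= 1 & ni <= nf & nj >= 1 & nj <= ncol(frame)
    nk <- (nj[ok] - 1L) * nf + ni[ok]
    hit <- pos[nk] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], pos[nk][hit]))
  }
  comp <- if (is.null(edges)) seq_len(nrow(idx)) else {
    g <- igraph::make_graph(edges = as.vector(t(edges)), n = nrow(idx),
                            directed = FALSE)
    igraph::components(g)$membership
  }
  counts <- frame[cbind(idx[, 1], idx[, 2])]
  spots <- lapply(split(seq_along(comp), comp), function(rows) {
    if (length(rows) < min_spot_size) return(NULL)
    w <- counts[rows]
    cx <- sum((idx[rows, 1] - 0.5) * w) / sum(w)
    cy <- sum((idx[rows, 2] - 0.5) * w) / sum(w)
    data.frame(panel = panel_id, x = cx, y = cy, total = sum(w),
               n_pixels = length(rows),
               x0 = min(idx[rows, 1]) - 1, x1 = max(idx[rows, 1]),
               y0 = min(idx[rows, 2]) - 1, y1 = max(idx[rows, 2]))
  })
  spots <- do.call(rbind, spots)
  if (is.null(spots)) return(.empty_spot_list())
  rownames(spots) <- NULL
  class(spots) <- c("spot_list", "data.frame")
  spots
}

#' Estimate the rotation-axis azimuth from a spot field
#'
#' The projection of the rotation axis onto the detector forms a line through
#' the beam centre along which reflections have the widest reflecting range
#' and few spots are found. Spots are binned by the azimuth of
#' \code{spot - beam_centre} modulo 180 degrees (36 bins), the histogram is
#' smoothed with a 3-bin circular moving average, and the bin centre of
#' minimum density is returned.
#'
#' @param spots A \code{spot_list} (>= 50 spots recommended).
#' @param beam_centre \code{c(x, y)} in pixels.
#' @param n_bins Number of azimuthal bins over [0, 180) (default 36).
#' @return Angle in degrees in [0, 180), with attribute \code{confidence}
#'   ("ok" or "low") and \code{histogram} (the smoothed bin densities).
#' @export
estimate_axis_azimuth <- function(spots, beam_centre, n_bins = 36) {
  ang <- (atan2(spots$y - beam_centre[2], spots$x - beam_centre[1]) * 180 / pi) %% 180
  width <- 180 / n_bins
  bin <- pmin(floor(ang / width) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  sm <- (counts + counts[c(n_bins, 1:(n_bins - 1))] +
           counts[c(2:n_bins, 1)]) / 3
  best <- which.min(sm)
  out <- (best - 0.5) * width
  deficit <- mean(sm) - min(sm)
  conf <- if (nrow(spots) < 50 || deficit <= 3 * sqrt(mean(sm) / 3)) "low" else "ok"
  if (conf == "low")
    warning("axis azimuth estimate is low-confidence (few spots or no clear minimum)")
  structure(out, confidence = conf, histogram = sm)
}
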