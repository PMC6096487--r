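# File formats: experiment description JSON (versioned schema), reflection
# tables (commented CSV + RDS binary container), distortion maps (JSON
# header + raw float32), raw frames (TIFF single panel / binary container
# with JSON sidecar), and flat key=value configuration files.

.schema_version <- "1.0"

.exp_to_list <- function(exp) {
  sv <- NULL
  if (!is.null(exp$scan_varying)) {
    sv <- lapply(exp$scan_varying, function(s)
      list(n_samples = s$n_samples, values = s$values, sigma = s$sigma))
  }
  list(
    schema_version = .schema_version,
    beam = list(direction = exp$beam$direction,
                wavelength = exp$beam$wavelength),
    detector = list(panels = lapply(exp$detector$panels, function(p)
      list(origin = p$origin, fast_axis = p$fast_axis,
           slow_axis = p$slow_axis, pixel_size = p$pixel_size,
           n_pixels = p$n_pixels, gain = p$gain))),
    goniometer = list(rotation_axis = exp$goniometer$rotation_axis),
    scan = list(image_range = exp$scan$image_range,
                oscillation = exp$scan$oscillation),
    crystal = list(U = as.numeric(exp$crystal$U),
                   g_star = as.numeric(exp$crystal$g_star),
                   lattice_constraint = exp$crystal$lattice_constraint),
    scan_varying = sv)
}

#' Write an experiment description file (JSON)
#'
#' Canonical, versioned JSON serialization of an \code{experiment_model}.
#' Numbers are written at full precision, so write-read-write cycles are
#' byte-identical. Panel distortion maps are not embedded; they live in
#' separate map files (\code{\link{write_distortion_maps}}).
#'
#' @param exp \code{experiment_model}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_experiment <- function(exp, path) {
  js <- jsonlite::toJSON(.exp_to_list(exp), digits = NA, auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
  writeLines(js, path)
  invisible(path)
}

#' Read an experiment description file (JSON)
#'
#' @param path File written by \code{\link{write_experiment}}.
#' @return An \code{experiment_model}.
#' @export
read_experiment <- function(path) {
  x <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  if (is.null(x$schema_version))
    stop("edgeom_validation_error: missing schema_version")
  if (!identical(x$schema_version, .schema_version))
    stop(sprintf("edgeom_unsupported_version: schema_version %s (supported: %s)",
                 x$schema_version, .schema_version))
  need <- c("beam", "detector", "goniometer", "scan", "crystal")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("edgeom_validation_error: missing key(s) ", paste(miss, collapse = ", "))
  panels <- lapply(seq_len(nrow(x$detector$panels)), function(i) {
    p <- lapply(x$detector$panels, function(col)
      if (is.matrix(col)) col[i, ] else col[[i]])
    panel_model(p$origin, p$fast_axis, p$slow_axis, p$pixel_size,
                p$n_pixels, p$gain)
  })
  exp <- experiment_model(
    beam_model(x$beam$direction, x$beam$wavelength),
    detector_model(panels),
    goniometer_model(x$goniometer$rotation_axis),
    scan_model(x$scan$image_range, x$scan$oscillation),
    crystal_model(matrix(x$crystal$U, 3, 3), matrix(x$crystal$g_star, 3, 3),
                  x$crystal$lattice_constraint))
  if (!is.null(x$scan_varying) && length(x$scan_varying)) {
    exp$scan_varying <- lapply(x$scan_varying, function(s)
      gaussian_smoother(s$n_samples, s$values, s$sigma, exp$scan))
  }
  exp
}

#' Write a reflection table as commented CSV
#'
#' Plain CSV preceded by comment lines naming the format version, the
#' column units and the flag bit meanings; reading it back is lossless at
#' full numeric precision.
#'
#' @param refl \code{reflection_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_reflections <- function(refl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# edgeom reflection table v1",
    "# units: x/y px (0-based continuous), phi deg, var_* px^2 / deg^2",
    sprintf("# flags: %s", paste(sprintf("%s=%d", names(reflection_flags),
                                         reflection_flags), collapse = " "))),
    con)
  utils::write.csv(format(as.data.frame(refl), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reflection table written by \code{\link{write_reflections}}
#' @param path CSV path.
#' @return A \code{reflection_table}.
#' @export
read_reflections <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  df$flags <- as.integer(df$flags)
  for (col in c("h", "k", "l", "panel")) df[[col]] <- as.integer(df[[col]])
  reflection_table(df)
}

#' Write/read a reflection table as a binary container (RDS)
#'
#' Lossless binary serialization of the same table.
#' @param refl \code{reflection_table}.
#' @param path Path (conventionally .rds).
#' @return \code{path} / the table.
#' @rdname reflections_bin
#' @export
write_reflections_bin <- function(refl, path) {
  saveRDS(refl, path, version = 2)
  invisible(path)
}

#' @rdname reflections_bin
#' @export
read_reflections_bin <- function(path) {
  refl <- readRDS(path)
  reflection_table(refl)
}

#' Write distortion maps (JSON header + raw float32 arrays)
#'
#' \code{path.json} names the panel shape, sign convention and byte layout;
#' \code{path.bin} holds the fast map then the slow map as little-endian
#' 32-bit floats in column-major order.
#'
#' @param maps \code{distortion_map_pair}.
#' @param path Base path (without extension).
#' @param panel_id Panel the maps belong to (default 0).
#' @return Base \code{path}, invisibly.
#' @export
write_distortion_maps <- function(maps, path, panel_id = 0L) {
  hdr <- list(format = "edgeom distortion maps v1", panel = panel_id,
              shape = dim(maps$offset_fast),
              sign_convention = "corrected - raw, pixels",
              dtype = "float32", byte_order = "little",
              order = c("fast", "slow"))
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, pretty = TRUE),
             paste0(path, ".json"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(maps$offset_fast), con, size = 4, endian = "little")
  writeBin(as.numeric(maps$offset_slow), con, size = 4, endian = "little")
  invisible(path)
}

#' Read distortion maps written by \code{\link{write_distortion_maps}}
#' @param path Base path (without extension).
#' @return A \code{distortion_map_pair}.
#' @export
read_distortion_maps <- function(path) {
  hdr <- jsonlite::fromJSON(readLines(paste0(path, ".json")))
  shp <- as.integer(hdr$shape)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  n <- prod(shp)
  f <- readBin(con, "numeric", n, size = 4, endian = "little")
  s <- readBin(con, "numeric", n, size = 4, endian = "little")
  distortion_map_pair(matrix(f, shp[1], shp[2]), matrix(s, shp[1], shp[2]))
}

#' Write a single-panel frame as 16-bit TIFF
#'
#' Counts above 65535 are clipped (TIFF container limit); exact count
#' round-tripping for arbitrary depth uses \code{\link{write_frames_bin}}.
#'
#' @param frame Integer count matrix (fast x slow).
#' @param path Output .tif path.
#' @return \code{path}, invisibly.
#' @export
write_frame_tiff <- function(frame, path) {
  m <- pmin(pmax(t(frame), 0), 65535) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a frame written by \code{\link{write_frame_tiff}}
#' @param path .tif path.
#' @return Integer count matrix (fast x slow).
#' @export
read_frame_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(t(m) * 65535)), ncol(m), nrow(m))
}

#' Write/read a multi-panel frame stack as a binary container
#'
#' \code{path.json} records image numbers and per-panel shapes;
#' \code{path.bin} holds int32 counts, frames in order, panels within
#' frames, column-major.
#'
#' @param frames List of frames; each frame is a matrix (single panel) or a
#'   list of per-panel matrices.
#' @param path Base path (without extension).
#' @return Base \code{path} / the frame list.
#' @rdname frames_bin
#' @export
write_frames_bin <- function(frames, path) {
  norm <- lapply(frames, function(f) if (is.matrix(f)) list(f) else f)
  hdr <- list(format = "edgeom frames v1", n_frames = length(norm),
              n_panels = length(norm[[1]]),
              shapes = lapply(norm[[1]], dim), dtype = "int32",
              byte_order = "little")
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, pretty = TRUE),
             paste0(path, ".json"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (f in norm) for (p in f)
    writeBin(as.integer(p), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname frames_bin
#' @export
read_frames_bin <- function(path) {
  hdr <- jsonlite::fromJSON(readLines(paste0(path, ".json")))
  shapes <- hdr$shapes
  if (is.matrix(shapes)) shapes <- asplit(shapes, 1)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  lapply(seq_len(hdr$n_frames), function(i) {
    f <- lapply(shapes, function(s) {
      s <- as.integer(s)
      matrix(readBin(con, "integer", prod(s), size = 4, endian = "little"),
             s[1], s[2])
    })
    if (length(f) == 1) f[[1]] else f
  })
}

#' Read a flat key=value configuration file
#'
#' One \code{key = value} pair per line; \code{#} starts a comment. Values
#' are parsed as numbers, logicals or comma-separated lists where possible.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2)
      stop("edgeom_validation_error: bad config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!any(is.na(num))) num
      else if (all(parts %in% c("true", "false", "TRUE", "FALSE")))
        as.logical(toupper(parts))
      else if (length(parts) > 1) parts else val
  }
  out
}
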