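#' Read a multi-page grayscale TIFF into an image stack
#'
#' Planes are taken in file order as z. Integer-typed files are read with
#' intensities unmodified (e.g. a 16-bit file yields values in 0..65535);
#' float files are read as stored.
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param voxel_size `c(x, y, z)` voxel size in micrometers.
#' @return an [image_stack].
#' @export
read_stack <- function(path, voxel_size) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    stop("multi-channel/RGB TIFF pages are not supported; expected grayscale")
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 32L
  d <- dim(pages[[1]])
  vox <- array(0, dim = c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) vox[z, , ] <- pages[[z]]
  if (bits <= 16) {
    vox <- round(vox * (2^bits - 1))
  } else {
    sidecar <- paste0(path, ".range.json")
    if (file.exists(sidecar)) {
      rg <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      vox <- vox * rg$scale + rg$offset
    }
  }
  image_stack(vox, voxel_size)
}

#' Write an image stack as a multi-page TIFF
#'
#' Integer-valued stacks are written as 8- or 16-bit unsigned grayscale
#' (whichever fits the value range) and round-trip exactly through
#' [read_stack()]. Float stacks are written with 32-bit samples: values in
#' `[0, 1]` (probability maps) are stored on their native scale; other float
#' data is affine-mapped into `[0, 1]` with the mapping recorded in a
#' `<path>.range.json` sidecar, so [read_stack()] restores original values
#' to within 32-bit quantization.
#'
#' @param stack an [image_stack].
#' @param path output path.
#' @export
write_stack <- function(stack, path) {
  stopifnot_stack(stack)
  v <- stack$voxels
  integerish <- all(v == round(v)) && min(v) >= 0 && max(v) <= 65535
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , , drop = TRUE])
  sidecar <- paste0(path, ".range.json")
  if (file.exists(sidecar)) unlink(sidecar)
  if (integerish) {
    bits <- if (max(v) <= 255) 8L else 16L
    top <- 2^bits - 1
    pages <- lapply(pages, function(p) matrix(p, nrow = dim(v)[2]) / top)
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else if (min(v) >= 0 && max(v) <= 1) {
    # probability maps: stored as 32-bit samples on the native [0, 1] scale
    pages <- lapply(pages, function(p) matrix(p, nrow = dim(v)[2]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    # general float data: affine-mapped into [0, 1] for storage; the mapping
    # is recorded in a small JSON sidecar so reads restore original values
    lo <- min(v)
    hi <- max(v)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(pages, function(p) matrix((p - lo) / scale, nrow = dim(v)[2]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    jsonlite::write_json(list(offset = lo, scale = scale), sidecar,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an SWC neuron tracing
#'
#' Standard whitespace-delimited SWC with `#` comment lines. Each node is
#' `(id, type, x, y, z, radius, parent)`; a parent of `-1` marks a root and is
#' mapped to `NA`. Coordinates are interpreted in micrometers by default;
#' tracings saved in pixel units can be converted with `unit = "px"` and the
#' stack voxel size.
#'
#' @param path path to SWC file.
#' @param unit `"um"` (default) or `"px"`; with `"px"`, coordinates and radii
#'   are multiplied by `voxel_size` (radius by the xy component) to obtain um.
#' @param voxel_size required for `unit = "px"`: `c(x, y, z)` um per pixel.
#' @return a `swc_tracing`: data.frame with columns `id, type, x_um, y_um,
#'   z_um, radius_um, parent` (parent `NA` for roots).
#' @export
read_swc <- function(path, unit = c("um", "px"), voxel_size = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    df <- data.frame(id = integer(), type = integer(), x_um = numeric(),
                     y_um = numeric(), z_um = numeric(), radius_um = numeric(),
                     parent = integer())
    class(df) <- c("swc_tracing", "data.frame")
    return(df)
  }
  fields <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(fields) != 7L)) {
    stop("malformed SWC line: expected 7 whitespace-separated fields")
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (any(!is.finite(m))) stop("malformed SWC line: non-numeric field")
  df <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                   x_um = m[, 3], y_um = m[, 4], z_um = m[, 5],
                   radius_um = m[, 6], parent = as.integer(m[, 7]))
  if (unit == "px") {
    if (is.null(voxel_size)) stop("unit = 'px' requires `voxel_size`")
    df$x_um <- df$x_um * voxel_size[1]
    df$y_um <- df$y_um * voxel_size[2]
    df$z_um <- df$z_um * voxel_size[3]
    df$radius_um <- df$radius_um * voxel_size[1]
  }
  df$parent[df$parent == -1L] <- NA_integer_
  if (anyDuplicated(df$id)) stop("duplicate SWC node ids")
  if (any(df$radius_um < 0)) stop("negative SWC radius")
  bad <- !is.na(df$parent) & !(df$parent %in% df$id)
  if (any(bad)) {
    stop(sprintf("SWC parent id %d refers to no node", df$parent[which(bad)[1]]))
  }
  class(df) <- c("swc_tracing", "data.frame")
  df
}

#' Read / write point annotations of spine centers
#'
#' Delimited table (CSV) with required columns `x_um`, `y_um`, `z_um`,
#' `rater`, `round`. Extra columns are ignored on read; the required fields
#' round-trip losslessly.
#'
#' @param path CSV path.
#' @return a `point_annotations` data.frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  point_annotations(df)
}

#' @rdname read_annotations
#' @param points a `point_annotations` object (or coercible data.frame).
#' @export
write_annotations <- function(points, path) {
  points <- point_annotations(points)
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Construct a point annotation set
#'
#' @param df data.frame with columns `x_um, y_um, z_um, rater, round`
#'   (`round` defaults to 1 if absent).
#' @return a validated `point_annotations` data.frame.
#' @export
point_annotations <- function(df) {
  if (!("round" %in% names(df))) df$round <- 1L
  need <- c("x_um", "y_um", "z_um", "rater", "round")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("annotation table lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  df <- df[need]
  if (nrow(df)) {
    if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um)) ||
        any(!is.finite(df$z_um))) {
      stop("annotation coordinates must be finite")
    }
    if (any(!nzchar(as.character(df$rater)))) stop("empty rater label")
  }
  df$rater <- as.character(df$rater)
  df$round <- as.integer(df$round)
  class(df) <- c("point_annotations", "data.frame")
  df
}

#' Rescale a stack to a target xy resolution
#'
#' Each z-plane is resampled by bilinear interpolation so that the pixel size
#' in x and y becomes `target_xy_um` (z is untouched). This mirrors the
#' common preprocessing step of bringing heterogeneous datasets to one
#' working resolution (e.g. 94 nm/px) before segmentation.
#'
#' @param stack an [image_stack] with equal x and y pixel size.
#' @param target_xy_um target pixel size in um (> 0).
#' @return an [image_stack] with updated geometry and voxel size.
#' @export
rescale_stack <- function(stack, target_xy_um) {
  stopifnot_stack(stack)
  if (!is.finite(target_xy_um) || target_xy_um <= 0) {
    stop("`target_xy_um` must be > 0")
  }
  vs <- stack$voxel_size
  factor_x <- vs[1] / target_xy_um
  factor_y <- vs[2] / target_xy_um
  d <- dim(stack$voxels)
  ny <- max(1L, as.integer(round(d[2] * factor_y)))
  nx <- max(1L, as.integer(round(d[3] * factor_x)))
  if (ny == d[2] && nx == d[3]) {
    out <- stack$voxels
  } else {
    out <- array(0, dim = c(d[1], ny, nx))
    for (z in seq_len(d[1])) {
      out[z, , ] <- EBImage::resize(stack$voxels[z, , , drop = TRUE],
                                    w = ny, h = nx, filter = "bilinear")
    }
  }
  image_stack(out, c(target_xy_um, target_xy_um, vs[3]))
}
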