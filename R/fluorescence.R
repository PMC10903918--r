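#' Extract mean-fluorescence traces per ROI from a movie
#'
#' @param movie list of [image_stack] frames (a time series), or a 4D array
#'   `[z, y, x, t]`.
#' @param rois a [roi_set] whose voxels lie within the frame geometry.
#' @return a `trace_matrix`: numeric matrix (n_rois x n_frames) with ROI ids
#'   as rownames; entry `(i, t)` is the mean intensity over ROI i's voxels
#'   at frame t.
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(inherits(rois, "roi_set"))
  if (is.array(movie) && length(dim(movie)) == 4) {
    movie <- lapply(seq_len(dim(movie)[4]), function(t) {
      image_stack(movie[, , , t, drop = TRUE], rois$voxel_size)
    })
  }
  nt <- length(movie)
  nr <- length(rois$rois)
  out <- matrix(NA_real_, nr, nt,
                dimnames = list(sprintf("roi%d", seq_len(nr)), NULL))
  for (i in seq_len(nr)) {
    vx <- rois$rois[[i]]$voxels
    if (nrow(vx) == 0) stop(sprintf("ROI %d is empty", i))
    for (t in seq_len(nt)) {
      fr <- if (is_image_stack(movie[[t]])) movie[[t]]$voxels else movie[[t]]
      out[i, t] <- mean(fr[vx])
    }
  }
  class(out) <- c("trace_matrix", class(out))
  out
}

#' Normalized fluorescence change (delta F over F0)
#'
#' `dF/F0(t) = (F(t) - F0) / F0` where `F0` is the mean raw fluorescence
#' over the user-supplied baseline frames (conventionally ~20 frames free of
#' spontaneous calcium events). Invariant under multiplicative gain.
#'
#' @param trace numeric vector (one ROI's raw trace).
#' @param baseline_frames integer indices of baseline frames.
#' @return numeric vector of the same length.
#' @export
delta_f_over_f <- function(trace, baseline_frames) {
  f0 <- mean(trace[baseline_frames])
  if (!is.finite(f0) || f0 <= 0) {
    stop("baseline mean F0 must be positive and finite")
  }
  (trace - f0) / f0
}

#' Ratiometric spine-to-dendrite ratio (RSDR)
#'
#' `RSDR = (Maturity_spine / Structure_spine) /
#' (Maturity_dendrite / Structure_dendrite)`, where the spine terms are mean
#' raw fluorescence over one spine ROI in the maturity (e.g. tagged PSD-95
#' nanobody) and structural channels, and the dendrite terms are means over
#' all dendrite-labeled voxels in the field of view. Values above 1 indicate
#' preferential localization of the maturity marker to the spine. The ratio
#' is invariant under global rescaling of either channel.
#'
#' @param maturity_spine,structure_spine,maturity_dendrite,structure_dendrite
#'   positive mean intensities.
#' @return scalar RSDR (> 0).
#' @export
rsdr <- function(maturity_spine, structure_spine,
                 maturity_dendrite, structure_dendrite) {
  vals <- c(maturity_spine, structure_spine, maturity_dendrite,
            structure_dendrite)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all four mean intensities must be positive for a defined RSDR")
  }
  (maturity_spine / structure_spine) /
    (maturity_dendrite / structure_dendrite)
}

#' Per-ROI RSDR from two registered channels
#'
#' @param maturity,structure [image_stack]s of the two channels (registered,
#'   same geometry).
#' @param rois spine [roi_set].
#' @param dendrite_mask binary [image_stack] defining the dendritic arbor
#'   reference.
#' @return data.frame with one RSDR per ROI.
#' @export
rsdr_per_roi <- function(maturity, structure, rois, dendrite_mask) {
  dm <- dendrite_mask$voxels != 0
  md <- mean(maturity$voxels[dm])
  sd_ <- mean(structure$voxels[dm])
  vals <- vapply(seq_along(rois$rois), function(i) {
    vx <- rois$rois[[i]]$voxels
    rsdr(mean(maturity$voxels[vx]), mean(structure$voxels[vx]), md, sd_)
  }, numeric(1))
  data.frame(id = seq_along(rois$rois), rsdr = vals)
}

#' Pearson correlation between two traces, optionally smoothed
#'
#' Applies an optional centered moving average (default width 9, with
#' shorter windows at the edges) to both traces before computing Pearson's
#' r — the standard comparison between automatically and manually generated
#' ROI calcium traces.
#'
#' @param a,b numeric traces of equal length (> 2).
#' @param smoothing `"none"` or `"moving_average"`.
#' @param width moving-average window (odd).
#' @return Pearson correlation coefficient.
#' @export
trace_correlation <- function(a, b, smoothing = c("none", "moving_average"),
                              width = 9) {
  smoothing <- match.arg(smoothing)
  if (length(a) != length(b) || length(a) <= 2) {
    stop("traces must have equal length > 2")
  }
  if (smoothing == "moving_average") {
    a <- moving_average(a, width)
    b <- moving_average(b, width)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance trace: correlation undefined")
  }
  stats::cor(a, b)
}

# centered moving average with edge truncation
moving_average <- function(x, width) {
  h <- (width - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}
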