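#' ROI build configuration
#'
#' Tunable acceptance rules for converting the spine probability map into
#' discrete ROIs. `seed_threshold`/`seed_relation`/`max_distance_to_seed_um`
#' drive the flood-fill builder; `area_threshold` drives the
#' connected-component builder; the size/plane/distance filters apply to
#' both.
#'
#' @param seed_threshold minimum probability for a flood-fill seed.
#' @param area_threshold binarization threshold for connected components.
#' @param seed_relation rho in (0, 1]: a voxel joins a region only if its
#'   probability is at least `rho * seed probability`.
#' @param max_distance_to_seed_um maximum physical distance to the seed.
#' @param min_roi_size_vox,max_roi_size_vox ROI volume bounds (voxels).
#' @param min_planes minimum distinct z-planes an ROI must span.
#' @param max_dist_to_dendrite_um explicit distance-to-dendrite bound in um,
#'   or `NULL` when proximity is already enforced implicitly via the dilation
#'   gate of [gate_spines_by_dendrite()].
#' @export
roi_config <- function(seed_threshold = 0.25, area_threshold = 0.25,
                       seed_relation = 0.5, max_distance_to_seed_um = 3,
                       min_roi_size_vox = 10, max_roi_size_vox = 10000,
                       min_planes = 2, max_dist_to_dendrite_um = NULL) {
  stopifnot(seed_threshold > 0, seed_threshold < 1,
            area_threshold > 0, area_threshold < 1,
            seed_relation > 0, seed_relation <= 1,
            min_roi_size_vox >= 1, min_roi_size_vox <= max_roi_size_vox)
  structure(list(seed_threshold = seed_threshold,
                 area_threshold = area_threshold,
                 seed_relation = seed_relation,
                 max_distance_to_seed_um = max_distance_to_seed_um,
                 min_roi_size_vox = min_roi_size_vox,
                 max_roi_size_vox = max_roi_size_vox,
                 min_planes = min_planes,
                 max_dist_to_dendrite_um = max_dist_to_dendrite_um),
            class = "roi_config")
}

#' Construct an ROI set
#'
#' @param rois list of ROIs, each `list(voxels, centroid_um, plane_span,
#'   mean_prob, max_prob)` with `voxels` an n x 3 matrix of 1-based
#'   `(z, y, x)` indices.
#' @param dim stack dimensions `c(z, y, x)`.
#' @param voxel_size `c(x, y, z)` um.
#' @export
roi_set <- function(rois, dim, voxel_size) {
  structure(list(rois = rois, dim = as.integer(dim),
                 voxel_size = as.numeric(voxel_size)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROI(s) in a %s stack\n", length(x$rois),
              paste(x$dim, collapse = " x ")))
  invisible(x)
}

#' @export
length.roi_set <- function(x) length(x$rois)

make_roi <- function(vox_idx, prob_map, voxel_size) {
  probs <- prob_map[vox_idx]
  ctr <- colMeans(voxel_centers_um(vox_idx, voxel_size))
  list(voxels = vox_idx, centroid_um = ctr,
       plane_span = length(unique(vox_idx[, 1])),
       mean_prob = mean(probs), max_prob = max(probs))
}

#' Build spine ROIs by seeded flood filling
#'
#' Seeds are taken in strictly decreasing probability order (ties broken by
#' array linear order, making results deterministic) among unvisited voxels
#' above `seed_threshold`. Each
#' region grows over 26-connected neighbors whose probability is at least
#' `seed_relation` times the seed probability and whose physical distance to
#' the seed does not exceed `max_distance_to_seed_um`. Visited voxels are
#' never reused, so ROIs are pairwise disjoint.
#'
#' @param spine_map spine probability [image_stack] (values in `[0, 1]`).
#' @param config a [roi_config].
#' @return a [roi_set].
#' @export
flood_fill_rois <- function(spine_map, config = roi_config()) {
  stopifnot_stack(spine_map)
  v <- spine_map$voxels
  vs <- spine_map$voxel_size
  d <- dim(v)
  offs <- neighbor_offsets(26)
  cand <- which(v >= config$seed_threshold)
  ord <- order(-v[cand], cand)   # decreasing prob, then (z,y,x) linear order
  cand <- cand[ord]
  visited <- array(FALSE, d)
  rois <- list()
  for (seed in cand) {
    if (visited[seed]) next
    seed_prob <- v[seed]
    floor_prob <- config$seed_relation * seed_prob
    seed_idx <- arrayInd(seed, d)
    seed_um <- voxel_centers_um(seed_idx, vs)
    region <- seed
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        zz <- co[, 1] + offs[o, 1]
        yy <- co[, 2] + offs[o, 2]
        xx <- co[, 3] + offs[o, 3]
        ok <- zz >= 1L & zz <= d[1] & yy >= 1L & yy <= d[2] &
          xx >= 1L & xx <= d[3]
        if (!any(ok)) next
        lin <- zz[ok] + (yy[ok] - 1L) * d[1] + (xx[ok] - 1L) * d[1] * d[2]
        lin <- unique(lin[!visited[lin]])
        if (!length(lin)) next
        keep <- v[lin] >= floor_prob
        if (any(keep)) {
          lin <- lin[keep]
          ci <- arrayInd(lin, d)
          cum <- voxel_centers_um(ci, vs)
          dist <- sqrt((cum[, 1] - seed_um[1])^2 + (cum[, 2] - seed_um[2])^2 +
                         (cum[, 3] - seed_um[3])^2)
          lin <- lin[dist <= config$max_distance_to_seed_um]
          if (length(lin)) {
            visited[lin] <- TRUE
            region <- c(region, lin)
            nxt <- c(nxt, lin)
          }
        }
      }
      frontier <- nxt
    }
    rois[[length(rois) + 1]] <- make_roi(arrayInd(region, d), v, vs)
  }
  roi_set(rois, d, vs)
}

#' Build spine ROIs by thresholded 3D connected components
#'
#' Binarizes the spine map at `area_threshold`; every 3D 26-connected
#' component becomes one ROI.
#'
#' @inheritParams flood_fill_rois
#' @export
connected_component_rois <- function(spine_map, config = roi_config()) {
  stopifnot_stack(spine_map)
  v <- spine_map$voxels
  vs <- spine_map$voxel_size
  lab <- label_components(v >= config$area_threshold, connectivity = 26)
  k <- max(lab)
  rois <- lapply(seq_len(k), function(i) {
    make_roi(which(lab == i, arr.ind = TRUE), v, vs)
  })
  roi_set(rois, dim(v), vs)
}

#' Apply ROI acceptance filters
#'
#' Keeps an ROI iff its voxel count lies in
#' `[min_roi_size_vox, max_roi_size_vox]`, it spans at least `min_planes`
#' distinct z-planes, and — when an explicit `max_dist_to_dendrite_um` is
#' configured — the minimum physical distance from its voxels to the nearest
#' dendrite voxel does not exceed that bound.
#'
#' @param rois a [roi_set].
#' @param config a [roi_config].
#' @param dendrite_mask binary [image_stack]; required in explicit distance
#'   mode.
#' @return a filtered [roi_set].
#' @export
filter_rois <- function(rois, config = roi_config(), dendrite_mask = NULL) {
  stopifnot(inherits(rois, "roi_set"))
  explicit <- !is.null(config$max_dist_to_dendrite_um)
  if (explicit && is.null(dendrite_mask)) {
    stop("explicit distance-to-dendrite filtering requires `dendrite_mask`")
  }
  keep <- vapply(rois$rois, function(roi) {
    n <- nrow(roi$voxels)
    if (n < config$min_roi_size_vox || n > config$max_roi_size_vox) return(FALSE)
    if (roi$plane_span < config$min_planes) return(FALSE)
    if (explicit) {
      dmin <- min(min_dist_to_mask_um(roi$voxels, dendrite_mask$voxels,
                                      rois$voxel_size))
      if (dmin > config$max_dist_to_dendrite_um) return(FALSE)
    }
    TRUE
  }, logical(1))
  roi_set(rois$rois[keep], rois$dim, rois$voxel_size)
}

#' Render an ROI set as an integer label volume
#'
#' Background is 0; ROI `i`'s voxels carry label `i`. Overlaps (possible
#' only for ROI sets not produced by the builders here) are resolved in ROI
#' order: the first ROI wins.
#'
#' @param rois a [roi_set].
#' @param geometry optional `c(z, y, x)` dims (defaults to `rois$dim`).
#' @return integer [image_stack] of labels.
#' @export
rois_to_label_volume <- function(rois, geometry = rois$dim) {
  lab <- array(0L, geometry)
  for (i in rev(seq_along(rois$rois))) {
    vx <- rois$rois[[i]]$voxels
    if (any(vx[, 1] > geometry[1] | vx[, 2] > geometry[2] |
            vx[, 3] > geometry[3] | vx < 1)) {
      stop(sprintf("ROI %d has out-of-bounds voxels", i))
    }
    lab[vx] <- i
  }
  image_stack(lab, rois$voxel_size)
}

#' Summarize an ROI set as a table
#'
#' @param rois a [roi_set].
#' @return data.frame with id, centroid (um), size, plane span and mean/max
#'   probability per ROI.
#' @export
roi_table <- function(rois) {
  if (!length(rois$rois)) {
    return(data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), size_vox = integer(),
                      plane_span = integer(), mean_prob = numeric(),
                      max_prob = numeric()))
  }
  do.call(rbind, lapply(seq_along(rois$rois), function(i) {
    r <- rois$rois[[i]]
    data.frame(id = i, x_um = r$centroid_um[1], y_um = r$centroid_um[2],
               z_um = r$centroid_um[3], size_vox = nrow(r$voxels),
               plane_span = r$plane_span, mean_prob = r$mean_prob,
               max_prob = r$max_prob)
  }))
}
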