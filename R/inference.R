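#' Predict dendrite/spine probability maps for a whole stack
#'
#' Each z-plane is processed independently: normalized to `[-1, 1]`,
#' reflect-padded to a multiple of `2^depth`, run through the network in
#' evaluation mode, and cropped back. Optionally the stack is first rescaled
#' to the model's working xy resolution and the maps are rescaled back to the
#' native geometry.
#'
#' @param model a `seg_model`.
#' @param stack an [image_stack].
#' @param target_xy_um optional working resolution; `NULL` keeps the native
#'   resolution.
#' @return list of two [image_stack]s `dendrite_map` and `spine_map` with
#'   the input geometry and values in `[0, 1]`.
#' @export
predict_stack <- function(model, stack, target_xy_um = NULL) {
  stopifnot_stack(stack)
  work <- stack
  if (!is.null(target_xy_um)) work <- rescale_stack(stack, target_xy_um)
  d <- dim(work$voxels)
  div <- 2^model$config$depth
  ny <- ceiling(d[2] / div) * div
  nx <- ceiling(d[3] / div) * div
  dmap <- array(0, d)
  smap <- array(0, d)
  for (z in seq_len(d[1])) {
    plane <- normalize_intensity(matrix(work$voxels[z, , , drop = TRUE], d[2]))
    padded <- reflect_pad(plane, ny, nx)
    out <- predict_tiles(model, padded)
    dmap[z, , ] <- out$dendrite[seq_len(d[2]), seq_len(d[3]), 1]
    smap[z, , ] <- out$spine[seq_len(d[2]), seq_len(d[3]), 1]
  }
  maps <- list(dendrite_map = image_stack(dmap, work$voxel_size),
               spine_map = image_stack(smap, work$voxel_size))
  if (!is.null(target_xy_um)) {
    maps$dendrite_map <- rescale_stack(maps$dendrite_map, stack$voxel_size[1])
    maps$spine_map <- rescale_stack(maps$spine_map, stack$voxel_size[1])
    # rounding in the two resamplings can leave a 1-px size mismatch; crop/pad
    maps$dendrite_map <- conform_geometry(maps$dendrite_map, dim(stack$voxels))
    maps$spine_map <- conform_geometry(maps$spine_map, dim(stack$voxels))
    maps$dendrite_map$voxel_size <- stack$voxel_size
    maps$spine_map$voxel_size <- stack$voxel_size
  }
  maps
}

conform_geometry <- function(stack, target_dim) {
  d <- dim(stack$voxels)
  if (identical(d, target_dim)) return(stack)
  out <- array(0, target_dim)
  z <- seq_len(min(d[1], target_dim[1]))
  y <- seq_len(min(d[2], target_dim[2]))
  x <- seq_len(min(d[3], target_dim[3]))
  out[z, y, x] <- stack$voxels[z, y, x]
  stack$voxels <- out
  stack
}

#' Remove small segments from the dendrite prediction map
#'
#' The dendrite map is binarized at `threshold`; per-plane (2D, 8-connected)
#' components smaller than `min_size_2d` pixels and volumetric (3D,
#' 26-connected) components smaller than `min_size_3d` voxels are removed,
#' and the corresponding probabilities zeroed. The spine map is untouched.
#'
#' @param maps list with `dendrite_map` and `spine_map` (from
#'   [predict_stack()]).
#' @param threshold binarization threshold in (0, 1).
#' @param min_size_2d minimum per-plane component area (px).
#' @param min_size_3d minimum 3D component volume (voxels).
#' @return maps with a cleaned `dendrite_map`.
#' @export
clean_dendrite_map <- function(maps, threshold = 0.5, min_size_2d = 10,
                               min_size_3d = 50) {
  stopifnot(threshold > 0, threshold < 1)
  v <- maps$dendrite_map$voxels
  mask <- v >= threshold
  d <- dim(mask)
  for (z in seq_len(d[1])) {
    lab <- label_components(matrix(mask[z, , ], d[2]), connectivity = 26)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0], nbins = max(lab))
      drop <- which(sizes < min_size_2d)
      if (length(drop)) {
        kill <- matrix(lab %in% drop, d[2])
        plane <- mask[z, , ]
        plane[kill] <- FALSE
        mask[z, , ] <- plane
      }
    }
  }
  lab3 <- label_components(mask, connectivity = 26)
  if (max(lab3) > 0) {
    sizes <- tabulate(lab3[lab3 > 0], nbins = max(lab3))
    drop <- which(sizes < min_size_3d)
    if (length(drop)) mask[array(lab3 %in% drop, d)] <- FALSE
  }
  v[!mask] <- 0
  maps$dendrite_map$voxels <- v
  maps
}

#' Gate spine predictions by proximity to the dendrite
#'
#' Dilates the (binarized) cleaned dendrite mask by a physical radius and
#' zeroes all spine probability outside it, implicitly enforcing a maximum
#' distance-to-dendrite for spine predictions. The dendrite map is unchanged.
#'
#' @param maps list with `dendrite_map` and `spine_map`.
#' @param dilation_um dilation radius in micrometers (>= 0).
#' @param threshold dendrite binarization threshold.
#' @return maps with a gated `spine_map`.
#' @export
gate_spines_by_dendrite <- function(maps, dilation_um = 1.0, threshold = 0.5) {
  stopifnot(dilation_um >= 0)
  vs <- maps$dendrite_map$voxel_size
  dend <- maps$dendrite_map$voxels >= threshold
  allowed <- dilate_um(dend, dilation_um, vs)
  s <- maps$spine_map$voxels
  s[!allowed] <- 0
  maps$spine_map$voxels <- s
  maps
}
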