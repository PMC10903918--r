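#' Label connected components in a 3D binary volume
#'
#' Breadth-first labeling with 26-connectivity (faces, edges, corners) by
#' default, or 6-connectivity (faces only). A 2D plane passed as a
#' single-plane volume is labeled with the corresponding 8- or
#' 4-neighborhood.
#'
#' @param mask logical/0-1 3D array indexed `[z, y, x]` (or a matrix,
#'   promoted to one plane).
#' @param connectivity 26 (default) or 6.
#' @return integer array of the same shape: 0 background, 1..k component ids.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (is.matrix(mask)) mask <- array(mask, c(1L, nrow(mask), ncol(mask)))
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  offs <- neighbor_offsets(connectivity)
  labels <- array(0L, d)
  mask <- mask != 0
  remaining <- which(mask)
  visited <- !mask  # treat background as visited
  k <- 0L
  for (seed in remaining) {
    if (visited[seed]) next
    k <- k + 1L
    frontier <- seed
    visited[seed] <- TRUE
    labels[seed] <- k
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nb <- integer(0)
      for (o in seq_len(nrow(offs))) {
        zz <- co[, 1] + offs[o, 1]
        yy <- co[, 2] + offs[o, 2]
        xx <- co[, 3] + offs[o, 3]
        ok <- zz >= 1L & zz <= d[1] & yy >= 1L & yy <= d[2] &
          xx >= 1L & xx <= d[3]
        if (!any(ok)) next
        lin <- zz[ok] + (yy[ok] - 1L) * d[1] + (xx[ok] - 1L) * d[1] * d[2]
        lin <- lin[!visited[lin]]
        if (length(lin)) {
          lin <- unique(lin)
          visited[lin] <- TRUE
          labels[lin] <- k
          nb <- c(nb, lin)
        }
      }
      frontier <- nb
    }
  }
  labels
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(g != 0) > 0, , drop = FALSE]
  if (connectivity == 6) {
    g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  } else if (connectivity != 26) {
    stop("connectivity must be 6 or 26")
  }
  g
}

#' Dilate a binary volume with a physical-unit ellipsoidal element
#'
#' The structuring element is the set of voxel offsets whose physical
#' displacement (scaled by the per-axis voxel size) has Euclidean norm at most
#' `radius_um`; dilation is the union of the mask shifted by each offset.
#' With anisotropic voxels this yields an ellipsoid in voxel units and a
#' sphere in physical units.
#'
#' @param mask 0/1 3D array `[z, y, x]`.
#' @param radius_um dilation radius in micrometers (0 returns mask unchanged).
#' @param voxel_size `c(x, y, z)` um.
#' @return logical array of the same shape.
#' @export
dilate_um <- function(mask, radius_um, voxel_size) {
  d <- dim(mask)
  mask <- mask != 0
  if (radius_um <= 0) return(mask)
  rz <- floor(radius_um / voxel_size[3])
  ry <- floor(radius_um / voxel_size[2])
  rx <- floor(radius_um / voxel_size[1])
  g <- as.matrix(expand.grid(dz = -rz:rz, dy = -ry:ry, dx = -rx:rx))
  keep <- (g[, "dx"] * voxel_size[1])^2 + (g[, "dy"] * voxel_size[2])^2 +
    (g[, "dz"] * voxel_size[3])^2 <= radius_um^2
  g <- g[keep, , drop = FALSE]
  out <- array(FALSE, d)
  for (o in seq_len(nrow(g))) {
    dz <- g[o, 1]; dy <- g[o, 2]; dx <- g[o, 3]
    if (max(1L, 1L - dz) > min(d[1], d[1] - dz) ||
        max(1L, 1L - dy) > min(d[2], d[2] - dy) ||
        max(1L, 1L - dx) > min(d[3], d[3] - dx)) next
    sz <- max(1L, 1L - dz):min(d[1], d[1] - dz)
    sy <- max(1L, 1L - dy):min(d[2], d[2] - dy)
    sx <- max(1L, 1L - dx):min(d[3], d[3] - dx)
    out[sz + dz, sy + dy, sx + dx] <-
      out[sz + dz, sy + dy, sx + dx, drop = FALSE] |
      mask[sz, sy, sx, drop = FALSE]
  }
  out
}

# minimum physical distance (um) from each query voxel to the nearest TRUE
# voxel of `mask`; queries is an n x 3 matrix of (z, y, x) indices
min_dist_to_mask_um <- function(queries, mask, voxel_size) {
  tgt <- which(mask != 0, arr.ind = TRUE)
  if (nrow(tgt) == 0) return(rep(Inf, nrow(queries)))
  tx <- (tgt[, 3] - 0.5) * voxel_size[1]
  ty <- (tgt[, 2] - 0.5) * voxel_size[2]
  tz <- (tgt[, 1] - 0.5) * voxel_size[3]
  qx <- (queries[, 3] - 0.5) * voxel_size[1]
  qy <- (queries[, 2] - 0.5) * voxel_size[2]
  qz <- (queries[, 1] - 0.5) * voxel_size[3]
  out <- numeric(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    out[i] <- sqrt(min((tx - qx[i])^2 + (ty - qy[i])^2 + (tz - qz[i])^2))
  }
  out
}
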