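#' Rasterize a neuron tracing into a binary volume
#'
#' Converts an SWC tracing into a binary mask on the geometry of a template
#' stack by drawing interpolated spheres along every parent-child segment:
#' sphere centers and radii are linearly interpolated between the two anchor
#' nodes with a spacing fine relative to the voxel size, and a voxel is set
#' iff its physical center lies inside at least one sphere. Distances are
#' measured in micrometers, so anisotropic voxel sizes are handled correctly.
#'
#' @param tracing a `swc_tracing` from [read_swc()].
#' @param template an [image_stack] providing shape and voxel size, or a list
#'   with fields `dim` (`c(z, y, x)`) and `voxel_size`.
#' @return a binary [image_stack] (0/1 values) on the template geometry.
#' @export
rasterize_tracing <- function(tracing, template) {
  geom <- template_geometry(template)
  if (any(geom$voxel_size <= 0)) stop("non-positive voxel size")
  vox <- array(0L, dim = geom$dim)
  if (nrow(tracing) == 0) return(image_stack(vox, geom$voxel_size))
  idx <- stats::setNames(seq_len(nrow(tracing)), tracing$id)
  # root nodes contribute their own sphere; segments contribute interpolated
  # sphere chains
  for (i in seq_len(nrow(tracing))) {
    p <- tracing$parent[i]
    a <- c(tracing$x_um[i], tracing$y_um[i], tracing$z_um[i])
    ra <- tracing$radius_um[i]
    if (is.na(p)) {
      vox <- stamp_spheres(vox, rbind(a), ra, geom$voxel_size)
    } else {
      j <- idx[[as.character(p)]]
      b <- c(tracing$x_um[j], tracing$y_um[j], tracing$z_um[j])
      rb <- tracing$radius_um[j]
      vox <- stamp_segment(vox, a, b, ra, rb, geom$voxel_size)
    }
  }
  image_stack(vox, geom$voxel_size)
}

template_geometry <- function(template) {
  if (is_image_stack(template)) {
    list(dim = dim(template$voxels), voxel_size = template$voxel_size)
  } else if (is.list(template) && !is.null(template$dim) &&
             !is.null(template$voxel_size)) {
    list(dim = as.integer(template$dim),
         voxel_size = as.numeric(template$voxel_size))
  } else {
    stop("`template` must be an image_stack or list(dim=, voxel_size=)")
  }
}

# stamp a chain of interpolated spheres along segment a-b (um coords)
stamp_segment <- function(vox, a, b, ra, rb, voxel_size, aniso = FALSE) {
  seg_len <- sqrt(sum((a - b)^2))
  step <- min(voxel_size) / 4
  n <- max(2L, ceiling(seg_len / max(step, 1e-9)) + 1L)
  t <- seq(0, 1, length.out = n)
  centers <- cbind(a[1] + t * (b[1] - a[1]),
                   a[2] + t * (b[2] - a[2]),
                   a[3] + t * (b[3] - a[3]))
  radii <- ra + t * (rb - ra)
  if (aniso) {
    stamp_spheres_aniso(vox, centers, radii, voxel_size)
  } else {
    stamp_spheres(vox, centers, radii, voxel_size)
  }
}

# voxel-capture-aware variant: per-axis radius is at least half the voxel
# edge, so a continuous curve always rasterizes into a connected voxel chain
# even when thinner than the (anisotropic) voxel grid. Used by the synthetic
# scene generator; exact Euclidean-ball rasterization stays in
# stamp_spheres().
stamp_spheres_aniso <- function(vox, centers, radii, voxel_size) {
  d <- dim(vox)
  radii <- rep_len(radii, nrow(centers))
  cx <- ((seq_len(d[3])) - 0.5) * voxel_size[1]
  cy <- ((seq_len(d[2])) - 0.5) * voxel_size[2]
  cz <- ((seq_len(d[1])) - 0.5) * voxel_size[3]
  for (k in seq_len(nrow(centers))) {
    ctr <- centers[k, ]
    # always stamp the containing voxel: a polyline sampled finer than the
    # voxel grid then rasterizes into a 26-connected voxel chain
    iz <- floor(ctr[3] / voxel_size[3]) + 1L
    iy <- floor(ctr[2] / voxel_size[2]) + 1L
    ix <- floor(ctr[1] / voxel_size[1]) + 1L
    if (iz >= 1 && iz <= d[1] && iy >= 1 && iy <= d[2] &&
        ix >= 1 && ix <= d[3]) {
      vox[iz, iy, ix] <- 1L
    }
    r <- pmax(radii[k], voxel_size / 2)  # (x, y, z) per-axis radii
    xi <- which(abs(cx - ctr[1]) <= r[1] + voxel_size[1])
    yi <- which(abs(cy - ctr[2]) <= r[2] + voxel_size[2])
    zi <- which(abs(cz - ctr[3]) <= r[3] + voxel_size[3])
    if (!length(xi) || !length(yi) || !length(zi)) next
    dx2 <- ((cx[xi] - ctr[1]) / r[1])^2
    dy2 <- ((cy[yi] - ctr[2]) / r[2])^2
    dz2 <- ((cz[zi] - ctr[3]) / r[3])^2
    inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
    if (any(inside)) {
      block <- vox[zi, yi, xi, drop = FALSE]
      block[inside] <- 1L
      vox[zi, yi, xi] <- block
    }
  }
  vox
}

# set voxels whose centers fall inside any of the given spheres
# centers: n x 3 matrix (x, y, z) um; radii: scalar or length n
stamp_spheres <- function(vox, centers, radii, voxel_size) {
  d <- dim(vox)
  radii <- rep_len(radii, nrow(centers))
  cx <- ((seq_len(d[3])) - 0.5) * voxel_size[1]
  cy <- ((seq_len(d[2])) - 0.5) * voxel_size[2]
  cz <- ((seq_len(d[1])) - 0.5) * voxel_size[3]
  for (k in seq_len(nrow(centers))) {
    ctr <- centers[k, ]
    r <- radii[k]
    xi <- which(abs(cx - ctr[1]) <= r + voxel_size[1])
    yi <- which(abs(cy - ctr[2]) <= r + voxel_size[2])
    zi <- which(abs(cz - ctr[3]) <= r + voxel_size[3])
    if (r == 0) {
      # degenerate sphere: exactly the voxel containing the center
      iz <- floor(ctr[3] / voxel_size[3]) + 1L
      iy <- floor(ctr[2] / voxel_size[2]) + 1L
      ix <- floor(ctr[1] / voxel_size[1]) + 1L
      if (iz >= 1 && iz <= d[1] && iy >= 1 && iy <= d[2] && ix >= 1 && ix <= d[3]) {
        vox[iz, iy, ix] <- 1L
      }
      next
    }
    if (!length(xi) || !length(yi) || !length(zi)) next
    dx2 <- (cx[xi] - ctr[1])^2
    dy2 <- (cy[yi] - ctr[2])^2
    dz2 <- (cz[zi] - ctr[3])^2
    # outer-sum over the bounding box only
    dist2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)  # [z, y, x] block
    inside <- dist2 <= r^2
    if (any(inside)) {
      block <- vox[zi, yi, xi, drop = FALSE]
      block[inside] <- 1L
      vox[zi, yi, xi] <- block
    }
  }
  vox
}
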