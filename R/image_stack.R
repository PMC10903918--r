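#' 3D image stack with physical voxel size
#'
#' The universal carrier for raw microscopy data, binary label volumes and
#' prediction probability maps. Voxels are stored in a 3D array indexed
#' `[z, y, x]` (1-based); the physical center of voxel `(z, y, x)` lies at
#' `((i - 1) + 0.5) * voxel_size` along each axis, in micrometers. A single
#' plane is a stack with z-extent 1.
#'
#' @param voxels numeric 3D array indexed `[z, y, x]`, or a 2D matrix `[y, x]`
#'   which is promoted to a single-plane stack.
#' @param voxel_size numeric length-3 vector `c(x, y, z)` of voxel edge
#'   lengths in micrometers; all components must be positive.
#' @return An object of class `image_stack` with fields `voxels` and
#'   `voxel_size`.
#' @examples
#' s <- image_stack(array(0, c(2, 8, 8)), voxel_size = c(0.094, 0.094, 0.5))
#' dim(s$voxels)
#' @export
image_stack <- function(voxels, voxel_size) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(1L, nrow(voxels), ncol(voxels)))
  }
  if (length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array indexed [z, y, x]")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be three positive reals c(x, y, z) in um")
  }
  structure(list(voxels = voxels, voxel_size = voxel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d plane(s) of %d x %d px, voxel %.4g x %.4g x %.4g um (x,y,z)\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

is_image_stack <- function(x) inherits(x, "image_stack")

stopifnot_stack <- function(x, arg = deparse(substitute(x))) {
  if (!is_image_stack(x)) stop(sprintf("`%s` must be an image_stack", arg))
  invisible(x)
}

#' Convert voxel indices to physical coordinates
#'
#' @param idx integer matrix with columns `(z, y, x)` of 1-based voxel indices.
#' @param voxel_size `c(x, y, z)` voxel size in um.
#' @return numeric matrix with columns `(x_um, y_um, z_um)` of voxel centers.
#' @keywords internal
voxel_centers_um <- function(idx, voxel_size) {
  idx <- rbind(idx)
  cbind(x_um = (idx[, 3] - 0.5) * voxel_size[1],
        y_um = (idx[, 2] - 0.5) * voxel_size[2],
        z_um = (idx[, 1] - 0.5) * voxel_size[3])
}

# physical um coordinate -> enclosing 1-based voxel index (z, y, x)
um_to_voxel <- function(xyz_um, voxel_size) {
  xyz_um <- rbind(xyz_um)
  cbind(z = floor(xyz_um[, 3] / voxel_size[3]) + 1L,
        y = floor(xyz_um[, 2] / voxel_size[2]) + 1L,
        x = floor(xyz_um[, 1] / voxel_size[1]) + 1L)
}
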