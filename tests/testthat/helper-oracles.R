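# Independent brute-force oracles used to cross-check the package's
# implementations on small inputs. Deliberately written with naive per-voxel
# loops and label propagation, sharing no code with the package internals.

# connected-component labeling by iterative minimum-label propagation
brute_label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  lab[mask != 0] <- seq_len(sum(mask != 0))
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[rowSums(offs != 0) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  repeat {
    changed <- FALSE
    for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      if (lab[z, y, x] == 0) next
      for (o in seq_len(nrow(offs))) {
        zz <- z + offs$dz[o]; yy <- y + offs$dy[o]; xx <- x + offs$dx[o]
        if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3]) next
        if (lab[zz, yy, xx] > 0 && lab[zz, yy, xx] < lab[z, y, x]) {
          lab[z, y, x] <- lab[zz, yy, xx]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # renumber to 1..k
  ids <- sort(unique(lab[lab > 0]))
  out <- array(0L, d)
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

# naive seeded region growing matching the flood-fill ROI contract
brute_flood_fill <- function(v, voxel_size, seed_threshold, rho, max_dist_um) {
  d <- dim(v)
  coords_um <- function(z, y, x) {
    c((x - 0.5) * voxel_size[1], (y - 0.5) * voxel_size[2],
      (z - 0.5) * voxel_size[3])
  }
  visited <- array(FALSE, d)
  regions <- list()
  repeat {
    best <- -Inf; seed <- NULL
    for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      if (!visited[z, y, x] && v[z, y, x] >= seed_threshold && v[z, y, x] > best) {
        best <- v[z, y, x]; seed <- c(z, y, x)
      }
    }
    if (is.null(seed)) break
    floor_prob <- rho * best
    su <- coords_um(seed[1], seed[2], seed[3])
    region <- matrix(seed, 1)
    visited[seed[1], seed[2], seed[3]] <- TRUE
    queue <- list(seed)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        q <- p + c(dz, dy, dx)
        if (any(q < 1) || q[1] > d[1] || q[2] > d[2] || q[3] > d[3]) next
        if (visited[q[1], q[2], q[3]]) next
        if (v[q[1], q[2], q[3]] < floor_prob) next
        if (sqrt(sum((coords_um(q[1], q[2], q[3]) - su)^2)) > max_dist_um) next
        visited[q[1], q[2], q[3]] <- TRUE
        region <- rbind(region, q)
        queue[[length(queue) + 1]] <- q
      }
    }
    regions[[length(regions) + 1]] <- region
  }
  regions
}

# sorted voxel-set signature for comparing ROI collections
voxel_signature <- function(vox) {
  paste(sort(paste(vox[, 1], vox[, 2], vox[, 3])), collapse = ";")
}

tiny_scene <- function(seed = 1, n_spines = 4) {
  scene_spec(n_spines = n_spines, stack_shape = c(6, 64, 64), seed = seed)
}
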