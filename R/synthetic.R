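#' Specify a synthetic dendrite/spine scene
#'
#' Defines the geometry, optics and noise of a simulated two-photon z-stack:
#' smooth tubular dendrites with spine heads attached via thin necks,
#' anisotropic Gaussian PSF blur, shot-like noise with intensity-proportional
#' variance plus Gaussian read noise. Defaults mirror typical ex vivo
#' two-photon acquisitions of CA1 pyramidal dendrites (94 x 94 x 500 nm
#' voxels, ~0.5 um dendrite radius, 0.25-0.4 um spine heads).
#'
#' @param n_dendrites number of dendrite tubes.
#' @param dendrite_radius_um tube radius (um).
#' @param n_spines number of spines (>= 0).
#' @param spine_head_radius_um length-2 range of head radii (um).
#' @param neck_length_um length-2 range of neck lengths (um).
#' @param neck_radius_um neck radius (um).
#' @param voxel_size `c(x, y, z)` um.
#' @param stack_shape `c(z, y, x)` voxel counts.
#' @param psf_sigma_um Gaussian PSF sigma per axis `c(x, y, z)` um.
#' @param noise_gaussian_sd read-noise standard deviation (intensity units).
#' @param photon_scale shot-noise scale: noise variance = intensity * scale.
#' @param baseline background intensity.
#' @param amplitude added intensity inside labeled structures.
#' @param seed RNG seed; a fixed seed makes the whole scene reproducible.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(n_dendrites = 1,
                       dendrite_radius_um = 0.5,
                       n_spines = 5,
                       spine_head_radius_um = c(0.25, 0.4),
                       neck_length_um = c(0.3, 0.8),
                       neck_radius_um = 0.12,
                       voxel_size = c(0.094, 0.094, 0.5),
                       stack_shape = c(10, 96, 96),
                       psf_sigma_um = c(0.1, 0.1, 0.35),
                       noise_gaussian_sd = 3,
                       photon_scale = 0.4,
                       baseline = 10,
                       amplitude = 100,
                       seed = 1L) {
  spec <- list(n_dendrites = n_dendrites, dendrite_radius_um = dendrite_radius_um,
               n_spines = n_spines, spine_head_radius_um = spine_head_radius_um,
               neck_length_um = neck_length_um, neck_radius_um = neck_radius_um,
               voxel_size = as.numeric(voxel_size),
               stack_shape = as.integer(stack_shape),
               psf_sigma_um = as.numeric(psf_sigma_um),
               noise_gaussian_sd = noise_gaussian_sd,
               photon_scale = photon_scale, baseline = baseline,
               amplitude = amplitude, seed = as.integer(seed))
  geo <- c(spec$dendrite_radius_um, spec$spine_head_radius_um,
           spec$neck_length_um, spec$neck_radius_um, spec$voxel_size)
  if (any(!is.finite(geo)) || any(geo <= 0)) {
    stop("all geometric scene parameters must be positive")
  }
  if (spec$n_spines < 0) stop("n_spines must be >= 0")
  class(spec) <- "scene_spec"
  spec
}

#' Generate a ground-truthed synthetic scene
#'
#' Dendrites are random low-order parametric (quadratic Bezier) tubes; each
#' spine is a head sphere connected to the tube by a thin neck. Returns exact
#' binary masks and head centers. Spine and dendrite labels are disjoint
#' (necks belong to the spine label), spine heads are pairwise separated by
#' more than twice the maximum head radius so the spine mask has exactly
#' `n_spines` connected components.
#'
#' @param spec a [scene_spec].
#' @return list with `spine_mask` and `dendrite_mask` ([image_stack]s),
#'   `spine_centers` (n x 3 matrix, um, columns x/y/z) and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  d <- spec$stack_shape
  vs <- spec$voxel_size
  ext <- c(d[3] * vs[1], d[2] * vs[2], d[1] * vs[3])  # (x, y, z) um
  geom <- list(dim = d, voxel_size = vs)

  curves <- lapply(seq_len(spec$n_dendrites), function(i) {
    frac <- (i - 0.5) / spec$n_dendrites
    y0 <- ext[2] * (frac + stats::runif(1, -0.1, 0.1))
    p0 <- c(0.03 * ext[1], y0, ext[3] * stats::runif(1, 0.4, 0.6))
    p2 <- c(0.97 * ext[1], y0 + stats::runif(1, -0.15, 0.15) * ext[2],
            ext[3] * stats::runif(1, 0.4, 0.6))
    p1 <- c(ext[1] / 2, y0 + stats::runif(1, -0.2, 0.2) * ext[2],
            ext[3] * stats::runif(1, 0.4, 0.6))
    t <- seq(0, 1, length.out = 60)
    b <- cbind((1 - t)^2 %o% p0[1] + 2 * t * (1 - t) %o% p1[1] + t^2 %o% p2[1],
               (1 - t)^2 %o% p0[2] + 2 * t * (1 - t) %o% p1[2] + t^2 %o% p2[2],
               (1 - t)^2 %o% p0[3] + 2 * t * (1 - t) %o% p1[3] + t^2 %o% p2[3])
    b
  })

  dend <- array(0L, d)
  for (b in curves) {
    for (k in seq_len(nrow(b) - 1)) {
      dend <- stamp_segment(dend, b[k, ], b[k + 1, ],
                            spec$dendrite_radius_um, spec$dendrite_radius_um, vs)
    }
  }

  max_hr <- max(spec$spine_head_radius_um)
  sep_min <- 2 * max_hr + 0.3
  placements <- place_spines(curves, spec, ext, sep_min)
  spine <- array(0L, d)
  centers <- matrix(numeric(0), 0, 3,
                    dimnames = list(NULL, c("x_um", "y_um", "z_um")))
  for (p in placements) {
    # capture-aware stamping keeps thin necks/heads connected across coarse
    # z planes (a 0.12 um neck is thinner than half a 0.5 um z step)
    spine <- stamp_segment(spine, p$neck_from, p$head_center,
                           spec$neck_radius_um, spec$neck_radius_um, vs,
                           aniso = TRUE)
    spine <- stamp_spheres_aniso(spine, rbind(p$head_center), p$head_radius, vs)
    centers <- rbind(centers, p$head_center)
  }
  spine[dend == 1L] <- 0L  # labels are disjoint; necks belong to the spine
  list(spine_mask = image_stack(spine, vs),
       dendrite_mask = image_stack(dend, vs),
       spine_centers = centers, spec = spec)
}

# choose attachment points along the dendrite curves with guaranteed
# head-to-head separation; errors with the feasible maximum when the stack
# cannot host the requested count
place_spines <- function(curves, spec, ext, sep_min) {
  if (spec$n_spines == 0) return(list())
  # per-axis margin, capped so thin stacks (few z planes) remain feasible
  margin <- pmin(max(spec$spine_head_radius_um) + 0.2, ext / 2 * 0.9)
  out <- vector("list", spec$n_spines)
  for (attempt in 1:40) {
    ok <- TRUE
    curve_of <- 1 + (seq_len(spec$n_spines) - 1) %% length(curves)
    # arc positions per curve, evenly spread with jitter
    for (i in seq_len(spec$n_spines)) {
      b <- curves[[curve_of[i]]]
      n_on_curve <- sum(curve_of == curve_of[i])
      rank_on_curve <- sum(curve_of[seq_len(i)] == curve_of[i])
      tpos <- (rank_on_curve - 0.5) / n_on_curve +
        stats::runif(1, -0.2, 0.2) / n_on_curve
      tpos <- min(max(tpos, 0.05), 0.95)
      k <- max(2, min(nrow(b) - 1, round(tpos * nrow(b))))
      attach <- b[k, ]
      tang <- b[k + 1, ] - b[k - 1, ]
      tang <- tang / sqrt(sum(tang^2))
      side <- if (i %% 2 == 0) 1 else -1
      # mostly in-plane perpendicular direction (z is coarse)
      perp <- c(-tang[2], tang[1], 0)
      if (sqrt(sum(perp^2)) < 1e-6) perp <- c(0, 1, 0)
      perp <- perp / sqrt(sum(perp^2))
      ang <- stats::runif(1, -0.4, 0.4)
      dir <- c(cos(ang) * perp[1] - sin(ang) * tang[1],
               cos(ang) * perp[2] - sin(ang) * tang[2],
               stats::runif(1, -0.1, 0.1))
      dir <- side * dir / sqrt(sum(dir^2))
      hr <- stats::runif(1, spec$spine_head_radius_um[1],
                         spec$spine_head_radius_um[2])
      nl <- stats::runif(1, spec$neck_length_um[1], spec$neck_length_um[2])
      head_center <- attach + dir * (spec$dendrite_radius_um + nl + hr)
      if (any(head_center < margin) || any(head_center > ext - margin)) {
        head_center <- attach - dir * (spec$dendrite_radius_um + nl + hr)
        if (any(head_center < margin) || any(head_center > ext - margin)) {
          ok <- FALSE
          break
        }
        dir <- -dir
      }
      out[[i]] <- list(neck_from = attach + dir * (0.7 * spec$dendrite_radius_um),
                       head_center = head_center, head_radius = hr)
    }
    if (ok && spec$n_spines > 1) {
      hc <- do.call(rbind, lapply(out, `[[`, "head_center"))
      dm <- as.matrix(stats::dist(hc))
      if (min(dm[upper.tri(dm)]) <= sep_min) ok <- FALSE
    }
    if (ok) return(out)
  }
  # rough feasible count: curve length divided by required separation
  feas <- max(0L, floor(0.9 * ext[1] * length(curves) / sep_min))
  stop(sprintf(
    "could not place %d spines with head separation > %.2f um; roughly %d are feasible in this stack",
    spec$n_spines, sep_min, feas))
}

#' Render a synthetic scene into a noisy intensity stack
#'
#' Intensity is `baseline + amplitude * (spine | dendrite)`, convolved with an
#' anisotropic Gaussian PSF (sigma per axis in um), then corrupted by
#' shot-like noise (Gaussian with variance proportional to intensity, scale
#' `photon_scale`) and Gaussian read noise. Deterministic given `spec$seed`.
#'
#' @param gt output of [generate_scene()].
#' @param spec the [scene_spec] (defaults to `gt$spec`).
#' @return an [image_stack] of float intensities.
#' @export
render_stack <- function(gt, spec = gt$spec) {
  img <- spec$baseline +
    spec$amplitude * pmax(gt$spine_mask$voxels, gt$dendrite_mask$voxels)
  # psf_sigma_um is (x, y, z); convert to voxel units per array axis (z, y, x)
  sig_vox <- c(spec$psf_sigma_um[3] / spec$voxel_size[3],
               spec$psf_sigma_um[2] / spec$voxel_size[2],
               spec$psf_sigma_um[1] / spec$voxel_size[1])
  img <- gaussian_blur3d(img, sig_vox)
  set.seed(spec$seed + 1000L)
  shot <- stats::rnorm(length(img), sd = sqrt(pmax(img, 0) * spec$photon_scale))
  read <- stats::rnorm(length(img), sd = spec$noise_gaussian_sd)
  out <- img + array(shot, dim(img)) + array(read, dim(img))
  image_stack(out, spec$voxel_size)
}

# separable Gaussian blur; sigma in voxel units per array axis (z, y, x)
gaussian_blur3d <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (!is.finite(s) || s < 1e-3) next
    n <- dim(arr)[axis]
    h <- ceiling(3 * s)
    k <- stats::dnorm(-h:h, sd = s)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - h):(i + h)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok]
      K[i, ] <- K[i, ] / sum(K[i, ])
    }
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    dd <- dim(a)
    a <- K %*% matrix(a, nrow = dd[1])
    dim(a) <- dd
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Model of imperfect human spine annotators
#'
#' @param n_raters number of raters.
#' @param detection_prob per-spine detection probability: a scalar in `[0,1]`
#'   or a function of the spine head radius returning one.
#' @param jitter_sd_um `c(xy, z)` Gaussian jitter of annotated centers (um).
#' @param false_positive_rate expected Poisson count of spurious annotations
#'   per rater per stack, placed at least 1 um away from any true structure.
#' @param seed RNG seed.
#' @export
rater_model <- function(n_raters = 7, detection_prob = 0.85,
                        jitter_sd_um = c(0.15, 0.5),
                        false_positive_rate = 1, seed = 1L) {
  if (is.numeric(detection_prob)) {
    p <- detection_prob
    if (p < 0 || p > 1) stop("detection_prob must be in [0,1]")
    detection_prob <- function(head_radius_um) p
  }
  if (any(jitter_sd_um < 0)) stop("jitter must be >= 0")
  structure(list(n_raters = n_raters, detection_prob = detection_prob,
                 jitter_sd_um = jitter_sd_um,
                 false_positive_rate = false_positive_rate,
                 seed = as.integer(seed)),
            class = "rater_model")
}

#' Simulate multi-rater point annotations of a scene
#'
#' Each rater independently detects each spine with the model's detection
#' probability, annotates its center with anisotropic Gaussian jitter, and
#' contributes Poisson-distributed false positives placed at least 1 um from
#' any true structure.
#'
#' @param gt output of [generate_scene()] (head radii are re-derived from
#'   `gt$spec` only through the centers; detection_prob receives the mean
#'   head radius when per-spine radii are not stored).
#' @param model a [rater_model].
#' @param round annotation round recorded for all generated points.
#' @return a `point_annotations` data.frame.
#' @export
simulate_raters <- function(gt, model, round = 1L) {
  stopifnot(inherits(model, "rater_model"))
  set.seed(model$seed + 17L * as.integer(round))
  centers <- gt$spine_centers
  vs <- gt$spec$voxel_size
  d <- gt$spec$stack_shape
  ext <- c(d[3] * vs[1], d[2] * vs[2], d[1] * vs[3])
  mean_hr <- mean(gt$spec$spine_head_radius_um)
  # candidate false-positive sites: voxels > 1 um from any labeled structure
  fp_pool <- NULL
  if (model$false_positive_rate > 0) {
    occ <- dilate_um(pmax(gt$spine_mask$voxels, gt$dendrite_mask$voxels) > 0,
                     1.0, vs)
    fp_pool <- which(!occ, arr.ind = TRUE)
  }
  rows <- list()
  for (r in seq_len(model$n_raters)) {
    label <- sprintf("rater%02d", r)
    if (nrow(centers)) {
      for (i in seq_len(nrow(centers))) {
        if (stats::runif(1) <= model$detection_prob(mean_hr)) {
          jit <- c(stats::rnorm(2, sd = model$jitter_sd_um[1]),
                   stats::rnorm(1, sd = model$jitter_sd_um[2]))
          rows[[length(rows) + 1]] <- data.frame(
            x_um = centers[i, 1] + jit[1], y_um = centers[i, 2] + jit[2],
            z_um = centers[i, 3] + jit[3], rater = label,
            round = as.integer(round))
        }
      }
    }
    n_fp <- stats::rpois(1, model$false_positive_rate)
    if (n_fp > 0 && !is.null(fp_pool) && nrow(fp_pool)) {
      pick <- fp_pool[sample.int(nrow(fp_pool), n_fp, replace = TRUE), ,
                      drop = FALSE]
      ctr <- voxel_centers_um(pick, vs)
      for (j in seq_len(n_fp)) {
        rows[[length(rows) + 1]] <- data.frame(
          x_um = ctr[j, 1], y_um = ctr[j, 2], z_um = ctr[j, 3],
          rater = label, round = as.integer(round))
      }
    }
  }
  if (!length(rows)) {
    return(point_annotations(data.frame(x_um = numeric(), y_um = numeric(),
                                        z_um = numeric(), rater = character(),
                                        round = integer())))
  }
  point_annotations(do.call(rbind, rows))
}

#' Write a synthetic training dataset to disk
#'
#' Renders each scene, writes the raw stack plus the paired binary spine and
#' dendrite masks as multi-page TIFFs, and returns (and writes) a manifest
#' recording paths and per-entry voxel sizes.
#'
#' @param scenes list of [scene_spec]s.
#' @param out_dir output directory (created if needed).
#' @return manifest data.frame with columns `id, image, spines, dendrites,
#'   vox_x_um, vox_y_um, vox_z_um`, also written to `manifest.csv`.
#' @export
make_training_set <- function(scenes, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(scenes), function(i) {
    spec <- scenes[[i]]
    gt <- generate_scene(spec)
    raw <- render_stack(gt, spec)
    paths <- file.path(out_dir, sprintf(
      c("scene%03d_raw.tif", "scene%03d_spines.tif", "scene%03d_dendrites.tif"), i))
    write_stack(raw, paths[1])
    write_stack(gt$spine_mask, paths[2])
    write_stack(gt$dendrite_mask, paths[3])
    data.frame(id = i, image = paths[1], spines = paths[2],
               dendrites = paths[3], vox_x_um = spec$voxel_size[1],
               vox_y_um = spec$voxel_size[2], vox_z_um = spec$voxel_size[3])
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
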