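test_that("generated scenes honor component count, disjointness and determinism", {
  spec <- tiny_scene(seed = 7, n_spines = 5)
  gt <- generate_scene(spec)
  expect_equal(nrow(gt$spine_centers), 5L)
  expect_equal(max(label_components(gt$spine_mask$voxels)), 5L)
  expect_equal(sum(gt$spine_mask$voxels * gt$dendrite_mask$voxels), 0)
  expect_gt(sum(gt$dendrite_mask$voxels), 0)
  # bitwise-identical reproduction from the same seed
  gt2 <- generate_scene(spec)
  expect_identical(gt$spine_mask$voxels, gt2$spine_mask$voxels)
  expect_identical(gt$spine_centers, gt2$spine_centers)
  # no spines: empty spine mask, non-empty dendrite mask
  gt0 <- generate_scene(tiny_scene(seed = 3, n_spines = 0))
  expect_equal(sum(gt0$spine_mask$voxels), 0)
  expect_gt(sum(gt0$dendrite_mask$voxels), 0)
})

test_that("infeasible spine counts error with a feasible maximum", {
  spec <- scene_spec(n_spines = 50, stack_shape = c(4, 32, 32), seed = 1)
  expect_error(generate_scene(spec), "feasible")
})

test_that("scene component counts hold across seeds (fuzz)", {
  for (seed in 1:6) {
    gt <- generate_scene(tiny_scene(seed = seed, n_spines = 4))
    expect_equal(max(label_components(gt$spine_mask$voxels)), 4L)
    expect_equal(sum(gt$spine_mask$voxels * gt$dendrite_mask$voxels), 0)
  }
})

test_that("rendering reduces to the scaled masks in the noise-free limit", {
  spec <- scene_spec(n_spines = 3, stack_shape = c(4, 48, 48),
                     psf_sigma_um = c(1e-9, 1e-9, 1e-9),
                     noise_gaussian_sd = 0, photon_scale = 0, seed = 5)
  gt <- generate_scene(spec)
  raw <- render_stack(gt, spec)
  comb <- pmax(gt$spine_mask$voxels, gt$dendrite_mask$voxels)
  expect_equal(raw$voxels, spec$baseline + spec$amplitude * comb,
               tolerance = 1e-12)
})

test_that("doubling the amplitude doubles foreground-background contrast", {
  base <- scene_spec(n_spines = 3, stack_shape = c(4, 48, 48),
                     noise_gaussian_sd = 1, seed = 9)
  gt <- generate_scene(base)
  spec2 <- base
  spec2$amplitude <- base$amplitude * 2
  r1 <- render_stack(gt, base)
  r2 <- render_stack(gt, spec2)
  fg <- pmax(gt$spine_mask$voxels, gt$dendrite_mask$voxels) == 1
  c1 <- mean(r1$voxels[fg]) - mean(r1$voxels[!fg])
  c2 <- mean(r2$voxels[fg]) - mean(r2$voxels[!fg])
  expect_equal(c2 / c1, 2, tolerance = 0.05)
})

test_that("empirical SNR decreases monotonically with read-noise level", {
  sds <- c(1, 4, 16)
  snr <- vapply(sds, function(s) {
    vals <- vapply(1:10, function(seed) {
      spec <- scene_spec(n_spines = 3, stack_shape = c(4, 48, 48),
                         noise_gaussian_sd = s, seed = seed)
      gt <- generate_scene(spec)
      r <- render_stack(gt, spec)
      fg <- pmax(gt$spine_mask$voxels, gt$dendrite_mask$voxels) == 1
      (mean(r$voxels[fg]) - mean(r$voxels[!fg])) / stats::sd(r$voxels[!fg])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(snr) < 0))
})

test_that("simulated raters honor the degenerate detection contracts", {
  gt <- generate_scene(tiny_scene(seed = 7, n_spines = 5))
  # perfect raters annotate exactly the true centers
  ann <- simulate_raters(gt, rater_model(detection_prob = 1,
                                         jitter_sd_um = c(0, 0),
                                         false_positive_rate = 0, seed = 1))
  expect_equal(nrow(ann), 7 * 5)
  for (r in unique(ann$rater)) {
    pts <- ann[ann$rater == r, c("x_um", "y_um", "z_um")]
    expect_equal(unname(as.matrix(pts[order(pts$x_um), ])),
                 unname(gt$spine_centers[order(gt$spine_centers[, 1]), ]))
  }
  # blind raters annotate nothing
  ann0 <- simulate_raters(gt, rater_model(detection_prob = 0,
                                          false_positive_rate = 0, seed = 1))
  expect_equal(nrow(ann0), 0L)
  # determinism
  m <- rater_model(seed = 4)
  expect_identical(simulate_raters(gt, m), simulate_raters(gt, m))
})

test_that("per-rater detection frequency matches the model probability", {
  p <- 0.8
  fracs <- unlist(lapply(1:12, function(seed) {
    gt <- generate_scene(tiny_scene(seed = seed, n_spines = 5))
    ann <- simulate_raters(gt, rater_model(n_raters = 7, detection_prob = p,
                                           jitter_sd_um = c(0, 0),
                                           false_positive_rate = 0,
                                           seed = seed))
    table(factor(ann$rater, levels = sprintf("rater%02d", 1:7))) / 5
  }))
  n <- length(fracs) * 5
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(fracs) - p), 4 * se)
})

test_that("false positives land far from true structures", {
  gt <- generate_scene(tiny_scene(seed = 2, n_spines = 3))
  ann <- simulate_raters(gt, rater_model(detection_prob = 0,
                                         false_positive_rate = 5, seed = 8))
  expect_gt(nrow(ann), 0)
  occ <- pmax(gt$spine_mask$voxels, gt$dendrite_mask$voxels)
  vs <- gt$spec$voxel_size
  for (i in seq_len(nrow(ann))) {
    q <- cbind(z = floor(ann$z_um[i] / vs[3]) + 1,
               y = floor(ann$y_um[i] / vs[2]) + 1,
               x = floor(ann$x_um[i] / vs[1]) + 1)
    d <- spinequant:::min_dist_to_mask_um(q, occ, vs)
    expect_gte(d, 1.0 - max(vs))  # voxel-center discretization slack
  }
})

test_that("make_training_set writes a loadable, complete manifest", {
  td <- withr::local_tempdir()
  scenes <- list(tiny_scene(seed = 1, n_spines = 3),
                 scene_spec(n_spines = 3, stack_shape = c(6, 64, 64),
                            voxel_size = c(0.1245, 0.1245, 0.5), seed = 2))
  manifest <- make_training_set(scenes, td)
  expect_equal(nrow(manifest), 2L)
  expect_equal(sum(grepl("\\.tif$", list.files(td))), 6L)
  expect_true(all(file.exists(c(manifest$image, manifest$spines,
                                manifest$dendrites))))
  # per-entry voxel sizes are recorded (mixed-resolution datasets)
  expect_equal(manifest$vox_x_um, c(0.094, 0.1245))
  s <- read_stack(manifest$image[2], c(0.1245, 0.1245, 0.5))
  expect_equal(dim(s$voxels), c(6L, 64L, 64L))
})
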