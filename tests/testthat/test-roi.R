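vs <- c(0.1, 0.1, 0.5)

gaussian_blob_map <- function(d, centers_px, peak = 0.9, sigma_px = 2) {
  v <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    for (k in seq_len(nrow(centers_px))) {
      c0 <- centers_px[k, ]
      v[z, y, x] <- max(v[z, y, x], peak * exp(
        -((z - c0[1])^2 / 2 + (y - c0[2])^2 / (2 * sigma_px^2) +
            (x - c0[3])^2 / (2 * sigma_px^2))))
    }
  }
  v
}

test_that("flood fill finds single and well-separated double blobs", {
  d <- c(3, 24, 24)
  # with the relative floor rho*peak at or below the seed threshold, a
  # single blob is absorbed into exactly one ROI
  cfg <- roi_config(seed_threshold = 0.25, seed_relation = 0.27,
                    max_distance_to_seed_um = 0.7)
  v1 <- gaussian_blob_map(d, rbind(c(2, 12, 12)))
  r1 <- flood_fill_rois(image_stack(v1, vs), cfg)
  expect_equal(length(r1), 1L)
  peak_idx <- which(v1 == max(v1), arr.ind = TRUE)
  expect_true(any(apply(r1$rois[[1]]$voxels, 1, function(q) {
    all(q == peak_idx[1, ])
  })))
  # all probabilities below the seed threshold: no ROIs
  r0 <- flood_fill_rois(image_stack(v1 * 0.1, vs), cfg)
  expect_equal(length(r0), 0L)
  # two blobs farther apart than the distance cap, with the valley below
  # the relative floor: two ROIs
  v2 <- gaussian_blob_map(d, rbind(c(2, 12, 5), c(2, 12, 19)))
  r2 <- flood_fill_rois(image_stack(v2, vs), cfg)
  expect_equal(length(r2), 2L)
})

test_that("flood fill matches the brute-force region-growing oracle", {
  set.seed(5)
  for (i in 1:3) {
    d <- c(4, 12, 12)
    v <- array(runif(prod(d)), d)
    v[v < 0.3] <- 0
    cfg <- roi_config(seed_threshold = 0.4, seed_relation = 0.5,
                      max_distance_to_seed_um = 0.5)
    fast <- flood_fill_rois(image_stack(v, vs), cfg)
    slow <- brute_flood_fill(v, vs, 0.4, 0.5, 0.5)
    expect_equal(length(fast), length(slow))
    sig_fast <- sort(vapply(fast$rois,
                            function(r) voxel_signature(r$voxels), ""))
    sig_slow <- sort(vapply(slow, voxel_signature, ""))
    expect_equal(sig_fast, sig_slow)
  }
})

test_that("connected-component ROIs match exhaustive labeling", {
  set.seed(9)
  d <- c(4, 14, 14)
  v <- array(runif(prod(d)), d)
  cfg <- roi_config(area_threshold = 0.7)
  rois <- connected_component_rois(image_stack(v, vs), cfg)
  oracle <- brute_label_components(v >= 0.7, 26)
  expect_equal(length(rois), max(oracle))
  sig_fast <- sort(vapply(rois$rois, function(r) voxel_signature(r$voxels), ""))
  sig_slow <- sort(vapply(seq_len(max(oracle)), function(k) {
    voxel_signature(which(oracle == k, arr.ind = TRUE))
  }, ""))
  expect_equal(sig_fast, sig_slow)
  # threshold above the max: no ROIs
  expect_equal(length(connected_component_rois(
    image_stack(v * 0.2, vs), cfg)), 0L)
})

test_that("threshold superlevel sets nest as the threshold drops", {
  set.seed(3)
  d <- c(3, 16, 16)
  v <- gaussian_blob_map(d, rbind(c(2, 5, 5), c(2, 11, 11)), sigma_px = 3)
  hi <- connected_component_rois(image_stack(v, vs),
                                 roi_config(area_threshold = 0.6))
  lo <- connected_component_rois(image_stack(v, vs),
                                 roi_config(area_threshold = 0.2))
  expect_lte(length(lo), length(hi) + 1)
  # each high-threshold ROI is contained in exactly one low-threshold ROI
  lo_lab <- spinequant:::rois_to_label_volume(lo)$voxels
  for (r in hi$rois) {
    owners <- unique(lo_lab[r$voxels])
    expect_equal(length(owners), 1L)
    expect_gt(owners, 0)
  }
})

test_that("flood-fill ROIs are pairwise disjoint", {
  set.seed(12)
  v <- array(runif(5 * 16 * 16), c(5, 16, 16))
  rois <- flood_fill_rois(image_stack(v, vs),
                          roi_config(seed_threshold = 0.3))
  seen <- character(0)
  for (r in rois$rois) {
    keys <- paste(r$voxels[, 1], r$voxels[, 2], r$voxels[, 3])
    expect_false(any(keys %in% seen))
    seen <- c(seen, keys)
  }
})

test_that("ROI filters enforce size, plane span and dendrite distance", {
  d <- c(5, 20, 20)
  v <- array(0, d)
  v[2, 5:8, 5:8] <- 0.9       # 16 voxels, single plane
  v[4:5, 14:16, 14:16] <- 0.9 # 18 voxels, two planes
  rois <- connected_component_rois(image_stack(v, vs),
                                   roi_config(area_threshold = 0.5))
  expect_equal(length(rois), 2L)
  # min_planes = 2 removes the single-plane ROI
  f1 <- filter_rois(rois, roi_config(min_roi_size_vox = 1, min_planes = 2))
  expect_equal(length(f1), 1L)
  # size window
  f2 <- filter_rois(rois, roi_config(min_roi_size_vox = 17, min_planes = 1))
  expect_equal(length(f2), 1L)
  f3 <- filter_rois(rois, roi_config(min_roi_size_vox = 1, min_planes = 1))
  expect_equal(length(f3), 2L)
  # raising thresholds never increases the surviving count (monotonicity)
  for (ms in c(1, 5, 17, 30)) {
    n_lo <- length(filter_rois(rois, roi_config(min_roi_size_vox = ms,
                                                min_planes = 1)))
    n_hi <- length(filter_rois(rois, roi_config(min_roi_size_vox = ms + 5,
                                                min_planes = 1)))
    expect_lte(n_hi, n_lo)
  }
  # explicit distance mode: an ROI touching the dendrite is always kept
  dend <- array(0, d); dend[2, 5:8, 5:8] <- 1
  dmask <- image_stack(dend, vs)
  f4 <- filter_rois(rois, roi_config(min_roi_size_vox = 1, min_planes = 1,
                                     max_dist_to_dendrite_um = 0.01), dmask)
  expect_equal(length(f4), 1L)
  expect_error(filter_rois(rois, roi_config(max_dist_to_dendrite_um = 1)),
               "dendrite_mask")
})

test_that("label volumes conserve ROI voxels and handle empties", {
  d <- c(4, 12, 12)
  v <- array(0, d)
  v[1:2, 2:4, 2:4] <- 0.9
  v[3:4, 8:10, 8:10] <- 0.9
  rois <- connected_component_rois(image_stack(v, vs),
                                   roi_config(area_threshold = 0.5))
  lab <- rois_to_label_volume(rois)
  expect_setequal(unique(as.vector(lab$voxels)), c(0L, 1L, 2L))
  for (i in seq_along(rois$rois)) {
    expect_equal(sum(lab$voxels == i), nrow(rois$rois[[i]]$voxels))
  }
  empty <- roi_set(list(), d, vs)
  expect_true(all(rois_to_label_volume(empty)$voxels == 0))
})

test_that("ImageJ export writes one parseable record per ROI per plane", {
  r1 <- list(voxels = cbind(z = rep(2L, 4), y = c(3L, 3L, 4L, 4L),
                            x = c(5L, 6L, 5L, 6L)),
             centroid_um = c(0.55, 0.35, 0.75), plane_span = 1L,
             mean_prob = 0.9, max_prob = 0.9)
  r2 <- list(voxels = cbind(z = 1:3, y = rep(8L, 3), x = rep(8L, 3)),
             centroid_um = c(0.75, 0.75, 0.75), plane_span = 3L,
             mean_prob = 0.5, max_prob = 0.6)
  rs <- roi_set(list(r1, r2), dim = c(4, 10, 10), voxel_size = vs)
  f <- tempfile(fileext = ".zip")
  export_imagej_rois(rs, f)
  listing <- utils::unzip(f, list = TRUE)
  expect_equal(nrow(listing), 4L)  # 1 plane + 3 planes
  expect_equal(sum(startsWith(listing$Name, "roi0002")), 3L)
  rec <- read_imagej_rois(f)
  first <- rec[[which(vapply(rec, `[[`, "", "name") == "roi0001-z0002.roi")]]
  expect_equal(first$slice, 2L)
  # polygon encloses the 2x2 pixel block (0-based corners 4..6 x 2..4)
  expect_equal(range(first$x), c(4, 6))
  expect_equal(range(first$y), c(2, 4))
  expect_equal(first$type, 0L)
  # empty set: a bare (valid) empty archive
  f2 <- tempfile(fileext = ".zip")
  export_imagej_rois(roi_set(list(), c(4, 10, 10), vs), f2)
  bytes <- readBin(f2, "raw", file.size(f2))
  expect_equal(length(bytes), 22L)
  expect_equal(as.integer(bytes[1:4]), c(0x50, 0x4b, 0x05, 0x06))
  # an ROI with no voxels is a contract violation
  bad <- roi_set(list(list(voxels = matrix(integer(0), 0, 3))), c(4, 10, 10), vs)
  expect_error(export_imagej_rois(bad, tempfile(fileext = ".zip")), "no voxels")
})
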