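vs <- c(0.094, 0.094, 0.5)

test_that("TIFF roundtrips preserve voxel values for every dtype path", {
  f <- tempfile(fileext = ".tif")
  # 16-bit integer stack: exact
  s <- image_stack(array(sample(0:65535, 3 * 6 * 5, TRUE), c(3, 6, 5)), vs)
  write_stack(s, f)
  expect_equal(read_stack(f, vs)$voxels, s$voxels)
  # single-page file: degenerate stack with z-extent 1
  s1 <- image_stack(matrix(sample(0:255, 20), 4), vs)
  write_stack(s1, f)
  r1 <- read_stack(f, vs)
  expect_equal(dim(r1$voxels)[1], 1L)
  expect_equal(r1$voxels, s1$voxels)
  # probability map: within 32-bit quantization
  s2 <- image_stack(array(runif(3 * 4 * 4), c(3, 4, 4)), vs)
  write_stack(s2, f)
  expect_lt(max(abs(read_stack(f, vs)$voxels - s2$voxels)), 1e-6)
  # general float data via the range sidecar
  s3 <- image_stack(array(rnorm(3 * 4 * 4, 100, 40), c(3, 4, 4)), vs)
  write_stack(s3, f)
  expect_lt(max(abs(read_stack(f, vs)$voxels - s3$voxels)), 1e-4)
  # all-zero mask
  s4 <- image_stack(array(0, c(2, 4, 4)), vs)
  write_stack(s4, f)
  expect_true(all(read_stack(f, vs)$voxels == 0))
})

test_that("read_stack rejects missing files and RGB pages", {
  expect_error(read_stack(tempfile(), vs), "not found")
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(48), c(4, 4, 3)), f)  # RGB page
  expect_error(read_stack(f, vs), "grayscale")
})

test_that("image_stack validates geometry and voxel size", {
  expect_error(image_stack(array(0, c(2, 2, 2, 2)), vs), "3D")
  expect_error(image_stack(array(0, c(2, 2, 2)), c(0.1, -1, 0.5)), "positive")
  expect_error(image_stack(array(0, c(2, 2, 2)), c(0.1, 0.1)), "positive|three")
  # a bare matrix is promoted to a single-plane stack
  expect_equal(dim(image_stack(matrix(0, 3, 4), vs)$voxels), c(1L, 3L, 4L))
})

test_that("SWC parsing handles roots, comments and malformed input", {
  f <- tempfile(fileext = ".swc")
  writeLines(c("# neuron", "1 3 2.0 2.0 1.0 0.5 -1", "2 3 4.0 2.0 1.0 0.3 1"), f)
  tr <- read_swc(f)
  expect_equal(nrow(tr), 2L)
  expect_true(is.na(tr$parent[1]))
  expect_equal(tr$parent[2], 1L)

  writeLines("# only comments", f)
  expect_equal(nrow(read_swc(f)), 0L)

  writeLines(c("1 3 0 0 0 1 -1", "2 3 1 0 0 1 99"), f)
  expect_error(read_swc(f), "refers to no node")

  writeLines("1 3 0 0 0 1", f)
  expect_error(read_swc(f), "malformed")

  # pixel-unit coordinates are converted with the voxel size
  writeLines("1 3 10 20 2 5 -1", f)
  tr_px <- read_swc(f, unit = "px", voxel_size = vs)
  expect_equal(tr_px$x_um, 10 * vs[1])
  expect_equal(tr_px$z_um, 2 * vs[3])
})

test_that("rasterized sphere matches the exhaustive distance oracle", {
  vsi <- c(0.1, 0.1, 0.1)  # isotropic
  f <- tempfile(fileext = ".swc")
  writeLines("1 3 2.0 2.0 2.0 1.0 -1", f)
  tr <- read_swc(f)
  tmpl <- list(dim = c(40L, 40L, 40L), voxel_size = vsi)
  m <- rasterize_tracing(tr, tmpl)
  cnt <- 0
  for (z in 1:40) for (y in 1:40) for (x in 1:40) {
    p <- c((x - 0.5) * 0.1, (y - 0.5) * 0.1, (z - 0.5) * 0.1)
    if (sum((p - c(2, 2, 2))^2) <= 1) cnt <- cnt + 1
  }
  expect_equal(sum(m$voxels), cnt)
})

test_that("degenerate and composite rasterization contracts hold", {
  vsi <- c(0.1, 0.1, 0.5)
  tmpl <- list(dim = c(5L, 30L, 30L), voxel_size = vsi)
  f <- tempfile(fileext = ".swc")
  # radius-0 node occupies exactly the voxel containing its center
  writeLines("1 3 1.23 1.57 1.1 0.0 -1", f)
  m0 <- rasterize_tracing(read_swc(f), tmpl)
  expect_equal(sum(m0$voxels), 1)
  expect_equal(m0$voxels[3, 16, 13], 1L)  # floor(um / voxel) + 1
  # a segment mask contains both endpoint spheres
  writeLines(c("1 3 1.0 1.0 1.0 0.3 -1", "2 3 2.0 1.5 1.0 0.2 1"), f)
  seg <- rasterize_tracing(read_swc(f), tmpl)
  for (line in c("1 3 1.0 1.0 1.0 0.3 -1", "2 3 2.0 1.5 1.0 0.2 -1")) {
    writeLines(line, f)
    sph <- rasterize_tracing(read_swc(f), tmpl)
    expect_true(all(seg$voxels >= sph$voxels))
  }
})

test_that("annotation tables roundtrip and validate columns", {
  ann <- point_annotations(data.frame(
    x_um = c(1, 2, 3), y_um = c(4, 5, 6), z_um = c(0.5, 1, 1.5),
    rater = c("a", "a", "b"), round = c(1L, 1L, 2L)))
  f <- tempfile(fileext = ".csv")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(as.data.frame(back), as.data.frame(ann))
  # missing rater column errors; extra columns are ignored
  utils::write.csv(data.frame(x_um = 1, y_um = 2, z_um = 3), f, row.names = FALSE)
  expect_error(read_annotations(f), "rater")
  utils::write.csv(cbind(as.data.frame(ann), extra = 9), f, row.names = FALSE)
  expect_equal(as.data.frame(read_annotations(f)), as.data.frame(ann))
})

test_that("rescale_stack geometry, identity and interpolation accuracy", {
  s <- image_stack(array(runif(2 * 100 * 100), c(2, 100, 100)),
                   c(0.094, 0.094, 0.5))
  expect_identical(rescale_stack(s, 0.094)$voxels, s$voxels)
  r <- rescale_stack(s, 0.047)
  expect_equal(dim(r$voxels), c(2L, 200L, 200L))
  expect_equal(r$voxel_size[1:2], c(0.047, 0.047))
  # physical extent preserved to within one voxel
  expect_lt(abs(dim(r$voxels)[3] * 0.047 - 100 * 0.094), 0.094)
  expect_error(rescale_stack(s, -1), "> 0")

  # smooth plane: down-then-up resampling stays close to the original, and
  # the result agrees with an independent bilinear resampler
  g <- outer(seq_len(64), seq_len(64), function(i, j) {
    sin(i / 9) + cos(j / 11)
  })
  sm <- image_stack(array(g, c(1, 64, 64)), c(0.1, 0.1, 0.5))
  down <- rescale_stack(sm, 0.2)
  up <- rescale_stack(down, 0.1)
  expect_lt(mean(abs(up$voxels[1, , ] - g)), 0.05)
  expect_gte(min(down$voxels), min(g))
  expect_lte(max(down$voxels), max(g))
})
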