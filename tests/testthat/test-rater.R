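pts <- function(x, y, z, rater, round = 1L) {
  data.frame(x_um = x, y_um = y, z_um = z, rater = rater, round = round)
}

test_that("nearby annotations from different raters form one cluster", {
  p <- rbind(pts(10, 10, 5, "a"), pts(10.3, 10, 6, "b"))
  cl <- cluster_annotations(p)
  expect_equal(length(cl$clusters), 1L)
  expect_equal(nrow(cl$clusters[[1]]$members), 2L)
})

test_that("oversize clusters are split below the maximum size", {
  set.seed(2)
  p <- pts(10 + runif(9, -0.2, 0.2), 10 + runif(9, -0.2, 0.2),
           5 + runif(9, -0.5, 0.5), sprintf("r%d", 1:9))
  cl <- cluster_annotations(p, max_size = 7)
  sizes <- vapply(cl$clusters, function(c) nrow(c$members), integer(1))
  expect_equal(sum(sizes), 9L)
  expect_true(all(sizes <= 7))
  expect_gte(length(cl$clusters), 2L)
})

test_that("points too distant in z are ejected into singletons", {
  p <- rbind(pts(10, 10, 5, "a"), pts(10.1, 10, 5.2, "b"),
             pts(10, 10.1, 5.1, "c"), pts(10, 10, 10, "d"))  # 5 um away in z
  cl <- cluster_annotations(p)
  sizes <- sort(vapply(cl$clusters, function(c) nrow(c$members), integer(1)))
  expect_equal(sizes, c(1L, 3L))
  lone <- cl$clusters[[which(sizes == 1)[1]]]
  ras <- lapply(cl$clusters, function(c) c$members$rater)
  expect_true(any(vapply(ras, function(r) identical(r, "d"), logical(1))))
})

test_that("clustering postconditions hold on random point clouds (fuzz)", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60
    p <- pts(runif(n, 0, 12), runif(n, 0, 12), runif(n, 0, 6),
             sample(sprintf("r%d", 1:7), n, TRUE))
    cl <- cluster_annotations(p, seed = seed)
    sizes <- vapply(cl$clusters, function(c) nrow(c$members), integer(1))
    expect_equal(sum(sizes), n)                  # every point in one cluster
    expect_true(all(sizes <= 7))                 # max size respected
    for (c in cl$clusters) {                     # membership radii respected
      ctr <- c$centroid
      expect_true(all(abs(c$members$x_um - ctr[1]) <= 0.85 + 1e-9))
      expect_true(all(abs(c$members$y_um - ctr[2]) <= 0.85 + 1e-9))
      expect_true(all(abs(c$members$z_um - ctr[3]) <= 2.5 + 1e-9))
    }
  }
})

test_that("empty input yields an empty cluster set", {
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), rater = character(0),
                      round = integer(0))
  cl <- cluster_annotations(empty)
  expect_equal(length(cl$clusters), 0L)
})

test_that("recall matrix counts co-clustered raters correctly", {
  # identical point sets: perfect mutual recall
  p <- rbind(pts(1:4, 1, 1, "a"), pts(1:4 + 0.05, 1, 1, "b"))
  m <- pairwise_recall_matrix(cluster_annotations(p))
  expect_equal(unname(m), matrix(1, 2, 2))
  # b annotated exactly half of a's spines
  p2 <- rbind(pts(seq(1, 16, 2), 1, 1, "a"), pts(c(1, 3, 5, 7) + 0.05, 1, 1, "b"))
  m2 <- pairwise_recall_matrix(cluster_annotations(p2))
  expect_equal(m2["a", "b"], 0.5)
  expect_equal(m2["b", "a"], 1.0)
  expect_equal(diag(m2), c(a = 1, b = 1))
  # invariant under rigid translation of all points
  p3 <- p2
  p3$x_um <- p3$x_um + 5; p3$y_um <- p3$y_um - 2; p3$z_um <- p3$z_um + 1
  expect_equal(pairwise_recall_matrix(cluster_annotations(p3)), m2)
})

test_that("simulated recall approaches the detection probability", {
  p_true <- 0.85
  offs <- unlist(lapply(1:10, function(seed) {
    gt <- generate_scene(tiny_scene(seed = seed, n_spines = 5))
    ann <- simulate_raters(gt, rater_model(
      n_raters = 7, detection_prob = p_true, jitter_sd_um = c(0.1, 0.3),
      false_positive_rate = 0, seed = seed))
    m <- pairwise_recall_matrix(cluster_annotations(ann, seed = seed))
    m[row(m) != col(m)]
  }))
  se <- stats::sd(offs) / sqrt(length(offs))
  expect_lt(abs(mean(offs) - p_true), max(4 * se, 0.03))
})

test_that("cluster count recovers the true spine count under good raters", {
  errs <- vapply(1:10, function(seed) {
    gt <- generate_scene(tiny_scene(seed = seed, n_spines = 5))
    ann <- simulate_raters(gt, rater_model(
      n_raters = 7, detection_prob = 0.9, jitter_sd_um = c(0.1, 0.3),
      false_positive_rate = 0, seed = seed + 100))
    abs(length(cluster_annotations(ann, seed = seed)$clusters) - 5) / 5
  }, numeric(1))
  expect_lte(mean(errs), 0.05)
})

test_that("reliability summary computes IRR, intra-rater and cluster sizes", {
  # constructed matrix semantics: all off-diagonals equal -> sd 0
  p <- rbind(pts(1:5, 1, 1, "a"), pts(1:5 + 0.02, 1, 1, "b"),
             pts(1:4 + 0.04, 1, 1, "c"))
  rs <- reliability_summary(cluster_annotations(p))
  expect_true(all(rs$recall_matrix[c("a", "b"), "c"] == 0.8))
  expect_equal(sum(rs$cluster_size_counts), 5)
  expect_equal(rs$cluster_size_fraction[3], 4 / 5)
  # identical rounds give 100% intra-rater reliability
  two <- rbind(pts(1:6, 2, 1, "k", 1L), pts(1:6, 2, 1, "k", 2L))
  expect_equal(intra_rater_reliability(two), 100)
  # and a half-missing second round gives 75% (mean of 0.5 and 1)
  half <- rbind(pts(1:4, 2, 1, "k", 1L), pts(1:2, 2, 1, "k", 2L))
  expect_equal(intra_rater_reliability(half), 75)
  expect_error(intra_rater_reliability(pts(1, 1, 1, "a")), "two annotation")
})

test_that("mask IoU identities, symmetry and toy values", {
  A <- array(0, c(2, 3, 3)); A[1, 1:2, 1:2] <- 1
  B <- array(0, c(2, 3, 3)); B[1, 2:3, 1:2] <- 1
  expect_equal(mask_iou(A, A), 1)
  expect_equal(mask_iou(A, B), mask_iou(B, A))
  expect_equal(mask_iou(A, B), 2 / 6)
  disj <- array(0, c(2, 3, 3)); disj[2, 3, 3] <- 1
  expect_equal(mask_iou(A, disj), 0)
  expect_equal(mask_iou(A * 0, A * 0), 1)  # agreement on absence
  expect_error(mask_iou(A, array(0, c(1, 3, 3))), "shape")
})

test_that("rater mask combination obeys set algebra", {
  set.seed(4)
  ms <- lapply(1:3, function(i) array(rbinom(27, 1, 0.4), c(3, 3, 3)))
  inter <- combine_rater_masks(ms, "intersection")
  uni <- combine_rater_masks(ms, "union")
  for (m in ms) {
    expect_true(all(inter <= (m != 0)))
    expect_true(all((m != 0) <= uni))
  }
  expect_equal(combine_rater_masks(ms[1], "union") * 1, ms[[1]] * 1)
  # three pairwise disjoint masks: empty intersection, additive union
  d1 <- array(0, c(1, 2, 6)); d2 <- d1; d3 <- d1
  d1[1, 1, 1:2] <- 1; d2[1, 1, 3:4] <- 1; d3[1, 1, 5:6] <- 1
  expect_equal(sum(combine_rater_masks(list(d1, d2, d3), "intersection")), 0)
  expect_equal(combine_rater_masks(list(d1, d2, d3), "union") * 1,
               (d1 + d2 + d3 > 0) * 1)
})
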