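#' Cluster spine-center annotations across raters
#'
#' Pools the point annotations of all raters (an algorithm's ROI centroids
#' can be included as an extra rater) and groups points that refer to the
#' same dendritic spine. Coordinates are anisotropically scaled so the xy
#' and z matching radii become one common radius, then density-clustered
#' (eps-neighborhood graph components with every point a core point, i.e.
#' DBSCAN with min_samples = 1 — singleton annotations must form their own
#' clusters). Three a priori adjustment passes follow: (i) points too
#' distant from their cluster centroid (more than `r_xy` in x or y, or `r_z`
#' in z) are ejected into singleton clusters; (ii) clusters with more than
#' `max_size` members are split with 2-means until none is oversize;
#' (iii) cluster pairs whose centroids are within the radii are greedily
#' merged (nearest pairs first) when the merged cluster stays within
#' `max_size` and all members remain within the radii of the merged
#' centroid. Centroids are recomputed after every change.
#'
#' @param points a `point_annotations` data.frame (um coordinates).
#' @param r_xy matching radius in x and y (um).
#' @param r_z matching radius in z (um).
#' @param max_size maximum annotations per cluster (default 7 = the number
#'   of raters).
#' @param seed seed for the 2-means splits.
#' @return a `cluster_set`: list with `clusters` (each
#'   `list(members, centroid)`, `members` a data.frame of the member points)
#'   and the parameters used.
#' @export
cluster_annotations <- function(points, r_xy = 0.85, r_z = 2.5,
                                max_size = 7, seed = 1L) {
  points <- point_annotations(points)
  if (nrow(points) == 0) {
    return(structure(list(clusters = list(),
                          params = list(r_xy = r_xy, r_z = r_z,
                                        max_size = max_size)),
                     class = "cluster_set"))
  }
  co <- cbind(points$x_um, points$y_um, points$z_um * (r_xy / r_z))
  n <- nrow(co)
  # eps-graph connected components (all points core, min_samples = 1)
  dm <- as.matrix(stats::dist(co)) <= r_xy
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    k <- k + 1L
    frontier <- s
    comp[s] <- k
    while (length(frontier)) {
      nb <- which(colSums(dm[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- k
      frontier <- nb
    }
  }
  clusters <- lapply(seq_len(k), function(i) which(comp == i))

  centroid <- function(idx) c(mean(points$x_um[idx]), mean(points$y_um[idx]),
                              mean(points$z_um[idx]))
  within_radii <- function(idx, ctr) {
    abs(points$x_um[idx] - ctr[1]) <= r_xy &
      abs(points$y_um[idx] - ctr[2]) <= r_xy &
      abs(points$z_um[idx] - ctr[3]) <= r_z
  }

  # pass (i): eject members too distant from the (recomputed) centroid
  i <- 1
  while (i <= length(clusters)) {
    repeat {
      idx <- clusters[[i]]
      if (length(idx) <= 1) break
      ctr <- centroid(idx)
      ok <- within_radii(idx, ctr)
      if (all(ok)) break
      # eject the farthest offender into a singleton cluster
      dist2 <- (points$x_um[idx] - ctr[1])^2 + (points$y_um[idx] - ctr[2])^2 +
        ((points$z_um[idx] - ctr[3]) * r_xy / r_z)^2
      worst <- idx[which.max(ifelse(ok, -Inf, dist2))]
      clusters[[i]] <- setdiff(idx, worst)
      clusters[[length(clusters) + 1]] <- worst
    }
    i <- i + 1
  }

  # pass (ii): split oversize clusters with 2-means until none exceeds max
  set.seed(seed)
  repeat {
    big <- which(lengths(clusters) > max_size)
    if (!length(big)) break
    i <- big[1]
    idx <- clusters[[i]]
    pts <- co[idx, , drop = FALSE]
    # initialize with the two most mutually distant members
    dm2 <- as.matrix(stats::dist(pts))
    far <- which(dm2 == max(dm2), arr.ind = TRUE)[1, ]
    km <- stats::kmeans(pts, centers = pts[far, , drop = FALSE])
    clusters[[i]] <- idx[km$cluster == 1]
    clusters[[length(clusters) + 1]] <- idx[km$cluster == 2]
  }

  # pass (iii): greedy merge of qualifying nearest cluster pairs
  repeat {
    ctrs <- t(vapply(clusters, centroid, numeric(3)))
    nc <- nrow(ctrs)
    if (nc < 2) break
    sc <- cbind(ctrs[, 1], ctrs[, 2], ctrs[, 3] * r_xy / r_z)
    dmc <- as.matrix(stats::dist(sc))
    close_xy <- abs(outer(ctrs[, 1], ctrs[, 1], `-`)) < r_xy &
      abs(outer(ctrs[, 2], ctrs[, 2], `-`)) < r_xy &
      abs(outer(ctrs[, 3], ctrs[, 3], `-`)) < r_z
    diag(close_xy) <- FALSE
    merged <- FALSE
    if (any(close_xy)) {
      ord <- order(dmc[close_xy])
      pairs <- which(close_xy, arr.ind = TRUE)
      pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
      pairs <- pairs[order(dmc[pairs]), , drop = FALSE]
      for (p in seq_len(nrow(pairs))) {
        a <- pairs[p, 1]; b <- pairs[p, 2]
        idx <- c(clusters[[a]], clusters[[b]])
        if (length(idx) > max_size) next
        if (!all(within_radii(idx, centroid(idx)))) next
        clusters[[a]] <- idx
        clusters <- clusters[-b]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }

  out <- lapply(clusters, function(idx) {
    list(members = points[idx, , drop = FALSE], centroid = centroid(idx))
  })
  structure(list(clusters = out,
                 params = list(r_xy = r_xy, r_z = r_z, max_size = max_size)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), sizes %s\n", length(x$clusters),
              paste(range(c(lengths_of(x), 0)), collapse = "-")))
  invisible(x)
}

lengths_of <- function(cs) vapply(cs$clusters, function(cl) nrow(cl$members),
                                  integer(1))

#' Pairwise recall matrix between raters
#'
#' Entry `(A, B)` is the fraction of clusters containing an annotation by
#' rater A that also contain one by rater B — the recall of A's spines by B
#' (TP / (TP + FN)). Duplicate same-rater members in one cluster count once.
#' The diagonal is identically 1. Raters with zero annotations get `NA`
#' rows/columns.
#'
#' @param clusters a `cluster_set`.
#' @param raters rater labels to include (default: all present).
#' @param round restrict to one annotation round, or `NULL` for all.
#' @return square numeric matrix with rater labels as dimnames.
#' @export
pairwise_recall_matrix <- function(clusters, raters = NULL, round = NULL) {
  membership <- lapply(clusters$clusters, function(cl) {
    m <- cl$members
    if (!is.null(round)) m <- m[m$round == round, , drop = FALSE]
    unique(m$rater)
  })
  all_raters <- sort(unique(unlist(membership)))
  if (is.null(raters)) raters <- all_raters
  n <- length(raters)
  out <- matrix(NA_real_, n, n, dimnames = list(raters, raters))
  for (a in raters) {
    has_a <- vapply(membership, function(m) a %in% m, logical(1))
    if (!any(has_a)) next
    for (b in raters) {
      has_b <- vapply(membership[has_a], function(m) b %in% m, logical(1))
      out[a, b] <- mean(has_b)
    }
  }
  out
}

#' Reliability summary statistics
#'
#' Inter-rater reliability (IRR) is the mean +/- sd of the off-diagonal
#' entries of the pairwise recall matrix, in percent. With two annotation
#' rounds per rater, intra-rater reliability is the mean of the two
#' directed recalls between a rater's rounds, averaged over raters. The
#' cluster-size distribution counts, for each k, the fraction of spines
#' (clusters) found by exactly k raters.
#'
#' @param clusters a `cluster_set` (points may carry 1 or 2 rounds).
#' @param raters rater labels to include.
#' @return list with `irr_mean_pct`, `irr_sd_pct`, `recall_matrix`,
#'   `intra_rater_pct` (NA without a second round), `cluster_size_counts`
#'   and `cluster_size_fraction`.
#' @export
reliability_summary <- function(clusters, raters = NULL) {
  mat <- pairwise_recall_matrix(clusters, raters)
  if (nrow(mat) < 2) stop("reliability requires at least 2 raters")
  off <- mat[row(mat) != col(mat)]
  irr_mean <- mean(off, na.rm = TRUE) * 100
  irr_sd <- stats::sd(off, na.rm = TRUE) * 100

  # intra-rater reliability: re-cluster each two-round rater's own points
  # (the pooled clustering saturates at max_size with 2 rounds x 7 raters)
  pts <- do.call(rbind, lapply(clusters$clusters, `[[`, "members"))
  intra <- tryCatch(
    intra_rater_reliability(pts, r_xy = clusters$params$r_xy,
                            r_z = clusters$params$r_z),
    error = function(e) NA_real_)

  sizes <- vapply(clusters$clusters, function(cl) {
    length(unique(cl$members$rater))
  }, integer(1))
  counts <- tabulate(sizes, nbins = max(c(sizes, 1)))
  list(irr_mean_pct = irr_mean, irr_sd_pct = irr_sd, recall_matrix = mat,
       intra_rater_pct = intra, cluster_size_counts = counts,
       cluster_size_fraction = counts / sum(counts))
}

#' Intra-rater reliability across two annotation rounds
#'
#' For every rater with two annotation rounds, the rater's own points are
#' clustered with the standard matching radii (maximum cluster size 2, one
#' point per round) and the two directed recalls between the rounds are
#' averaged; the result is the mean over raters, in percent.
#'
#' @param points a `point_annotations` data.frame carrying a `round` field
#'   with two rounds for at least one rater.
#' @param r_xy,r_z matching radii in um.
#' @return mean intra-rater reliability in percent.
#' @export
intra_rater_reliability <- function(points, r_xy = 0.85, r_z = 2.5) {
  points <- point_annotations(points)
  tab <- table(points$rater, points$round)
  two_round <- rownames(tab)[rowSums(tab > 0) >= 2]
  if (!length(two_round)) stop("no rater has two annotation rounds")
  per_rater <- vapply(two_round, function(r) {
    sub <- points[points$rater == r, , drop = FALSE]
    rounds <- sort(unique(sub$round))[1:2]
    # tag rounds as pseudo-raters so pairwise recall applies directly
    sub$rater <- paste0("round", match(sub$round, rounds))
    cl <- cluster_annotations(sub, r_xy = r_xy, r_z = r_z, max_size = 2)
    m <- pairwise_recall_matrix(cl)
    mean(m[row(m) != col(m)], na.rm = TRUE)
  }, numeric(1))
  mean(per_rater) * 100
}

#' Intersection-over-union of two binary volumes
#'
#' `|A and B| / |A or B|`; defined as 1 when both masks are empty (perfect
#' agreement on absence).
#'
#' @param A,B binary arrays of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
mask_iou <- function(A, B) {
  if (!identical(dim2(A), dim2(B))) stop("shape mismatch in mask_iou")
  a <- A != 0
  b <- B != 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Combine several raters' masks by intersection or union
#'
#' @param masks list of equal-shape binary arrays (or [image_stack]s).
#' @param mode `"intersection"` (voxelwise AND) or `"union"` (voxelwise OR).
#' @return binary array.
#' @export
combine_rater_masks <- function(masks, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  masks <- lapply(masks, function(m) {
    if (is_image_stack(m)) m$voxels != 0 else m != 0
  })
  d <- dim2(masks[[1]])
  if (any(!vapply(masks, function(m) identical(dim2(m), d), logical(1)))) {
    stop("shape mismatch across masks")
  }
  out <- masks[[1]]
  for (m in masks[-1]) {
    out <- if (mode == "intersection") out & m else out | m
  }
  out
}

#' Multi-rater benchmark reliability analysis
#'
#' Runs the full clustering + recall pipeline on a directory containing the
#' open multi-rater benchmark: a point-annotation table (`annotations.csv`
#' with columns `x_um, y_um, z_um, rater, round`) produced from the seven
#' raters' center-of-mass annotations. Returns the reliability summary.
#'
#' @param dir directory holding `annotations.csv`.
#' @param r_xy,r_z,max_size clustering parameters (see
#'   [cluster_annotations()]).
#' @return a [reliability_summary()] list.
#' @export
benchmark_reliability <- function(dir, r_xy = 0.85, r_z = 2.5, max_size = 7) {
  path <- file.path(dir, "annotations.csv")
  if (!file.exists(path)) {
    stop(sprintf(paste0(
      "benchmark annotations not found at %s; download the open multi-rater ",
      "benchmark archive and export the point annotations as annotations.csv ",
      "(columns x_um, y_um, z_um, rater, round)"), path))
  }
  ann <- read_annotations(path)
  cl <- cluster_annotations(ann, r_xy = r_xy, r_z = r_z, max_size = max_size)
  reliability_summary(cl)
}

#' Pixel-wise segmentation agreement across raters
#'
#' Computes the mean pairwise IoU over all rater pairs for dendrite and
#' spine label volumes stored as TIFF masks `<rater>_dendrites.tif` /
#' `<rater>_spines.tif` in `dir`.
#'
#' @param dir directory with per-rater mask TIFFs.
#' @param raters rater name prefixes (default the three pixel-wise raters
#'   `c("U", "V", "W")`).
#' @param voxel_size voxel size metadata passed to [read_stack()].
#' @return list with `dendrite_mean_iou`, `spine_mean_iou` and per-pair
#'   matrices.
#' @export
benchmark_segmentation_agreement <- function(dir, raters = c("U", "V", "W"),
                                             voxel_size = c(0.094, 0.094, 0.5)) {
  load_masks <- function(kind) {
    lapply(raters, function(r) {
      p <- file.path(dir, sprintf("%s_%s.tif", r, kind))
      if (!file.exists(p)) stop(sprintf("mask not found: %s", p))
      read_stack(p, voxel_size)$voxels > 0
    })
  }
  pair_mean <- function(masks) {
    n <- length(masks)
    mat <- matrix(NA_real_, n, n, dimnames = list(raters, raters))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j) mat[i, j] <- mask_iou(masks[[i]], masks[[j]])
    }
    list(mean = mean(mat[upper.tri(mat)]), matrix = mat)
  }
  dend <- pair_mean(load_masks("dendrites"))
  spin <- pair_mean(load_masks("spines"))
  list(dendrite_mean_iou = dend$mean, spine_mean_iou = spin$mean,
       dendrite_iou_matrix = dend$matrix, spine_iou_matrix = spin$matrix)
}
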