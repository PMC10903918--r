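#' Fixed-tile overfit sanity benchmark
#'
#' Builds a small set of fixed synthetic tiles (windows cropped around the
#' dendrite from independently generated scenes), trains a compact model
#' (F = 8, D = 2) on exactly those tiles for a fixed number of Adam steps,
#' and reports the ratio of the final to the initial combined loss
#' (dendrite Dice + spine MSE). A healthy implementation overfits this tiny
#' problem rapidly, so the ratio should drop well below 1.
#'
#' @param seed seed controlling scenes, initialization and ordering.
#' @param steps number of optimization steps.
#' @param n_tiles number of fixed tiles.
#' @param tile_size tile edge in px.
#' @param lr constant Adam learning rate for this sanity run.
#' @return list with `ratio`, `initial`, `final` and the per-step loss track.
#' @export
overfit_benchmark <- function(seed = 1, steps = 200, n_tiles = 8,
                              tile_size = 32, lr = 2e-3) {
  tiles <- fixed_structure_tiles(n_tiles, tile_size, seed)
  model <- build_model(arch_config(8, 2, tile_size, seed = seed))
  n <- length(tiles)
  x <- array(0, c(tile_size, tile_size, 1, n))
  yd <- array(0, c(tile_size, tile_size, 1, n))
  ys <- array(0, c(tile_size, tile_size, 1, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- tiles[[i]]$image
    yd[, , 1, i] <- tiles[[i]]$dendrites
    ys[, , 1, i] <- tiles[[i]]$spines
  }
  opt <- adam_init(model$params)
  track <- numeric(steps)
  for (s in seq_len(steps)) {
    fwd <- model_fwd(model, x, training = TRUE)
    for (nm in names(fwd$bn_updates)) model$bn[[nm]] <- fwd$bn_updates[[nm]]
    track[s] <- dice_loss(yd, fwd$dendrite) + spine_loss(ys, fwd$spine)
    grads <- model_bwd(model, fwd, dice_loss_grad(yd, fwd$dendrite),
                       spine_loss_grad(ys, fwd$spine))
    upd <- adam_step(opt, model$params, grads, lr)
    model$params <- upd$params
    opt <- upd$opt
  }
  list(ratio = min(track) / track[1], initial = track[1], final = min(track),
       track = track, model = model)
}

# crop fixed tiles centered on dendritic structure from synthetic scenes
fixed_structure_tiles <- function(n_tiles, tile_size, seed) {
  tiles <- vector("list", n_tiles)
  for (i in seq_len(n_tiles)) {
    spec <- scene_spec(n_spines = 3, stack_shape = c(4, 64, 64),
                       seed = seed * 1000L + i)
    gt <- generate_scene(spec)
    raw <- render_stack(gt, spec)
    # plane and window with the most labeled structure
    per_plane <- apply(gt$dendrite_mask$voxels + gt$spine_mask$voxels,
                       1, sum)
    z <- which.max(per_plane)
    comb <- gt$dendrite_mask$voxels[z, , ] + gt$spine_mask$voxels[z, , ]
    ys <- round(mean(which(rowSums(comb) > 0)))
    xs <- round(mean(which(colSums(comb) > 0)))
    y0 <- min(max(1, ys - tile_size %/% 2), 64 - tile_size + 1)
    x0 <- min(max(1, xs - tile_size %/% 2), 64 - tile_size + 1)
    ry <- y0:(y0 + tile_size - 1)
    rx <- x0:(x0 + tile_size - 1)
    tiles[[i]] <- list(
      image = normalize_intensity(raw$voxels[z, ry, rx]),
      spines = gt$spine_mask$voxels[z, ry, rx],
      dendrites = gt$dendrite_mask$voxels[z, ry, rx])
  }
  tiles
}

#' Train a model on synthetic scenes
#'
#' Convenience wrapper: writes a synthetic training set, streams tiles and
#' trains a compact dual-decoder model. Used by the end-to-end validation
#' pipeline and the reproduction script.
#'
#' @param n_train number of training scenes.
#' @param seed base seed (scenes use `seed*100 + i`).
#' @param steps total optimization steps.
#' @param tile_size training tile edge.
#' @param base_filters,depth architecture capacity.
#' @param lr constant learning rate for this scaled-down run.
#' @param n_spines spines per training scene.
#' @return trained `seg_model`.
#' @export
train_synthetic_model <- function(n_train = 20, seed = 1, steps = 300,
                                  tile_size = 48, base_filters = 8, depth = 2,
                                  lr = 2e-3, n_spines = 4) {
  out_dir <- tempfile("synth_train")
  scenes <- lapply(seq_len(n_train), function(i) {
    scene_spec(n_spines = n_spines, stack_shape = c(6, 64, 64),
               seed = seed * 100L + i)
  })
  manifest <- make_training_set(scenes, out_dir)
  on.exit(unlink(out_dir, recursive = TRUE))
  cfg <- train_config(lr0 = lr, warm_epochs = 1e6, tile_size = tile_size,
                      batch_size = 8, epochs = 1, steps_per_epoch = steps,
                      augment = FALSE, seed = seed)
  model <- build_model(arch_config(base_filters, depth, tile_size,
                                   seed = seed))
  train_model(model, manifest, cfg)$model
}

#' Evaluate spine recovery on held-out synthetic stacks
#'
#' Renders a held-out scene, predicts probability maps, applies the standard
#' post-processing (dendrite cleaning + dilation gating), builds
#' connected-component ROIs with default filters, and compares against the
#' known ground truth.
#'
#' @param model trained `seg_model`.
#' @param seed scene seed for the held-out stack.
#' @param n_spines true spine count for the held-out scene.
#' @param threshold spine-map binarization for the IoU measurement.
#' @return list with `n_true`, `n_rois`, `spine_iou`, `dendrite_iou`.
#' @export
evaluate_spine_recovery <- function(model, seed, n_spines = 4,
                                    threshold = 0.5) {
  spec <- scene_spec(n_spines = n_spines, stack_shape = c(6, 64, 64),
                     seed = seed)
  gt <- generate_scene(spec)
  raw <- render_stack(gt, spec)
  maps <- predict_stack(model, raw)
  maps <- clean_dendrite_map(maps)
  maps <- gate_spines_by_dendrite(maps, dilation_um = 1)
  rois <- connected_component_rois(maps$spine_map,
                                   roi_config(area_threshold = threshold))
  rois <- filter_rois(rois, roi_config(min_roi_size_vox = 10,
                                       max_roi_size_vox = 10000,
                                       min_planes = 1))
  list(n_true = n_spines, n_rois = length(rois),
       spine_iou = mask_iou(maps$spine_map$voxels >= threshold,
                            gt$spine_mask$voxels),
       dendrite_iou = mask_iou(maps$dendrite_map$voxels >= 0.5,
                               gt$dendrite_mask$voxels))
}
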