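#' Normalize tile intensities to [-1, 1]
#'
#' Linearly rescales so the minimum maps to -1 and the maximum to +1. A
#' constant tile (no dynamic range) maps to all zeros. The mapping is
#' invariant under positive affine transforms of the input.
#'
#' @param tile numeric matrix/array of raw intensities.
#' @return same shape, values in `[-1, 1]`.
#' @export
normalize_intensity <- function(tile) {
  lo <- min(tile)
  hi <- max(tile)
  if (hi == lo) return(tile * 0)
  2 * (tile - lo) / (hi - lo) - 1
}

#' Training configuration
#'
#' Defaults follow the reference training schedule: learning rate starting at
#' 5e-4, held for 15 warm epochs, then decayed as `exp(-0.1 * (epoch - 15))`;
#' 128 px square tiles.
#'
#' @param lr0 initial learning rate.
#' @param warm_epochs epochs at constant `lr0`.
#' @param decay_rate exponential decay rate per epoch after warm-up.
#' @param tile_size square tile edge (px).
#' @param batch_size tiles per optimization step.
#' @param epochs training epochs.
#' @param steps_per_epoch optimization steps per epoch.
#' @param resolution_mode `"mixed"` (use native stack resolutions) or
#'   `"fixed"` (rescale all stacks to `target_xy_um` before sampling).
#' @param target_xy_um working resolution for `resolution_mode = "fixed"`.
#' @param loss_mode `"sum"` (both head losses contribute to each update) or
#'   `"alternate"` (strictly alternating per-loss updates).
#' @param augment logical: apply random augmentation to streamed tiles.
#' @param seed RNG seed for streaming, augmentation and optimization.
#' @export
train_config <- function(lr0 = 0.5e-3, warm_epochs = 15, decay_rate = 0.1,
                         tile_size = 128, batch_size = 32, epochs = 50,
                         steps_per_epoch = 50,
                         resolution_mode = c("mixed", "fixed"),
                         target_xy_um = 0.094,
                         loss_mode = c("sum", "alternate"),
                         augment = TRUE, seed = 1L) {
  stopifnot(lr0 > 0, epochs >= 1)
  structure(list(lr0 = lr0, warm_epochs = warm_epochs, decay_rate = decay_rate,
                 tile_size = as.integer(tile_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 resolution_mode = match.arg(resolution_mode),
                 target_xy_um = target_xy_um,
                 loss_mode = match.arg(loss_mode),
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Constant at `lr0` for the first `warm_epochs` epochs, then exponential
#' decay `lr0 * exp(-decay_rate * (epoch - warm_epochs))` (0-based epochs).
#'
#' @param epoch 0-based epoch index.
#' @param config a [train_config].
#' @return learning rate.
#' @export
learning_rate <- function(epoch, config) {
  if (epoch < config$warm_epochs) {
    config$lr0
  } else {
    config$lr0 * exp(-config$decay_rate * (epoch - config$warm_epochs))
  }
}

#' Randomly augment a training sample
#'
#' Geometric transforms (flips, 90-degree rotations, small +/-10 degree
#' rotations) are applied identically to the image and both targets; targets
#' are re-binarized at 0.5 after interpolation. Photometric transforms
#' (Gaussian noise, brightness, contrast) touch the image only.
#'
#' @param sample list with `image`, `spines`, `dendrites` (equal-size
#'   matrices; targets binary).
#' @param seed RNG seed for reproducible augmentation.
#' @param p probability of applying each transform (0 disables all; default
#'   0.5).
#' @param max_angle small-rotation bound in degrees.
#' @param noise_sd Gaussian noise sd (image intensity units, post-normalize
#'   scale).
#' @return an augmented sample of the same structure.
#' @export
augment_tile <- function(sample, seed = NULL, p = 0.5, max_angle = 10,
                         noise_sd = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  img <- sample$image; sp <- sample$spines; de <- sample$dendrites
  if (p <= 0) return(sample)
  geo <- function(f) {
    img <<- f(img); sp <<- f(sp); de <<- f(de)
  }
  if (stats::runif(1) < p) geo(function(m) m[nrow(m):1, , drop = FALSE])
  if (stats::runif(1) < p) geo(function(m) m[, ncol(m):1, drop = FALSE])
  if (stats::runif(1) < p) {
    k <- sample(1:3, 1)
    rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
    geo(function(m) { for (i in seq_len(k)) m <- rot90(m); m })
  }
  if (stats::runif(1) < p) {
    ang <- stats::runif(1, -max_angle, max_angle)
    od <- dim(img)
    img <- EBImage::rotate(img, ang, filter = "bilinear", output.dim = od,
                           bg.col = min(img))
    sp <- (EBImage::rotate(sp, ang, filter = "none", output.dim = od) > 0.5) * 1
    de <- (EBImage::rotate(de, ang, filter = "none", output.dim = od) > 0.5) * 1
  }
  if (stats::runif(1) < p) {
    img <- img + stats::rnorm(length(img), sd = noise_sd)
  }
  if (stats::runif(1) < p) img <- img + stats::runif(1, -0.2, 0.2)  # brightness
  if (stats::runif(1) < p) img <- img * stats::runif(1, 0.8, 1.2)   # contrast
  list(image = img, spines = sp, dendrites = de)
}

# reflect-pad a matrix to at least (ty, tx)
reflect_pad <- function(m, ty, tx) {
  while (nrow(m) < ty) {
    add <- min(nrow(m), ty - nrow(m))
    m <- rbind(m, m[nrow(m):(nrow(m) - add + 1), , drop = FALSE])
  }
  while (ncol(m) < tx) {
    add <- min(ncol(m), tx - ncol(m))
    m <- cbind(m, m[, ncol(m):(ncol(m) - add + 1), drop = FALSE])
  }
  m
}

#' Stream normalized, augmented training batches from a dataset manifest
#'
#' Samples uniformly over (stack, plane, window): a random tile-size window
#' from a random plane of a random stack, per sample. In fixed-resolution
#' mode, stacks are rescaled to the target xy resolution before windowing;
#' in mixed mode, native resolutions are used. Stacks smaller than the tile
#' are reflect-padded. Image tiles are normalized to `[-1, 1]`; targets stay
#' binary.
#'
#' @param manifest data.frame from [make_training_set()] (columns `image`,
#'   `spines`, `dendrites`, `vox_x_um`, `vox_y_um`, `vox_z_um`).
#' @param config a [train_config].
#' @param seed stream seed (defaults to `config$seed`).
#' @return a function `(n)` returning a batch: list of `n` samples, each
#'   `list(image, spines, dendrites, stack_id)`.
#' @export
tile_stream <- function(manifest, config, seed = config$seed) {
  if (nrow(manifest) == 0) stop("empty manifest")
  stacks <- lapply(seq_len(nrow(manifest)), function(i) {
    vs <- c(manifest$vox_x_um[i], manifest$vox_y_um[i], manifest$vox_z_um[i])
    img <- read_stack(manifest$image[i], vs)
    sp <- read_stack(manifest$spines[i], vs)
    de <- read_stack(manifest$dendrites[i], vs)
    if (config$resolution_mode == "fixed") {
      img <- rescale_stack(img, config$target_xy_um)
      sp <- rescale_stack(sp, config$target_xy_um)
      de <- rescale_stack(de, config$target_xy_um)
      sp$voxels <- (sp$voxels > 0.5) * 1
      de$voxels <- (de$voxels > 0.5) * 1
    }
    list(img = img, sp = sp, de = de)
  })
  rng <- seed
  ts <- config$tile_size
  function(n) {
    set.seed(rng)
    batch <- vector("list", n)
    for (b in seq_len(n)) {
      i <- sample.int(length(stacks), 1)
      st <- stacks[[i]]
      d <- dim(st$img$voxels)
      z <- sample.int(d[1], 1)
      im <- st$img$voxels[z, , , drop = TRUE]
      spm <- st$sp$voxels[z, , , drop = TRUE]
      dem <- st$de$voxels[z, , , drop = TRUE]
      im <- reflect_pad(matrix(im, d[2]), ts, ts)
      spm <- reflect_pad(matrix(spm, d[2]), ts, ts)
      dem <- reflect_pad(matrix(dem, d[2]), ts, ts)
      y0 <- sample.int(nrow(im) - ts + 1, 1)
      x0 <- sample.int(ncol(im) - ts + 1, 1)
      sm <- list(image = normalize_intensity(im[y0:(y0 + ts - 1), x0:(x0 + ts - 1)]),
                 spines = spm[y0:(y0 + ts - 1), x0:(x0 + ts - 1)],
                 dendrites = dem[y0:(y0 + ts - 1), x0:(x0 + ts - 1)],
                 stack_id = i)
      if (config$augment) {
        sm2 <- augment_tile(sm)
        sm2$image <- normalize_intensity(sm2$image)
        sm2$stack_id <- i
        sm <- sm2
      }
      batch[[b]] <- sm
    }
    rng <<- rng + 1L
    batch
  }
}

#' Train the dual-decoder model
#'
#' Optimizes the dendrite head with the Dice loss and the spine head with
#' mean-squared error using the Adam optimizer and the warm-up/exponential
#' learning-rate schedule. The two losses are kept separate per head (summed
#' gradients by default, strictly alternating updates with
#' `loss_mode = "alternate"`). Logs both losses per epoch and keeps the
#' best-loss weights.
#'
#' @param model a `seg_model` from [build_model()].
#' @param manifest training manifest (see [tile_stream()]).
#' @param config a [train_config].
#' @param verbose print per-epoch losses.
#' @return list with `model` (best checkpoint), `final_model` (last state),
#'   `log` (data.frame epoch, lr, dendrite_loss, spine_loss).
#' @export
train_model <- function(model, manifest, config, verbose = FALSE) {
  stream <- tile_stream(manifest, config)
  opt <- adam_init(model$params)
  log <- data.frame()
  best <- list(loss = Inf, params = model$params, bn = model$bn)
  step_idx <- 0L
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- learning_rate(epoch, config)
    dl_sum <- 0; sl_sum <- 0
    for (step in seq_len(config$steps_per_epoch)) {
      batch <- stream(config$batch_size)
      ts <- config$tile_size
      n <- length(batch)
      x <- array(0, c(ts, ts, 1, n))
      yd <- array(0, c(ts, ts, 1, n))
      ys <- array(0, c(ts, ts, 1, n))
      for (b in seq_len(n)) {
        x[, , 1, b] <- batch[[b]]$image
        yd[, , 1, b] <- batch[[b]]$dendrites
        ys[, , 1, b] <- batch[[b]]$spines
      }
      fwd <- model_fwd(model, x, training = TRUE)
      for (nm in names(fwd$bn_updates)) model$bn[[nm]] <- fwd$bn_updates[[nm]]
      dl <- dice_loss(yd, fwd$dendrite)
      sl <- spine_loss(ys, fwd$spine)
      if (!is.finite(dl) || !is.finite(sl)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d step %d",
                     epoch, step))
      }
      dl_sum <- dl_sum + dl; sl_sum <- sl_sum + sl
      use_d <- config$loss_mode == "sum" || step_idx %% 2L == 0L
      use_s <- config$loss_mode == "sum" || step_idx %% 2L == 1L
      gd <- if (use_d) dice_loss_grad(yd, fwd$dendrite) else array(0, dim(yd))
      gs <- if (use_s) spine_loss_grad(ys, fwd$spine) else array(0, dim(ys))
      grads <- model_bwd(model, fwd, gd, gs)
      upd <- adam_step(opt, model$params, grads, lr)
      model$params <- upd$params
      opt <- upd$opt
      step_idx <- step_idx + 1L
    }
    dl_m <- dl_sum / config$steps_per_epoch
    sl_m <- sl_sum / config$steps_per_epoch
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 dendrite_loss = dl_m, spine_loss = sl_m))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  dendrite %.4f  spine %.5f",
                      epoch, lr, dl_m, sl_m))
    }
    if (dl_m + sl_m < best$loss) {
      best <- list(loss = dl_m + sl_m, params = model$params, bn = model$bn)
    }
  }
  best_model <- model
  best_model$params <- best$params
  best_model$bn <- best$bn
  list(model = best_model, final_model = model, log = log)
}

adam_init <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / (1 - b1^opt$t)
    vhat <- opt$v[[nm]] / (1 - b2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}
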