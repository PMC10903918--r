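#' Configure the dual-decoder segmentation architecture
#'
#' The network is a U-Net-style encoder with residual blocks and max-pooling,
#' a shared latent representation at the bottom, and two structurally
#' identical decoders (one for dendrites, one for spines) that upsample with
#' parameter-free 2x nearest-neighbor upsampling followed by ordinary
#' convolutions, concatenating matching-scale encoder features (skip
#' connections) before each convolution. Batch normalization precedes every
#' activation; all activations are swish except the two final single-channel
#' 1x1 convolutions, which use the logistic function so outputs are
#' probabilities in `[0, 1]`.
#'
#' @param base_filters initial filter count F (filters double each stage;
#'   8, 16 and 32 are the standard capacity settings).
#' @param depth number of pooling stages D; input tiles must be divisible by
#'   `2^depth`.
#' @param tile_size default square tile size for training (must be divisible
#'   by `2^depth`).
#' @param seed seed for weight initialization.
#' @return an `arch_config` list.
#' @export
arch_config <- function(base_filters = 8, depth = 4, tile_size = 128,
                        seed = 1L) {
  if (tile_size %% 2^depth != 0) {
    stop(sprintf("tile_size %d is not divisible by 2^%d", tile_size, depth))
  }
  structure(list(base_filters = as.integer(base_filters),
                 depth = as.integer(depth),
                 tile_size = as.integer(tile_size),
                 kernel_size = 3L, seed = as.integer(seed)),
            class = "arch_config")
}

#' Build the dual-decoder segmentation model
#'
#' Allocates and He-initializes all weights for the architecture described in
#' [arch_config()]. The model maps a single-channel tile (values in
#' `[-1, 1]`) to two same-shape probability maps (dendrites, spines).
#'
#' @param config an [arch_config].
#' @return a `seg_model` list with `params` (named weight list), `bn`
#'   (batch-norm running statistics) and `config`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "arch_config"))
  set.seed(config$seed)
  F <- config$base_filters
  D <- config$depth
  params <- list()
  bn <- list()
  he <- function(fan_in, n) {
    matrix(stats::rnorm(fan_in * n, sd = sqrt(2 / fan_in)), fan_in, n)
  }
  add_conv <- function(name, cin, cout, k) {
    params[[paste0(name, ".W")]] <<- he(k * k * cin, cout)
    params[[paste0(name, ".b")]] <<- numeric(cout)
  }
  add_bn <- function(name, c) {
    params[[paste0(name, ".gamma")]] <<- rep(1, c)
    params[[paste0(name, ".beta")]] <<- numeric(c)
    bn[[name]] <<- list(mean = numeric(c), var = rep(1, c))
  }
  add_resblock <- function(name, cin, cout) {
    add_conv(paste0(name, ".c1"), cin, cout, 3)
    add_bn(paste0(name, ".bn1"), cout)
    add_conv(paste0(name, ".c2"), cout, cout, 3)
    add_bn(paste0(name, ".bn2"), cout)
    if (cin != cout) add_conv(paste0(name, ".proj"), cin, cout, 1)
  }
  cin <- 1L
  for (s in seq_len(D)) {
    cout <- F * 2^(s - 1)
    add_resblock(sprintf("enc%d", s), cin, cout)
    cin <- cout
  }
  add_resblock("latent", cin, F * 2^D)
  for (head in c("dend", "spine")) {
    cin_d <- F * 2^D
    for (s in rev(seq_len(D))) {
      cout <- F * 2^(s - 1)
      skip_c <- F * 2^(s - 1)
      add_conv(sprintf("%s%d.c", head, s), cin_d + skip_c, cout, 3)
      add_bn(sprintf("%s%d.bn", head, s), cout)
      cin_d <- cout
    }
    add_conv(paste0(head, ".final"), cin_d, 1L, 1)
  }
  structure(list(params = params, bn = bn, config = config),
            class = "seg_model")
}

#' Count trainable parameters
#'
#' @param model a `seg_model`.
#' @return total number of trainable scalars (weights, biases, batch-norm
#'   scale/shift; running statistics are not trainable and not counted).
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

resblock_fwd <- function(x, name, model, training, caches) {
  p <- model$params
  c1 <- conv_fwd(x, p[[paste0(name, ".c1.W")]], p[[paste0(name, ".c1.b")]], 3)
  b1 <- bn_fwd(c1$out, p[[paste0(name, ".bn1.gamma")]],
               p[[paste0(name, ".bn1.beta")]], model$bn[[paste0(name, ".bn1")]],
               training)
  a1 <- swish(b1$out)
  c2 <- conv_fwd(a1, p[[paste0(name, ".c2.W")]], p[[paste0(name, ".c2.b")]], 3)
  b2 <- bn_fwd(c2$out, p[[paste0(name, ".bn2.gamma")]],
               p[[paste0(name, ".bn2.beta")]], model$bn[[paste0(name, ".bn2")]],
               training)
  a2 <- swish(b2$out)
  has_proj <- !is.null(p[[paste0(name, ".proj.W")]])
  sc <- if (has_proj) {
    conv_fwd(x, p[[paste0(name, ".proj.W")]], p[[paste0(name, ".proj.b")]], 1)
  } else list(out = x)
  caches[[name]] <- list(c1 = c1, b1 = b1, pre1 = b1$out, c2 = c2, b2 = b2,
                         pre2 = b2$out, sc = sc, has_proj = has_proj)
  list(out = a2 + sc$out, caches = caches)
}

resblock_bwd <- function(dout, name, model, caches, grads) {
  p <- model$params
  cc <- caches[[name]]
  # shortcut branch
  if (cc$has_proj) {
    g <- conv_bwd(dout, cc$sc, p[[paste0(name, ".proj.W")]], 1)
    grads[[paste0(name, ".proj.W")]] <- g$dW
    grads[[paste0(name, ".proj.b")]] <- g$db
    dx_sc <- g$dx
  } else {
    dx_sc <- dout
  }
  # main branch
  da2 <- dout * swish_grad(cc$pre2)
  g2 <- bn_bwd(da2, cc$b2, p[[paste0(name, ".bn2.gamma")]])
  grads[[paste0(name, ".bn2.gamma")]] <- g2$dgamma
  grads[[paste0(name, ".bn2.beta")]] <- g2$dbeta
  gc2 <- conv_bwd(g2$dx, cc$c2, p[[paste0(name, ".c2.W")]], 3)
  grads[[paste0(name, ".c2.W")]] <- gc2$dW
  grads[[paste0(name, ".c2.b")]] <- gc2$db
  da1 <- gc2$dx * swish_grad(cc$pre1)
  g1 <- bn_bwd(da1, cc$b1, p[[paste0(name, ".bn1.gamma")]])
  grads[[paste0(name, ".bn1.gamma")]] <- g1$dgamma
  grads[[paste0(name, ".bn1.beta")]] <- g1$dbeta
  gc1 <- conv_bwd(g1$dx, cc$c1, p[[paste0(name, ".c1.W")]], 3)
  grads[[paste0(name, ".c1.W")]] <- gc1$dW
  grads[[paste0(name, ".c1.b")]] <- gc1$db
  list(dx = gc1$dx + dx_sc, grads = grads)
}

# full forward pass; x is [H, W, 1, N]; returns heads plus caches for backprop
model_fwd <- function(model, x, training = FALSE) {
  D <- model$config$depth
  p <- model$params
  caches <- list()
  skips <- vector("list", D)
  h <- x
  for (s in seq_len(D)) {
    r <- resblock_fwd(h, sprintf("enc%d", s), model, training, caches)
    caches <- r$caches
    skips[[s]] <- r$out
    mp <- maxpool_fwd(r$out)
    caches[[sprintf("pool%d", s)]] <- mp
    h <- mp$out
  }
  r <- resblock_fwd(h, "latent", model, training, caches)
  caches <- r$caches
  latent <- r$out
  heads <- list()
  for (head in c("dend", "spine")) {
    h <- latent
    for (s in rev(seq_len(D))) {
      nm <- sprintf("%s%d", head, s)
      u <- upsample_fwd(h)
      cat_in <- concat_channels(u, skips[[s]])
      cv <- conv_fwd(cat_in, p[[paste0(nm, ".c.W")]], p[[paste0(nm, ".c.b")]], 3)
      bnf <- bn_fwd(cv$out, p[[paste0(nm, ".bn.gamma")]],
                    p[[paste0(nm, ".bn.beta")]], model$bn[[paste0(nm, ".bn")]],
                    training)
      caches[[nm]] <- list(cv = cv, bn = bnf, pre = bnf$out,
                           n_up = dim(u)[3])
      h <- swish(bnf$out)
    }
    fc <- conv_fwd(h, p[[paste0(head, ".final.W")]],
                   p[[paste0(head, ".final.b")]], 1)
    caches[[paste0(head, ".final")]] <- fc
    heads[[head]] <- logistic(fc$out)
  }
  list(dendrite = heads$dend, spine = heads$spine, caches = caches,
       bn_updates = if (training) collect_bn_updates(caches) else NULL)
}

collect_bn_updates <- function(caches) {
  upd <- list()
  for (nm in names(caches)) {
    cc <- caches[[nm]]
    if (!is.null(cc$b1)) {
      upd[[paste0(nm, ".bn1")]] <- cc$b1$state
      upd[[paste0(nm, ".bn2")]] <- cc$b2$state
    } else if (!is.null(cc$bn)) {
      upd[[paste0(nm, ".bn")]] <- cc$bn$state
    }
  }
  upd
}

# backward pass from head-output gradients (w.r.t. the probability outputs)
model_bwd <- function(model, fwd, d_dend, d_spine) {
  D <- model$config$depth
  p <- model$params
  caches <- fwd$caches
  grads <- list()
  d_latent <- NULL
  for (head in c("dend", "spine")) {
    y <- if (head == "dend") fwd$dendrite else fwd$spine
    dprob <- if (head == "dend") d_dend else d_spine
    dz <- dprob * y * (1 - y)                       # through final logistic
    fc <- caches[[paste0(head, ".final")]]
    g <- conv_bwd(dz, fc, p[[paste0(head, ".final.W")]], 1)
    grads[[paste0(head, ".final.W")]] <- g$dW
    grads[[paste0(head, ".final.b")]] <- g$db
    dh <- g$dx
    skip_grads <- vector("list", D)
    for (s in seq_len(D)) {
      nm <- sprintf("%s%d", head, s)
      cc <- caches[[nm]]
      da <- dh * swish_grad(cc$pre)
      gb <- bn_bwd(da, cc$bn, p[[paste0(nm, ".bn.gamma")]])
      grads[[paste0(nm, ".bn.gamma")]] <- gb$dgamma
      grads[[paste0(nm, ".bn.beta")]] <- gb$dbeta
      gcv <- conv_bwd(gb$dx, cc$cv, p[[paste0(nm, ".c.W")]], 3)
      grads[[paste0(nm, ".c.W")]] <- gcv$dW
      grads[[paste0(nm, ".c.b")]] <- gcv$db
      nu <- cc$n_up
      d_cat <- gcv$dx
      d_up <- d_cat[, , seq_len(nu), , drop = FALSE]
      skip_grads[[s]] <- d_cat[, , nu + seq_len(dim(d_cat)[3] - nu), ,
                               drop = FALSE]
      dh <- upsample_bwd(d_up)
    }
    d_latent <- if (is.null(d_latent)) dh else d_latent + dh
    attr_nm <- paste0("skip_", head)
    grads[[attr_nm]] <- skip_grads
  }
  skip_d <- grads[["skip_dend"]]; grads[["skip_dend"]] <- NULL
  skip_s <- grads[["skip_spine"]]; grads[["skip_spine"]] <- NULL
  r <- resblock_bwd(d_latent, "latent", model, caches, grads)
  grads <- r$grads
  dh <- r$dx
  for (s in rev(seq_len(D))) {
    dh <- maxpool_bwd(dh, caches[[sprintf("pool%d", s)]])
    dh <- dh + skip_d[[s]] + skip_s[[s]]
    r <- resblock_bwd(dh, sprintf("enc%d", s), model, caches, grads)
    grads <- r$grads
    dh <- r$dx
  }
  grads
}

#' Predict dendrite and spine maps for a batch of tiles
#'
#' Runs the network in evaluation mode (batch-norm running statistics), so
#' repeated calls on the same input give identical output.
#'
#' @param model a `seg_model`.
#' @param tiles matrix `[H, W]` (one tile) or array `[H, W, N]`.
#' @return list with `dendrite` and `spine` arrays shaped like `tiles`,
#'   values in `[0, 1]`.
#' @export
predict_tiles <- function(model, tiles) {
  if (is.matrix(tiles)) tiles <- array(tiles, c(dim(tiles), 1))
  d <- dim(tiles)
  x <- array(tiles, c(d[1], d[2], 1, d[3]))
  out <- model_fwd(model, x, training = FALSE)
  list(dendrite = array(out$dendrite, d), spine = array(out$spine, d))
}

#' Save / load a model checkpoint
#'
#' Weights and batch-norm state are serialized to an RDS file; the
#' architecture configuration is written alongside as a JSON sidecar.
#'
#' @param model a `seg_model`.
#' @param path checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(params = model$params, bn = model$bn), path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  blob <- readRDS(path)
  cfgl <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- arch_config(cfgl$base_filters, cfgl$depth, cfgl$tile_size, cfgl$seed)
  structure(list(params = blob$params, bn = blob$bn, config = cfg),
            class = "seg_model")
}
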