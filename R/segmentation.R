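#' Segmentation configuration
#'
#' Settings for the tile-based encoder-decoder (U-Net style) segmenter.
#' Full-scale work in the field uses 512-px tiles; the defaults here are a
#' desk scale (128-px tiles, depth 3, 16 base filters) that trains in
#' minutes on one CPU while preserving the architecture.
#'
#' @param tile_size tile side in pixels; must be divisible by `2^depth`.
#' @param depth number of 2x downsampling levels in the contracting path.
#' @param base_filters channels of the first level; doubled per level.
#' @param epochs maximum training epochs.
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling weight initialization and tile order.
#' @param threshold probability cut for binarizing predictions, in (0,1).
#' @param stop_loss early-stopping target: training stops once the epoch mean
#'   binary cross-entropy falls below this value (set 0 to disable).
#' @return an object of class `seg_config`.
#' @export
seg_config <- function(tile_size = 128L, depth = 3L, base_filters = 16L,
                       epochs = 100L, learning_rate = 1e-3, seed = 1L,
                       threshold = 0.5, stop_loss = 0.02) {
  if (tile_size %% (2^depth) != 0)
    stop("tile_size (", tile_size, ") must be divisible by 2^depth = ", 2^depth)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  structure(list(tile_size = as.integer(tile_size), depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed), threshold = threshold,
                 stop_loss = stop_loss),
            class = "seg_config")
}

#' Crop an image/mask pair into training tiles
#'
#' Tiles lie on a regular grid with the given stride; remainder tiles at the
#' right/bottom edge are shifted inward so that every tile is fully inside
#' the image (no zero padding).
#'
#' @param image numeric matrix (grayscale in \[0,1\]) or a `section_image`.
#' @param mask binary matrix of the same shape, or `NULL` for prediction
#'   tiling.
#' @param tile_size tile side in pixels.
#' @param stride grid step in pixels (>= 1).
#' @return list of tiles; each has `image`, `mask` (or `NULL`), and the
#'   0-based offsets `row0`, `col0`.
#' @export
crop_tiles <- function(image, mask = NULL, tile_size = 128L, stride = tile_size) {
  img <- if (inherits(image, "section_image")) image$pixels else image
  if (stride < 1) stop("stride must be >= 1")
  H <- nrow(img); W <- ncol(img)
  if (H < tile_size || W < tile_size)
    stop("image (", H, "x", W, ") smaller than tile_size ", tile_size)
  if (!is.null(mask) && !all(dim(mask) == c(H, W)))
    stop("image and mask shapes differ")
  starts <- function(n) {
    s <- seq(0L, n - tile_size, by = stride)
    if (s[length(s)] != n - tile_size) s <- c(s, n - tile_size)
    s
  }
  tiles <- list()
  for (r0 in starts(H)) {
    for (c0 in starts(W)) {
      ri <- (r0 + 1):(r0 + tile_size); ci <- (c0 + 1):(c0 + tile_size)
      tiles[[length(tiles) + 1L]] <- list(
        image = img[ri, ci, drop = FALSE],
        mask = if (is.null(mask)) NULL else mask[ri, ci, drop = FALSE],
        row0 = r0, col0 = c0)
    }
  }
  tiles
}

unet_layer_channels <- function(depth, base) {
  f <- base * 2^(seq_len(depth) - 1L)
  list(enc = f, bot = base * 2^depth)
}

#' Build an untrained segmentation network
#'
#' Contracting path of `depth` levels (two 3x3 convolutions + ReLU, then 2x2
#' max pooling per level), a two-convolution bottleneck, an expanding path
#' with nearest-neighbour upsampling, channel-halving convolution and skip
#' concatenation, and a final 1x1 projection producing per-pixel logits
#' (probabilities after the sigmoid).
#'
#' @param config a [seg_config()].
#' @return an object of class `seg_model` holding the parameter list.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "seg_config"))
  ch <- unet_layer_channels(config$depth, config$base_filters)
  set.seed(config$seed)
  p <- list()
  cin <- 1L
  for (l in seq_len(config$depth)) {
    f <- ch$enc[l]
    p[[paste0("enc", l, "a")]] <- nn_conv_init(3L, cin, f)
    p[[paste0("enc", l, "b")]] <- nn_conv_init(3L, f, f)
    cin <- f
  }
  p$bot_a <- nn_conv_init(3L, cin, ch$bot)
  p$bot_b <- nn_conv_init(3L, ch$bot, ch$bot)
  above <- ch$bot
  for (l in rev(seq_len(config$depth))) {
    f <- ch$enc[l]
    p[[paste0("up", l)]] <- nn_conv_init(3L, above, f)
    p[[paste0("dec", l, "a")]] <- nn_conv_init(3L, 2L * f, f)
    p[[paste0("dec", l, "b")]] <- nn_conv_init(3L, f, f)
    above <- f
  }
  p$out <- nn_conv_init(1L, ch$enc[1], 1L)
  structure(list(params = p, config = config, trained = FALSE),
            class = "seg_model")
}

concat_c <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
}

# forward pass; with keep_cache the im2col matrices are retained so the
# backward pass avoids rebuilding them
unet_forward <- function(params, x, depth, keep_cache = FALSE) {
  cf <- function(a, p) {
    if (keep_cache) {
      r <- .cm_conv2d_fwd_col(as_cube(a), p$w, p$b, p$k)
      list(y = relu(r$y), col = r$col)
    } else list(y = relu(conv_fwd(a, p)), col = NULL)
  }
  a <- as_cube(x)
  cache <- if (keep_cache) list() else NULL
  skips <- vector("list", depth)
  for (l in seq_len(depth)) {
    r1 <- cf(a, params[[paste0("enc", l, "a")]])
    r2 <- cf(r1$y, params[[paste0("enc", l, "b")]])
    mp <- .cm_maxpool_fwd(r2$y)
    skips[[l]] <- r2$y
    if (keep_cache) cache[[paste0("e", l)]] <- list(c1 = r1$y, c2 = r2$y,
                                                    col1 = r1$col, col2 = r2$col,
                                                    idx = mp$idx)
    a <- mp$y
  }
  r1 <- cf(a, params$bot_a)
  r2 <- cf(r1$y, params$bot_b)
  if (keep_cache) cache$bot <- list(b1 = r1$y, b2 = r2$y, col1 = r1$col,
                                    col2 = r2$col)
  a <- r2$y
  for (l in rev(seq_len(depth))) {
    u <- .cm_upsample_fwd(a)
    ru <- cf(u, params[[paste0("up", l)]])
    cat_in <- concat_c(ru$y, skips[[l]])
    r1 <- cf(cat_in, params[[paste0("dec", l, "a")]])
    r2 <- cf(r1$y, params[[paste0("dec", l, "b")]])
    if (keep_cache) cache[[paste0("d", l)]] <- list(uc = ru$y, d1 = r1$y,
                                                    d2 = r2$y, colu = ru$col,
                                                    col1 = r1$col, col2 = r2$col)
    a <- r2$y
  }
  if (keep_cache) {
    rz <- .cm_conv2d_fwd_col(a, params$out$w, params$out$b, 1L)
    cache$head_col <- rz$col
    cache$head_in_dim <- dim(a)
    z <- rz$y
  } else z <- conv_fwd(a, params$out)
  list(z = z, cache = cache)
}

conv_bwd_cached <- function(col, p, gout) {
  g <- as_cube(gout)
  cin <- nrow(p$w) / (p$k * p$k)
  .cm_conv2d_bwd_col(col, p$w, g, dim(g)[1], dim(g)[2], cin, p$k)
}

unet_backward <- function(params, cache, gz, depth) {
  grads <- list()
  g <- as_cube(gz)
  cin <- nrow(params$out$w)
  bw <- .cm_conv2d_bwd_col(cache$head_col, params$out$w, g,
                           cache$head_in_dim[1], cache$head_in_dim[2], cin, 1L)
  grads$out <- list(w = bw$gw, b = bw$gb)
  g <- bw$gx
  gskips <- vector("list", depth)
  for (l in seq_len(depth)) {
    cc <- cache[[paste0("d", l)]]
    f <- dim(cc$uc)[3]
    g <- relu_bwd(g, cc$d2)
    bw <- conv_bwd_cached(cc$col2, params[[paste0("dec", l, "b")]], g)
    grads[[paste0("dec", l, "b")]] <- list(w = bw$gw, b = bw$gb)
    g <- relu_bwd(bw$gx, cc$d1)
    bw <- conv_bwd_cached(cc$col1, params[[paste0("dec", l, "a")]], g)
    grads[[paste0("dec", l, "a")]] <- list(w = bw$gw, b = bw$gb)
    gcat <- bw$gx
    guc <- gcat[, , seq_len(f), drop = FALSE]
    gskips[[l]] <- gcat[, , f + seq_len(f), drop = FALSE]
    guc <- relu_bwd(guc, cc$uc)
    bw <- conv_bwd_cached(cc$colu, params[[paste0("up", l)]], guc)
    grads[[paste0("up", l)]] <- list(w = bw$gw, b = bw$gb)
    g <- .cm_upsample_bwd(bw$gx)
  }
  cb <- cache$bot
  g <- relu_bwd(g, cb$b2)
  bw <- conv_bwd_cached(cb$col2, params$bot_b, g)
  grads$bot_b <- list(w = bw$gw, b = bw$gb)
  g <- relu_bwd(bw$gx, cb$b1)
  bw <- conv_bwd_cached(cb$col1, params$bot_a, g)
  grads$bot_a <- list(w = bw$gw, b = bw$gb)
  g <- bw$gx
  for (l in rev(seq_len(depth))) {
    ce <- cache[[paste0("e", l)]]
    g <- .cm_maxpool_bwd(ce$idx, g, dim(ce$c2)[1], dim(ce$c2)[2]) + gskips[[l]]
    g <- relu_bwd(g, ce$c2)
    bw <- conv_bwd_cached(ce$col2, params[[paste0("enc", l, "b")]], g)
    grads[[paste0("enc", l, "b")]] <- list(w = bw$gw, b = bw$gb)
    g <- relu_bwd(bw$gx, ce$c1)
    bw <- conv_bwd_cached(ce$col1, params[[paste0("enc", l, "a")]], g)
    grads[[paste0("enc", l, "a")]] <- list(w = bw$gw, b = bw$gb)
    g <- bw$gx
  }
  grads
}

#' Train the segmentation network
#'
#' Stochastic gradient training with Adam, one tile per step, pixelwise mean
#' binary cross-entropy loss. Accuracy is the fraction of pixels where the
#' thresholded prediction matches the mask. Stops early once the epoch mean
#' loss drops below `config$stop_loss`.
#'
#' @param model a `seg_model` from [build_unet()].
#' @param tiles list of tiles from [crop_tiles()] (with masks).
#' @param config a [seg_config()]; defaults to the model's own.
#' @return the trained `seg_model`, with a `history` data frame
#'   (epoch, loss, accuracy) attached.
#' @export
train_seg <- function(model, tiles, config = model$config) {
  stopifnot(inherits(model, "seg_model"))
  if (length(tiles) == 0) stop("no training tiles supplied")
  if (any(vapply(tiles, function(t) is.null(t$mask), logical(1))))
    stop("every training tile needs a mask")
  params <- model$params
  state <- adam_init(params)
  set.seed(config$seed + 1L)
  hist <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(tiles))
    losses <- accs <- numeric(length(tiles))
    for (i in seq_along(ord)) {
      tl <- tiles[[ord[i]]]
      fwd <- unet_forward(params, tl$image, config$depth, keep_cache = TRUE)
      y <- as_cube(tl$mask * 1.0)
      lg <- bce_with_logits(fwd$z, y)
      losses[i] <- lg$loss
      accs[i] <- mean((fwd$z > 0) == (y > 0.5))
      grads <- unet_backward(params, fwd$cache, lg$grad, config$depth)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   accuracy = mean(accs)))
    if (config$stop_loss > 0 && mean(losses) < config$stop_loss) break
  }
  model$params <- params
  model$trained <- TRUE
  model$history <- hist
  model$config <- config
  model
}

#' Predict a full-image binary mask
#'
#' The image is tiled on the same edge-aligned grid as [crop_tiles()];
#' per-tile sigmoid probabilities are averaged where tiles overlap, then
#' thresholded.
#'
#' @param model a trained `seg_model`.
#' @param image numeric matrix or `section_image`.
#' @param config a [seg_config()]; defaults to the model's own.
#' @param stride tiling stride; defaults to the tile size.
#' @return binary integer matrix of the image's shape.
#' @export
predict_mask <- function(model, image, config = model$config,
                         stride = config$tile_size) {
  img <- if (inherits(image, "section_image")) image$pixels else image
  prob <- predict_prob(model, img, config, stride)
  (prob > config$threshold) * 1L
}

predict_prob <- function(model, img, config = model$config,
                         stride = config$tile_size) {
  tiles <- crop_tiles(img, NULL, config$tile_size, stride)
  acc <- matrix(0, nrow(img), ncol(img))
  cnt <- matrix(0, nrow(img), ncol(img))
  for (tl in tiles) {
    fwd <- unet_forward(model$params, tl$image, config$depth)
    p <- sigmoid(fwd$z[, , 1])
    ri <- tl$row0 + seq_len(config$tile_size)
    ci <- tl$col0 + seq_len(config$tile_size)
    acc[ri, ci] <- acc[ri, ci] + p
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  acc / cnt
}

#' Evaluate a predicted mask against instance ground truth
#'
#' @param pred binary matrix (prediction).
#' @param truth a `ground_truth` object or an integer instance-label matrix
#'   (0 = background).
#' @param min_overlap_px a predicted component counts as touching a truth
#'   instance only when they share at least this many pixels; components
#'   touching two or more instances are connection (merge) errors.
#' @return list with `pixel_accuracy`, `connection_errors`, `missed`.
#' @export
evaluate_seg <- function(pred, truth, min_overlap_px = 10L) {
  inst <- if (inherits(truth, "ground_truth")) truth$instance_mask else truth
  if (!all(dim(pred) == dim(inst))) stop("prediction and truth shapes differ")
  truth_bin <- (inst > 0) * 1L
  pixel_accuracy <- mean((pred > 0) == (truth_bin > 0))
  pred_lab <- label_components((pred > 0) * 1L, connectivity = 8L)
  both <- pred_lab > 0 & inst > 0
  connection_errors <- 0L
  if (any(both)) {
    tab <- table(pred = pred_lab[both], inst = inst[both])
    connection_errors <- sum(rowSums(tab >= min_overlap_px) >= 2)
  }
  n_inst <- max(inst)
  covered <- if (any(both)) unique(inst[both]) else integer(0)
  missed <- n_inst - length(covered)
  list(pixel_accuracy = pixel_accuracy,
       connection_errors = as.integer(connection_errors),
       missed = as.integer(missed))
}

#' Save / load a segmentation or VAE model checkpoint
#' @param model model object.
#' @param path file path.
#' @return `load_model` returns the model object.
#' @export
save_model <- function(model, path) saveRDS(model, path)

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Write a training history as CSV (epoch, loss, accuracy)
#' @param model trained model with a `history` element.
#' @param path output CSV path.
#' @export
write_history_csv <- function(model, path) {
  write.csv(model$history, path, row.names = FALSE)
}
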