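# Convolutional variational autoencoder over extracted bundle images, and
# latent-space morphing along the radial axis. The encoder maps an image to
# the mean and log-variance of a diagonal Gaussian posterior; training uses
# the reparameterization trick with summed per-pixel binary cross-entropy
# reconstruction loss plus beta * KL(q || N(0, I)). Morphing encodes anchor
# bundles to their posterior means (no sampling, so paths are
# deterministic) and decodes a piecewise-linear latent path.

#' VAE configuration
#'
#' Desk defaults (64-px inputs, 32 latent dimensions, 60 epochs) train in a
#' few minutes on one CPU; the full scale used on real data in the field
#' (256-px inputs, 200 latent dimensions, thousands of epochs) is the same
#' architecture scaled up.
#'
#' @param input_size square input side, a power of two >= 16.
#' @param latent_dim latent dimensionality (>= 2).
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param beta KL weight.
#' @param seed integer seed for initialization and sampling.
#' @return object of class `vae_config`.
#' @export
vae_config <- function(input_size = 64L, latent_dim = 32L, epochs = 60L,
                       learning_rate = 1e-3, beta = 1, seed = 1L) {
  if (bitwAnd(input_size, input_size - 1L) != 0 || input_size < 16)
    stop("input_size must be a power of two >= 16")
  if (latent_dim < 2) stop("latent_dim must be >= 2")
  structure(list(input_size = as.integer(input_size),
                 latent_dim = as.integer(latent_dim),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 beta = beta, seed = as.integer(seed)),
            class = "vae_config")
}

vae_channels <- c(8L, 16L, 32L)

#' Build an untrained VAE
#' @param config a [vae_config()].
#' @return object of class `vae_model`.
#' @export
build_vae <- function(config) {
  stopifnot(inherits(config, "vae_config"))
  set.seed(config$seed)
  ch <- vae_channels
  s <- config$input_size / 8L          # spatial side after 3 poolings
  flat <- s * s * ch[3]
  hid <- 128L
  p <- list(
    e1 = nn_conv_init(3L, 1L, ch[1]),
    e2 = nn_conv_init(3L, ch[1], ch[2]),
    e3 = nn_conv_init(3L, ch[2], ch[3]),
    efc = nn_dense_init(flat, hid),
    mu = nn_dense_init(hid, config$latent_dim),
    lv = nn_dense_init(hid, config$latent_dim),
    dfc1 = nn_dense_init(config$latent_dim, hid),
    dfc2 = nn_dense_init(hid, flat),
    d3 = nn_conv_init(3L, ch[3], ch[2]),
    d2 = nn_conv_init(3L, ch[2], ch[1]),
    d1 = nn_conv_init(3L, ch[1], ch[1]),
    out = nn_conv_init(1L, ch[1], 1L)
  )
  structure(list(params = p, config = config, trained = FALSE,
                 spatial = as.integer(s)),
            class = "vae_model")
}

dense_fwd <- function(x, p) as.vector(x %*% p$w) + p$b

vae_encode_fwd <- function(params, x, keep_cache = FALSE) {
  cf <- function(a, p) {
    if (keep_cache) {
      r <- .cm_conv2d_fwd_col(as_cube(a), p$w, p$b, p$k)
      list(y = relu(r$y), col = r$col)
    } else list(y = relu(conv_fwd(a, p)), col = NULL)
  }
  a0 <- as_cube(x)
  r1 <- cf(a0, params$e1); m1 <- .cm_maxpool_fwd(r1$y)
  r2 <- cf(m1$y, params$e2); m2 <- .cm_maxpool_fwd(r2$y)
  r3 <- cf(m2$y, params$e3); m3 <- .cm_maxpool_fwd(r3$y)
  flat <- matrix(as.vector(m3$y), 1)
  h <- relu(matrix(dense_fwd(flat, params$efc), 1))
  mu <- dense_fwd(h, params$mu)
  lv <- dense_fwd(h, params$lv)
  cache <- if (keep_cache)
    list(c1 = r1$y, c2 = r2$y, c3 = r3$y, col1 = r1$col, col2 = r2$col,
         col3 = r3$col, m1 = m1, m2 = m2, m3 = m3, flat = flat, h = h)
  list(mu = mu, lv = lv, cache = cache)
}

vae_decode_fwd <- function(params, z, spatial, keep_cache = FALSE) {
  cf <- function(a, p) {
    if (keep_cache) {
      r <- .cm_conv2d_fwd_col(as_cube(a), p$w, p$b, p$k)
      list(y = relu(r$y), col = r$col)
    } else list(y = relu(conv_fwd(a, p)), col = NULL)
  }
  zr <- matrix(z, 1)
  h1 <- relu(matrix(dense_fwd(zr, params$dfc1), 1))
  h2 <- relu(matrix(dense_fwd(h1, params$dfc2), 1))
  g <- array(as.vector(h2), dim = c(spatial, spatial, vae_channels[3]))
  u3 <- .cm_upsample_fwd(g); r3 <- cf(u3, params$d3)
  u2 <- .cm_upsample_fwd(r3$y); r2 <- cf(u2, params$d2)
  u1 <- .cm_upsample_fwd(r2$y); r1 <- cf(u1, params$d1)
  if (keep_cache) {
    rz <- .cm_conv2d_fwd_col(r1$y, params$out$w, params$out$b, 1L)
    zlog <- rz$y
  } else zlog <- conv_fwd(r1$y, params$out)
  cache <- if (keep_cache)
    list(zr = zr, h1 = h1, h2 = h2, d3 = r3$y, d2 = r2$y, d1 = r1$y,
         col3 = r3$col, col2 = r2$col, col1 = r1$col, colz = rz$col,
         d1_dim = dim(r1$y))
  list(logits = zlog, cache = cache)
}

vae_decode_bwd <- function(params, cache, glog) {
  grads <- list()
  bw <- .cm_conv2d_bwd_col(cache$colz, params$out$w, as_cube(glog),
                           cache$d1_dim[1], cache$d1_dim[2],
                           nrow(params$out$w), 1L)
  grads$out <- list(w = bw$gw, b = bw$gb)
  g <- relu_bwd(bw$gx, cache$d1)
  bw <- conv_bwd_cached(cache$col1, params$d1, g)
  grads$d1 <- list(w = bw$gw, b = bw$gb)
  g <- .cm_upsample_bwd(bw$gx)
  g <- relu_bwd(g, cache$d2)
  bw <- conv_bwd_cached(cache$col2, params$d2, g)
  grads$d2 <- list(w = bw$gw, b = bw$gb)
  g <- .cm_upsample_bwd(bw$gx)
  g <- relu_bwd(g, cache$d3)
  bw <- conv_bwd_cached(cache$col3, params$d3, g)
  grads$d3 <- list(w = bw$gw, b = bw$gb)
  g <- .cm_upsample_bwd(bw$gx)
  gflat <- matrix(as.vector(g), 1)
  gflat <- relu_bwd(gflat, cache$h2)
  grads$dfc2 <- list(w = t(cache$h1) %*% gflat, b = as.vector(gflat))
  g <- gflat %*% t(params$dfc2$w)
  g <- relu_bwd(g, cache$h1)
  grads$dfc1 <- list(w = t(cache$zr) %*% g, b = as.vector(g))
  gz <- as.vector(g %*% t(params$dfc1$w))
  list(grads = grads, gz = gz)
}

vae_encode_bwd <- function(params, cache, gmu, glv) {
  grads <- list()
  grads$mu <- list(w = t(cache$h) %*% matrix(gmu, 1), b = gmu)
  grads$lv <- list(w = t(cache$h) %*% matrix(glv, 1), b = glv)
  gh <- matrix(gmu, 1) %*% t(params$mu$w) + matrix(glv, 1) %*% t(params$lv$w)
  gh <- relu_bwd(gh, cache$h)
  grads$efc <- list(w = t(cache$flat) %*% gh, b = as.vector(gh))
  gflat <- gh %*% t(params$efc$w)
  g <- array(as.vector(gflat), dim = dim(cache$m3$y))
  g <- .cm_maxpool_bwd(cache$m3$idx, g, dim(cache$c3)[1], dim(cache$c3)[2])
  g <- relu_bwd(g, cache$c3)
  bw <- conv_bwd_cached(cache$col3, params$e3, g)
  grads$e3 <- list(w = bw$gw, b = bw$gb)
  g <- .cm_maxpool_bwd(cache$m2$idx, bw$gx, dim(cache$c2)[1], dim(cache$c2)[2])
  g <- relu_bwd(g, cache$c2)
  bw <- conv_bwd_cached(cache$col2, params$e2, g)
  grads$e2 <- list(w = bw$gw, b = bw$gb)
  g <- .cm_maxpool_bwd(cache$m1$idx, bw$gx, dim(cache$c1)[1], dim(cache$c1)[2])
  g <- relu_bwd(g, cache$c1)
  bw <- conv_bwd_cached(cache$col1, params$e1, g)
  grads$e1 <- list(w = bw$gw, b = bw$gb)
  grads
}

#' Train the VAE
#'
#' One image per Adam step. The loss per image is the summed per-pixel
#' binary cross-entropy of the reconstruction plus `beta` times the KL
#' divergence of the diagonal-Gaussian posterior from N(0, I).
#'
#' @param images list of numeric matrices in \[0,1\], or a 3-d array with
#'   images along the third dimension; all of side `config$input_size`.
#' @param config a [vae_config()].
#' @return trained `vae_model` with a `history` data frame (epoch, loss,
#'   recon, kl).
#' @export
train_vae <- function(images, config = vae_config()) {
  if (is.array(images) && length(dim(images)) == 3)
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  if (length(images) < 2) stop("need at least 2 training images")
  if (!all(vapply(images, function(m) all(dim(m) == config$input_size),
                  logical(1))))
    stop("all images must be ", config$input_size, "x", config$input_size)
  model <- build_vae(config)
  params <- model$params
  state <- adam_init(params)
  set.seed(config$seed + 1L)
  hist <- data.frame(epoch = integer(), loss = numeric(), recon = numeric(),
                     kl = numeric())
  npx <- config$input_size^2
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(images))
    rl <- kl <- numeric(length(images))
    for (ii in seq_along(ord)) {
      x <- images[[ord[ii]]]
      enc <- vae_encode_fwd(params, x, keep_cache = TRUE)
      eps <- rnorm(config$latent_dim)
      zlat <- enc$mu + eps * exp(0.5 * enc$lv)
      dec <- vae_decode_fwd(params, zlat, model$spatial, keep_cache = TRUE)
      y <- as_cube(x)
      lg <- bce_with_logits(dec$logits, y)
      recon <- lg$loss * npx                 # summed BCE
      kld <- -0.5 * sum(1 + enc$lv - enc$mu^2 - exp(enc$lv))
      rl[ii] <- recon; kl[ii] <- kld
      glog <- lg$grad * npx
      dbw <- vae_decode_bwd(params, dec$cache, glog)
      gmu <- dbw$gz + config$beta * enc$mu
      glv <- dbw$gz * eps * 0.5 * exp(0.5 * enc$lv) +
        config$beta * 0.5 * (exp(enc$lv) - 1)
      ebw <- vae_encode_bwd(params, enc$cache, gmu, glv)
      grads <- c(dbw$grads, ebw)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
    }
    hist <- rbind(hist, data.frame(epoch = ep,
                                   loss = mean(rl + config$beta * kl),
                                   recon = mean(rl), kl = mean(kl)))
  }
  model$params <- params
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Encode an image to its posterior mean latent vector
#' @param model a `vae_model`.
#' @param image numeric matrix of the model's input size.
#' @return numeric latent vector.
#' @export
vae_encode <- function(model, image) {
  vae_encode_fwd(model$params, image)$mu
}

#' Decode a latent vector to a probability image
#' @param model a `vae_model`.
#' @param z latent vector.
#' @return numeric matrix in (0,1).
#' @export
vae_decode <- function(model, z) {
  sigmoid(vae_decode_fwd(model$params, z, model$spatial)$logits[, , 1])
}

# bilinear resize of a matrix to size x size (pixel-center alignment)
resize_bilinear <- function(m, size) {
  H <- nrow(m); W <- ncol(m)
  map <- function(n_src, n_dst) {
    x <- (seq_len(n_dst) - 0.5) / n_dst * n_src + 0.5
    x <- pmin(pmax(x, 1), n_src)
    i0 <- pmin(floor(x), n_src - 1L)
    list(i0 = i0, f = x - i0)
  }
  rm_ <- map(H, size); cm_ <- map(W, size)
  a <- m[rm_$i0, cm_$i0, drop = FALSE]
  b <- m[rm_$i0 + 1L, cm_$i0, drop = FALSE]
  d <- m[rm_$i0, cm_$i0 + 1L, drop = FALSE]
  e <- m[rm_$i0 + 1L, cm_$i0 + 1L, drop = FALSE]
  fr <- matrix(rm_$f, size, size)
  fc <- matrix(cm_$f, size, size, byrow = TRUE)
  a * (1 - fr) * (1 - fc) + b * fr * (1 - fc) + d * (1 - fr) * fc + e * fr * fc
}

#' Extract per-bundle images for VAE training
#'
#' Each bundle's binary mask is cropped, centered on a square canvas (so
#' the shape's aspect is preserved) and rescaled to `size` x `size` by
#' bilinear resampling (values stay in \[0,1\]). Border-touching bundles
#' are skipped.
#'
#' @param labels instance label matrix.
#' @param records data frame from [measure_bundles()].
#' @param size output side (default 64).
#' @param margin fractional margin around the shape (default 0.1).
#' @return list with `images` (list of size x size binary matrices) and
#'   `records` (the rows used, aligned with `images`).
#' @export
extract_bundle_images <- function(labels, records, size = 64L, margin = 0.1) {
  keep <- !records$touches_border
  records <- records[keep, , drop = FALSE]
  imgs <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    rr <- (rec$bbox_min_row + 1):rec$bbox_max_row
    cc <- (rec$bbox_min_col + 1):rec$bbox_max_col
    crop <- (labels[rr, cc, drop = FALSE] == rec$label) * 1
    side <- ceiling(max(dim(crop)) * (1 + 2 * margin))
    canvas <- matrix(0, side, side)
    r0 <- floor((side - nrow(crop)) / 2)
    c0 <- floor((side - ncol(crop)) / 2)
    canvas[r0 + seq_len(nrow(crop)), c0 + seq_len(ncol(crop))] <- crop
    imgs[[i]] <- resize_bilinear(canvas, size)
  }
  list(images = imgs, records = records)
}

#' Pick anchor bundles nearest to target radial positions
#'
#' For each target position the extracted bundle whose relative position is
#' nearest is selected (the default targets are the radial stations used
#' for latent-space morphing: 0.01, 0.09, 0.40, 0.71, 1.00).
#'
#' @param extraction output of [extract_bundle_images()] run on records
#'   that carry `relative_position`.
#' @param targets increasing target positions.
#' @return list with `images`, `positions` (the selected bundles' actual
#'   positions) and `targets`.
#' @export
select_anchors <- function(extraction, targets = c(0.01, 0.09, 0.40, 0.71, 1.00)) {
  p <- extraction$records$relative_position
  idx <- vapply(targets, function(t) which.min(abs(p - t)), integer(1))
  list(images = extraction$images[idx], positions = p[idx], targets = targets)
}

#' Morph along a latent path through anchor bundles
#'
#' Anchors are encoded to their posterior means; the path interpolates
#' linearly between consecutive anchors and decodes every point. The first
#' and last frames equal the decoded anchor means.
#'
#' @param model trained `vae_model`.
#' @param anchor_images list of anchor images (model input size), ordered
#'   by radial position.
#' @param positions strictly increasing relative positions of the anchors
#'   (defaults evenly spaced when `NULL`).
#' @param frames_per_segment interpolation steps per segment (default 20);
#'   total frames = segments * frames_per_segment + 1.
#' @return object of class `latent_path`: `latents` (frames x latent_dim),
#'   `frames` (list of decoded images), `anchor_latents`, `positions`,
#'   `frame_positions`.
#' @export
morph <- function(model, anchor_images, positions = NULL,
                  frames_per_segment = 20L) {
  n <- length(anchor_images)
  if (n < 2) stop("need at least 2 anchors")
  if (is.null(positions)) positions <- seq(0, 1, length.out = n)
  if (any(diff(positions) <= 0))
    stop("anchor positions must be strictly increasing (no duplicates)")
  mus <- t(vapply(anchor_images, function(im) vae_encode(model, im),
                  numeric(model$config$latent_dim)))
  lat <- list(); fpos <- numeric(0)
  for (s in seq_len(n - 1)) {
    ts <- seq(0, 1, length.out = frames_per_segment + 1L)
    if (s > 1) ts <- ts[-1]
    for (t in ts) {
      lat[[length(lat) + 1L]] <- (1 - t) * mus[s, ] + t * mus[s + 1, ]
      fpos <- c(fpos, (1 - t) * positions[s] + t * positions[s + 1])
    }
  }
  lat <- do.call(rbind, lat)
  frames <- lapply(seq_len(nrow(lat)), function(i) vae_decode(model, lat[i, ]))
  structure(list(latents = lat, frames = frames, anchor_latents = mus,
                 positions = positions, frame_positions = fpos,
                 frames_per_segment = as.integer(frames_per_segment)),
            class = "latent_path")
}

#' Write morph frames as numbered PNGs
#' @param path_obj a `latent_path`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the written paths.
#' @export
write_frames_png <- function(path_obj, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(path_obj$frames))
  for (i in seq_along(path_obj$frames)) {
    paths[i] <- file.path(dir, sprintf("%s_%04d.png", prefix, i))
    f <- path_obj$frames[[i]]
    f[] <- pmin(1, pmax(0, f))
    png::writePNG(f, paths[i])
  }
  invisible(paths)
}

#' Export latent vectors as CSV
#' @param path_obj a `latent_path`.
#' @param path output CSV path.
#' @export
write_latents_csv <- function(path_obj, path) {
  df <- as.data.frame(path_obj$latents)
  names(df) <- paste0("z", seq_len(ncol(df)))
  df <- cbind(data.frame(frame = seq_len(nrow(df)),
                         p = path_obj$frame_positions), df)
  write.csv(df, path, row.names = FALSE)
}
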