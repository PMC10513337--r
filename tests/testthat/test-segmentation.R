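test_that("tile cropping covers images edge-aligned without padding", {
  img <- matrix(runif(512 * 512), 512, 512)
  expect_length(crop_tiles(img, NULL, 512L), 1)
  wide <- matrix(runif(512 * 1024), 512, 1024)
  expect_length(crop_tiles(wide, NULL, 512L), 2)
  odd <- matrix(runif(700 * 700), 700, 700)
  tl <- crop_tiles(odd, NULL, 512L)
  expect_length(tl, 4)
  for (t in tl) {
    expect_equal(dim(t$image), c(512, 512))
    expect_lte(t$row0 + 512, 700)
    expect_lte(t$col0 + 512, 700)
  }
  expect_error(crop_tiles(matrix(0, 100, 100), NULL, 512L), "smaller")
  expect_error(crop_tiles(img, matrix(0, 2, 2), 512L), "differ")
})

test_that("the network has the documented shape, range and parameter count", {
  cfg <- seg_config(tile_size = 32L, depth = 3L, base_filters = 16L, seed = 2L)
  m <- build_unet(cfg)
  x <- matrix(runif(32 * 32), 32, 32)
  f <- culmorph:::unet_forward(m$params, x, cfg$depth)
  expect_equal(dim(f$z), c(32, 32, 1))
  p <- culmorph:::sigmoid(f$z)
  expect_true(all(p > 0 & p < 1))
  # independent layer-by-layer parameter accounting
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  expected <- 0
  cin <- 1
  fts <- 16 * 2^(0:2)
  for (fl in fts) {
    expected <- expected + conv_n(3, cin, fl) + conv_n(3, fl, fl)
    cin <- fl
  }
  expected <- expected + conv_n(3, 64, 128) + conv_n(3, 128, 128)
  above <- 128
  for (fl in rev(fts)) {
    expected <- expected + conv_n(3, above, fl) + conv_n(3, 2 * fl, fl) +
      conv_n(3, fl, fl)
    above <- fl
  }
  expected <- expected + conv_n(1, 16, 1)
  expect_equal(culmorph:::n_params(m$params), expected)
  expect_equal(expected, 535505)
  # seeding contract: identical initial weights
  m2 <- build_unet(cfg)
  expect_identical(m$params, m2$params)
  expect_error(seg_config(tile_size = 100L, depth = 3L), "divisible")
  expect_error(seg_config(threshold = 1.2), "threshold")
})

test_that("analytic gradients match central differences", {
  set.seed(7)
  cfg <- seg_config(tile_size = 8L, depth = 2L, base_filters = 2L, seed = 3L)
  m <- build_unet(cfg)
  # move biases off zero so no ReLU sits at its kink and pools rarely tie
  for (nm in names(m$params))
    m$params[[nm]]$b <- rnorm(length(m$params[[nm]]$b), 0, 0.3)
  x <- matrix(runif(64), 8, 8)
  y <- array(rbinom(64, 1, 0.5), c(8, 8, 1))
  loss_fn <- function(params) {
    f <- culmorph:::unet_forward(params, x, 2L)
    culmorph:::bce_with_logits(f$z, y)$loss
  }
  f <- culmorph:::unet_forward(m$params, x, 2L, keep_cache = TRUE)
  lg <- culmorph:::bce_with_logits(f$z, y)
  gr <- culmorph:::unet_backward(m$params, f$cache, lg$grad, 2L)
  h <- 1e-5
  for (nm in names(m$params)) for (slot in c("w", "b")) {
    pv <- m$params[[nm]][[slot]]
    for (i in sample(length(pv), min(length(pv), 4))) {
      pp <- m$params; pp[[nm]][[slot]][i] <- pp[[nm]][[slot]][i] + h
      pm <- m$params; pm[[nm]][[slot]][i] <- pm[[nm]][[slot]][i] - h
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
      an <- gr[[nm]][[slot]][i]
      expect_lt(abs(num - an) / max(1e-8, abs(num) + abs(an)), 1e-4)
    }
  }
})

test_that("training overfits a single clean tile and logs its history", {
  sec <- generate_section(make_archetype(32, overrides = list(
    wall_thickness_px = 80L, tangential_width_px = 128L)), seed = 5)
  cfg <- seg_config(tile_size = 64L, depth = 2L, base_filters = 8L,
                    epochs = 200L, seed = 1L, stop_loss = 0.01)
  tiles <- crop_tiles(sec$image, (sec$truth$instance_mask > 0) * 1L, 64L)[1]
  m <- train_seg(build_unet(cfg), tiles, cfg)
  expect_gt(max(m$history$accuracy), 0.99)
  expect_lte(min(m$history$loss), m$history$loss[1])
  expect_error(train_seg(build_unet(cfg), list(), cfg), "tiles")
  # trained-model sanity: an all-background image predicts almost no bundle
  bg <- matrix(0.72, 64, 64) + matrix(rnorm(64 * 64, 0, 0.05), 64)
  pred <- predict_mask(m, bg)
  expect_lt(mean(pred), 0.01)
  td <- withr::local_tempdir()
  write_history_csv(m, file.path(td, "h.csv"))
  h <- read.csv(file.path(td, "h.csv"))
  expect_equal(names(h), c("epoch", "loss", "accuracy"))
  ck <- file.path(td, "m.rds")
  save_model(m, ck)
  m2 <- load_model(ck)
  expect_identical(m2$params, m$params)
})

test_that("stitched prediction averages overlaps consistently", {
  cfg <- seg_config(tile_size = 64L, depth = 2L, base_filters = 4L, seed = 4L)
  m <- build_unet(cfg)
  set.seed(2)
  img <- matrix(runif(64 * 96), 64, 96)
  p <- culmorph:::predict_prob(m, img, cfg, stride = 32L)
  tile_prob <- function(cols) {
    f <- culmorph:::unet_forward(m$params, img[, cols], cfg$depth)
    culmorph:::sigmoid(f$z[, , 1])
  }
  t1 <- tile_prob(1:64); t2 <- tile_prob(33:96)
  expect_equal(p[, 1:32], t1[, 1:32])
  expect_equal(p[, 65:96], t2[, 33:64])
  expect_equal(p[, 33:64], (t1[, 33:64] + t2[, 1:32]) / 2)
  expect_equal(dim(predict_mask(m, img, cfg)), dim(img))
  expect_true(all(predict_mask(m, img, cfg) %in% c(0L, 1L)))
})

test_that("evaluation counts accuracy, merge errors and missed instances", {
  inst <- matrix(0L, 40, 40)
  inst[5:12, 5:12] <- 1L
  inst[5:12, 20:27] <- 2L
  inst[30:36, 8:20] <- 3L
  perfect <- (inst > 0) * 1L
  ev <- evaluate_seg(perfect, inst)
  expect_equal(ev$pixel_accuracy, 1)
  expect_equal(ev$connection_errors, 0)
  expect_equal(ev$missed, 0)
  # bridge instances 1 and 2 with a thin line -> one merge error
  bridged <- perfect
  bridged[8, 13:19] <- 1L
  ev2 <- evaluate_seg(bridged, inst, min_overlap_px = 10L)
  expect_equal(ev2$connection_errors, 1)
  # drop instance 3 entirely -> one missed
  partial <- perfect
  partial[30:36, 8:20] <- 0L
  ev3 <- evaluate_seg(partial, inst)
  expect_equal(ev3$missed, 1)
  expect_error(evaluate_seg(matrix(0L, 3, 3), inst), "shapes")
  # accuracy equals 1 - normalized Hamming distance
  set.seed(3)
  rnd <- matrix(rbinom(1600, 1, 0.5), 40, 40)
  ev4 <- evaluate_seg(rnd, inst)
  expect_equal(ev4$pixel_accuracy, 1 - mean(rnd != (inst > 0)))
})

test_that("random predictions on a balanced mask score chance accuracy", {
  set.seed(12)
  mask <- matrix(0L, 128, 128)
  mask[, 1:64] <- 1L   # balanced
  inst <- label_components(mask)
  accs <- replicate(5, {
    rnd <- matrix(rbinom(128 * 128, 1, 0.5), 128, 128)
    evaluate_seg(rnd, inst)$pixel_accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.02)
})
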