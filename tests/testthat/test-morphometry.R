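test_that("connected-component labeling matches connectivity semantics", {
  m <- matrix(0L, 12, 12)
  m[2:6, 2:6] <- 1L
  m[8:12, 8:12] <- 1L
  expect_equal(max(label_components(m, 8)), 2)
  # squares touching only at a corner
  m2 <- matrix(0L, 10, 10)
  m2[1:5, 1:5] <- 1L
  m2[6:10, 6:10] <- 1L
  expect_equal(max(label_components(m2, 8)), 1)
  expect_equal(max(label_components(m2, 4)), 2)
  expect_error(label_components(m2, 6), "connectivity")
})

test_that("labeling agrees with a flood-fill oracle on random masks", {
  for (s in 1:50) {
    set.seed(s)
    m <- matrix(rbinom(25 * 25, 1, 0.35), 25, 25)
    for (conn in c(4L, 8L)) {
      got <- label_components(m, conn)
      ora <- oracle_label(m, conn)
      expect_equal(max(got), max(ora), info = paste("seed", s, "conn", conn))
      # same partition of pixels into components
      expect_equal(got > 0, ora > 0)
      key <- paste(got[got > 0], ora[ora > 0])
      expect_equal(length(unique(key)), max(got))
    }
  }
})

test_that("filled square yields exact textbook descriptors", {
  m <- matrix(0L, 14, 14)
  m[3:12, 3:12] <- 1L
  rec <- measure_region(label_components(m), 1)
  expect_equal(rec$area_px, 100)
  expect_equal(rec$extent, 1.0)
  expect_equal(rec$aspect, 1.0)
  expect_equal(rec$eccentricity, 0.0)
  expect_equal(rec$perimeter_px, 36)      # 8-chain through boundary centers
  expect_equal(rec$convex_area_px, 100)   # hull over pixel corner squares
  expect_equal(rec$centroid_row, mean(2:11))
  expect_false(rec$touches_border)
})

test_that("rasterized ellipse recovers the analytic eccentricity", {
  m <- ellipse_mask(40, 20)  # semi-axes 40 (cols) and 20 (rows)
  rec <- measure_region(label_components(m), 1)
  expect_lt(abs(rec$eccentricity - sqrt(1 - 0.25)), 0.02)
  expect_lt(abs(rec$aspect - 2), 0.1)
  expect_lt(abs(rec$area_px - pi * 40 * 20) / (pi * 800), 0.02)
})

test_that("descriptors match the brute-force oracle on random blobs", {
  for (s in 1:100) {
    m <- random_blob_mask(28, s)
    lab <- label_components(m)
    rec <- measure_region(lab, 1)
    ora <- oracle_measure(lab, 1)
    expect_equal(rec$area_px, ora$area)
    expect_equal(rec$centroid_row, ora$centroid[1])
    expect_equal(rec$centroid_col, ora$centroid[2])
    expect_equal(rec$aspect, ora$aspect)
    expect_equal(rec$extent, ora$extent)
    expect_lt(abs(rec$eccentricity - ora$eccentricity), 0.01)
    expect_lt(abs(rec$convex_area_px - ora$convex_area) /
                max(1, ora$convex_area), 0.01)
    bb <- matrix(0L, rec$bbox_max_row - rec$bbox_min_row,
                 rec$bbox_max_col - rec$bbox_min_col)
    idx <- which(lab == 1, arr.ind = TRUE)
    bb[cbind(idx[, 1] - rec$bbox_min_row, idx[, 2] - rec$bbox_min_col)] <- 1L
    expect_lt(abs(rec$perimeter_px - oracle_chain_perimeter(bb)) /
                oracle_chain_perimeter(bb), 0.02)
  }
})

test_that("chain perimeter is exact on rectangles and near-analytic on discs", {
  m <- matrix(0L, 20, 30)
  m[5:10, 5:24] <- 1L   # 6 x 20 rectangle
  rec <- measure_region(label_components(m), 1)
  expect_equal(rec$perimeter_px, 2 * (6 - 1) + 2 * (20 - 1))
  d <- ellipse_mask(25, 25)
  recd <- measure_region(label_components(d), 1)
  # chain length through boundary centers vs circle circumference (radius
  # reduced by half a pixel); the 8-chain metric inflates smooth boundaries
  # by several percent (digitization bias)
  expect_lt(abs(recd$perimeter_px - 2 * pi * 24.5) / (2 * pi * 24.5), 0.08)
})

test_that("descriptors are scale covariant and rotation aware", {
  # pixel replication: area scales exactly, moment/bbox descriptors are
  # preserved
  for (s in c(3, 11)) {
    m <- random_blob_mask(24, s)
    big <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
    r1 <- measure_region(label_components(m), 1)
    r2 <- measure_region(label_components(big), 1)
    expect_equal(r2$area_px, 4 * r1$area_px)
    expect_lt(abs(r2$eccentricity - r1$eccentricity), 0.02)
    expect_lt(abs(r2$aspect - r1$aspect), 0.02 * max(1, r1$aspect))
    expect_lt(abs(r2$extent - r1$extent), 0.02)
    rot <- t(m)[seq_len(ncol(m)), rev(seq_len(nrow(m))), drop = FALSE]
    r3 <- measure_region(label_components(rot), 1)
    expect_lt(abs(r3$aspect - 1 / r1$aspect), 0.02)
    expect_lt(abs(r3$eccentricity - r1$eccentricity), 0.01)
  }
  # analytic shapes rasterized at both scales: perimeter doubles within 3%
  for (ab in list(c(12, 20), c(18, 9))) {
    p1 <- measure_region(label_components(ellipse_mask(ab[1], ab[2])), 1)$perimeter_px
    p2 <- measure_region(label_components(ellipse_mask(2 * ab[1], 2 * ab[2])), 1)$perimeter_px
    expect_lt(abs(p2 / p1 - 2), 2 * 0.03)
  }
})

test_that("extent and convexity invariants hold across random blobs", {
  for (s in 21:40) {
    rec <- measure_region(label_components(random_blob_mask(26, s)), 1)
    expect_lte(rec$extent, 1)
    expect_gte(rec$convex_area_px, rec$area_px - 1e-9)
  }
})

test_that("eccentricity matches an independent moment implementation", {
  skip_if_not_installed("EBImage")
  for (s in c(2, 9, 17)) {
    m <- random_blob_mask(30, s)
    rec <- measure_region(label_components(m), 1)
    ft <- EBImage::computeFeatures.moment(t(m))  # EBImage is x-y transposed
    expect_lt(abs(rec$eccentricity - ft[1, "m.eccentricity"]), 0.01)
  }
})

test_that("relative position maps and clamps the radial coordinate", {
  fr <- tissue_frame(10, 110)
  expect_equal(relative_position(10, fr), 0)
  expect_equal(relative_position(60, fr), 0.5)
  expect_equal(relative_position(112, fr), 1)   # clamped beyond the pith
  expect_equal(relative_position(4, fr), 0)     # clamped above the epidermis
  expect_error(tissue_frame(50, 50), "degenerate")
})

test_that("measure_bundles returns one aligned row per instance", {
  m <- matrix(0L, 30, 30)
  m[2:6, 2:8] <- 1L
  m[20:28, 15:22] <- 1L
  lab <- label_components(m)
  fr <- tissue_frame(0, 30)
  rec <- measure_bundles(lab, fr)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$label, c(1, 2))
  expect_true(all(diff(rec$relative_position) > 0))
  expect_error(measure_region(lab, 5), "not present")
})
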