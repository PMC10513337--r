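test_that("archetype defaults encode the internode contrasts", {
  a2 <- make_archetype(2)
  a32 <- make_archetype(32)
  p <- seq(0.01, 0.99, length.out = 25)
  expect_gt(mean(a2$area_profile(p)), mean(a32$area_profile(p)))
  expect_lt(mean(a2$aspect_profile(p)), mean(a32$aspect_profile(p)))
  expect_gt(a2$wall_thickness_px, a32$wall_thickness_px)
  for (id in c(2, 12, 22, 32)) {
    a <- make_archetype(id)
    expect_gt(a$density_profile(0.05), a$density_profile(0.95))
    expect_lt(a$aspect_profile(0), 1)
    expect_gt(a$aspect_profile(1), 1)
    expect_gte(a$wall_thickness_px, 64)
    # profiles monotone in the documented directions
    expect_true(all(diff(a$density_profile(p)) <= 0))
    expect_true(all(diff(a$area_profile(p)) >= 0))
  }
  expect_error(make_archetype(7), "valid ids")
})

test_that("impossible profiles are rejected rather than silently empty", {
  arch <- make_archetype(2, overrides = list(
    area_profile = function(p) rep(1e6, length(p))))
  expect_error(generate_section(arch, seed = 1), "incompatible")
})

test_that("archetypes and sections are deterministic in their seeds", {
  a1 <- make_archetype(2, seed = 7)
  a2 <- make_archetype(2, seed = 7)
  expect_identical(a1$constants, a2$constants)
  arch <- make_archetype(32)
  s1 <- generate_section(arch, seed = 5)
  s2 <- generate_section(arch, seed = 5)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth$instance_mask, s2$truth$instance_mask)
  s3 <- generate_section(arch, seed = 6)
  expect_false(identical(s1$truth$instance_mask, s3$truth$instance_mask))
})

test_that("rendered stamps honour stage geometry, area and aspect", {
  set.seed(1)
  st <- render_bundle(1, 2000, 1.0)
  expect_lt(abs(sum(st) / (nrow(st) * ncol(st)) - pi / 4), 0.08)
  expect_lt(abs(sum(st) - 2000) / 2000, 0.15)
  st2 <- render_bundle(1, 2000, 0.5)
  expect_lt(abs(ncol(st2) - 0.5 * nrow(st2)), 2)
  st4 <- render_bundle(4, 3000, 1.2)
  lab <- label_components(st4)
  rec <- measure_region(lab, 1)
  expect_gt(rec$convex_area_px, rec$area_px)  # lobed concavities
  # extent declines with developmental stage
  exts <- vapply(1:4, function(s) {
    x <- render_bundle(s, 3000, 1.0, wobble = 0)
    sum(x) / (nrow(x) * ncol(x))
  }, numeric(1))
  expect_true(all(diff(exts) < 0))
  expect_error(render_bundle(1, 30, 1), "area_px")
  expect_error(render_bundle(3, 55, 1), "too small")
  expect_error(render_bundle(5, 500, 1), "stage")
})

test_that("sections keep every instance inside the tissue band, disjoint", {
  sec <- generate_section(make_archetype(32), rows = 440L, seed = 3)
  inst <- sec$truth$instance_mask
  wall <- sec$truth$frame$pith_row
  K <- max(inst)
  expect_gt(K, 30)
  expect_equal(sort(unique(as.vector(inst))), 0:K)  # consecutive ids
  fg <- which(inst > 0, arr.ind = TRUE)
  expect_true(all(fg[, 1] - 1 >= 0 & fg[, 1] - 1 < wall))
  expect_equal(nrow(sec$truth$params), K)
  # image formation: bundles darker than surrounding parenchyma, cavity bright
  px <- sec$image$pixels
  expect_lt(mean(px[inst > 0]), mean(px[inst == 0 & row(inst) <= wall]) - 0.2)
  expect_gt(mean(px[(wall + 5):440, ]), 0.9)
})

test_that("stratified sections recover their archetype calibration", {
  arch <- make_archetype(2)
  sec <- generate_section(arch, seed = 11)
  rec <- measure_bundles(sec$truth$instance_mask, sec$truth$frame)
  mm <- merge(rec, sec$truth$params, by = "label")
  expect_lt(median(abs(mm$area_px - mm$target_area) / mm$target_area), 0.15)
  expect_lt(median(abs(mm$aspect - mm$target_aspect)), 0.1)
  prof <- area_fraction_profile(sec$truth$instance_mask, sec$truth$frame, 20)
  expect_lt(abs(prof$area_fraction[1] - arch$target_area_fraction_epidermal),
            0.08)
  # single tangential row at the pith margin, tangentially elongated
  pith_rec <- rec[rec$relative_position > 0.9, ]
  expect_gt(nrow(pith_rec), 3)
  expect_true(all(pith_rec$aspect > 1))
})

test_that("iid placement reproduces a constant density profile", {
  # constant density and constant bundle geometry so edge clipping affects
  # both halves symmetrically
  arch <- make_archetype(2, overrides = list(
    wall_thickness_px = 200L,
    density_profile = function(p) rep(1.5e-4, length(p)),
    area_profile = function(p) rep(300, length(p)),
    aspect_profile = function(p) rep(1, length(p)),
    morphotype_profile = function(p) rep(1L, length(p))))
  counts <- matrix(0, 100, 2)
  for (s in 1:100) {
    sec <- generate_section(arch, seed = s, placement = "iid",
                            reject_overlap = FALSE)
    cr <- sec$truth$params$centroid_row
    counts[s, ] <- c(sum(cr < 100), sum(cr >= 100))
  }
  n <- sum(counts)
  # each bundle falls in the outer half with probability 1/2
  se <- sqrt(n * 0.25)
  expect_lt(abs(sum(counts[, 1]) - n / 2), 3 * se)
})

test_that("section and archetype round-trip through files", {
  skip_if_not_installed("tiff")
  arch <- make_archetype(22, overrides = list(area0 = 800), seed = 4)
  td <- withr::local_tempdir()
  yml <- file.path(td, "arch.yaml")
  write_archetype_yaml(arch, yml)
  back <- read_archetype_yaml(yml)
  expect_equal(back$constants, arch$constants)
  expect_equal(back$internode_id, arch$internode_id)
  sec <- generate_section(make_archetype(32, overrides = list(
    wall_thickness_px = 100L, tangential_width_px = 200L)), seed = 2)
  pth <- file.path(td, "mask.tiff")
  write_mask_tiff(sec$truth, pth)
  expect_identical(read_mask_tiff(pth), sec$truth$instance_mask)
  png_path <- file.path(td, "img.png")
  write_section_png(sec$image, png_path)
  round_trip <- png::readPNG(png_path)
  expect_equal(round_trip, sec$image$pixels, tolerance = 1 / 255)
})
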