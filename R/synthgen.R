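# Synthetic culm cross-section generator. Sections are radial strips with
# the epidermis at row 0 and the pith-cavity boundary at the bottom of the
# tissue band. Bundles are stamped as lobed quasi-elliptical shapes whose
# size, aspect and developmental morphotype follow radial profiles, with a
# single tangential row of tangentially-elongated bundles adjoining the
# pith boundary.
#
# Calibration constants below encode the qualitative radial trends of real
# moso-bamboo culm walls: bundle density and local area fraction highest at
# the epidermis side (local packing ~0.70 there), bundle area increasing
# epidermis->pith, aspect (tangential/radial) ~0.5 near the epidermis and
# >1 near the pith, and lower internodes having thicker walls, larger and
# more radially elongated bundles, and a lower whole-wall area ratio.

ARCHETYPE_DEFAULTS <- list(
  `2`  = list(wall_thickness_px = 600L, fill_epidermal = 0.76, fill_pith = 0.12,
              area0 = 900,  area1 = 6500, aspect0 = 0.48, aspect1 = 1.18),
  `12` = list(wall_thickness_px = 520L, fill_epidermal = 0.76, fill_pith = 0.16,
              area0 = 820,  area1 = 5200, aspect0 = 0.51, aspect1 = 1.22),
  `22` = list(wall_thickness_px = 440L, fill_epidermal = 0.76, fill_pith = 0.21,
              area0 = 740,  area1 = 4200, aspect0 = 0.54, aspect1 = 1.26),
  `32` = list(wall_thickness_px = 380L, fill_epidermal = 0.76, fill_pith = 0.26,
              area0 = 650,  area1 = 3400, aspect0 = 0.57, aspect1 = 1.30)
)

# Morphotype stages: 1 = solid fiber blob, 2 = two lobes flanking the
# phloem/xylem gap, 3-4 = four lobes around enlarged metaxylem positions.
STAGE_BREAKS <- c(0.12, 0.35, 0.65)

# boundary-shape parameters per stage: superellipse exponent n, pinch
# (notch) depth d, multiplicity m and sharpness pow. Stage 2 uses narrow
# deep notches at the radial ends (the phloem/xylem gap) so the bounding
# box barely shrinks while the area does; stages 3-4 notch at the four
# diagonal positions between the metaxylem lobes. Extent declines
# monotonically with stage.
STAGE_SHAPE <- list(
  list(n = 2.3, d = 0.00, m = 1L, pow = 6),
  list(n = 2.0, d = 0.50, m = 1L, pow = 20),
  list(n = 2.0, d = 0.34, m = 2L, pow = 6),
  list(n = 2.0, d = 0.46, m = 2L, pow = 6)
)

.shape_cache <- new.env(parent = emptyenv())

# numeric shape constants for a stage: unit boundary radius u(theta),
# half-extents mx, my, and extent k_area = area / bbox area
shape_constants <- function(stage) {
  key <- as.character(stage)
  if (!is.null(.shape_cache[[key]])) return(.shape_cache[[key]])
  s <- STAGE_SHAPE[[stage]]
  th <- seq(0, 2 * pi, length.out = 4096L)
  base <- (abs(cos(th))^s$n + abs(sin(th))^s$n)^(-1 / s$n)
  u <- base * (1 - s$d * abs(sin(s$m * th))^s$pow)
  mx <- max(u * abs(cos(th)))
  my <- max(u * abs(sin(th)))
  k_area <- (0.5 * sum(u^2) * diff(th[1:2])) / (4 * mx * my)
  out <- list(n = s$n, d = s$d, m = s$m, pow = s$pow, mx = mx, my = my,
              k_area = k_area)
  .shape_cache[[key]] <- out
  out
}

#' Internode archetype: generator parameters for one internode
#'
#' Returns calibrated default radial profiles for internodes 2, 12, 22 and
#' 32 (numbered from the culm base). Lower internodes get a thicker wall,
#' larger and more radially elongated (lower-aspect) bundles, and a lower
#' whole-wall bundle area ratio than upper internodes.
#'
#' @param internode_id one of 2, 12, 22, 32.
#' @param overrides named list replacing calibration constants
#'   (`wall_thickness_px`, `tangential_width_px`, `fill_epidermal`,
#'   `fill_pith`, `area0`, `area1`, `aspect0`, `aspect1`) or whole profile
#'   functions (`fill_profile`, `area_profile`, `aspect_profile`,
#'   `morphotype_profile`, `density_profile`).
#' @param seed integer seed stored with the archetype and used as the
#'   default by [generate_section()].
#' @return object of class `internode_archetype` with profile functions of
#'   the relative radial position p in \[0,1\]: `density_profile` (expected
#'   bundles per px^2), `area_profile` (mean bundle area, px^2),
#'   `aspect_profile` (tangential/radial bounding-box ratio),
#'   `morphotype_profile` (stage 1-4), plus `fill_profile` (local area
#'   fraction) and `target_area_fraction_epidermal`.
#' @export
make_archetype <- function(internode_id, overrides = list(), seed = 1L) {
  key <- as.character(internode_id)
  if (!key %in% names(ARCHETYPE_DEFAULTS))
    stop("unknown internode_id ", internode_id, "; valid ids: ",
         paste(names(ARCHETYPE_DEFAULTS), collapse = ", "))
  par <- ARCHETYPE_DEFAULTS[[key]]
  par$tangential_width_px <- 1024L
  const_names <- intersect(names(overrides), names(par))
  par[const_names] <- overrides[const_names]
  if (par$wall_thickness_px < 64) stop("wall_thickness_px must be >= 64")
  fill_profile <- function(p)
    par$fill_pith + (par$fill_epidermal - par$fill_pith) * (1 - p)^2
  area_profile <- function(p) par$area0 + (par$area1 - par$area0) * p^1.2
  aspect_profile <- function(p) par$aspect0 + (par$aspect1 - par$aspect0) * p
  morphotype_profile <- function(p)
    as.integer(1L + findInterval(p, STAGE_BREAKS))
  density_profile <- function(p) fill_profile(p) / area_profile(p)
  fun_names <- c("fill_profile", "area_profile", "aspect_profile",
                 "morphotype_profile", "density_profile")
  funs <- list(fill_profile = fill_profile, area_profile = area_profile,
               aspect_profile = aspect_profile,
               morphotype_profile = morphotype_profile,
               density_profile = density_profile)
  funs[intersect(names(overrides), fun_names)] <-
    overrides[intersect(names(overrides), fun_names)]
  structure(c(list(internode_id = as.integer(internode_id),
                   wall_thickness_px = as.integer(par$wall_thickness_px),
                   tangential_width_px = as.integer(par$tangential_width_px),
                   target_area_fraction_epidermal = 0.70,
                   constants = par, seed = as.integer(seed)),
              funs),
            class = "internode_archetype")
}

#' Render one vascular-bundle stamp
#'
#' Draws a binary stamp of the requested developmental stage: stage 1 is a
#' solid quasi-elliptical fiber blob; stage 2 has two fiber lobes flanking
#' a phloem/xylem gap (radial pinches); stages 3-4 have four lobes around
#' the metaxylem positions, stage 4 with deeper concavities. The stamp's
#' bounding box honours the requested tangential/radial aspect and its
#' pixel count the requested area (both within 15 percent).
#'
#' @param stage integer 1-4.
#' @param area_px target pixel count (>= 50).
#' @param aspect target bounding-box width/height ratio (> 0).
#' @param wobble amplitude of the random boundary perturbation (drawn from
#'   R's current RNG stream).
#' @return binary integer matrix (the stamp's bounding box).
#' @export
render_bundle <- function(stage, area_px, aspect, wobble = 0.03) {
  if (!stage %in% 1:4) stop("stage must be 1..4")
  if (area_px < 50) stop("area_px must be >= 50")
  if (aspect <= 0) stop("aspect must be positive")
  sc <- shape_constants(stage)
  h <- sqrt(area_px / (sc$k_area * aspect))
  w <- aspect * h
  min_dim <- c(3, 8, 12, 12)[stage]  # lobes need room to resolve
  if (w < min_dim || h < min_dim)
    stop("area ", area_px, " too small to realize stage ", stage, " lobes")
  a <- (w / 2) / sc$mx
  b <- (h / 2) / sc$my
  phi <- runif(1, 0, 2 * pi)
  H <- max(3L, ceiling(h)); W <- max(3L, ceiling(w))
  xs <- (seq_len(W) - (W + 1) / 2)
  ys <- (seq_len(H) - (H + 1) / 2)
  X <- matrix(xs, H, W, byrow = TRUE) / a
  Y <- matrix(ys, H, W) / b
  th <- atan2(Y, X)
  rad <- (abs(X)^sc$n + abs(Y)^sc$n)^(1 / sc$n)
  bound <- (1 - sc$d * abs(sin(sc$m * th))^sc$pow) *
    (1 + wobble * cos(3 * th + phi))
  stamp <- (rad <= bound) * 1L
  # trim to the realized bounding box
  rs <- which(rowSums(stamp) > 0); cs <- which(colSums(stamp) > 0)
  stamp[rs[1]:rs[length(rs)], cs[1]:cs[length(cs)], drop = FALSE]
}

place_stamp <- function(inst, stamp, top, left, label) {
  H <- nrow(stamp); W <- ncol(stamp)
  ri <- top:(top + H - 1L); ci <- left:(left + W - 1L)
  sub <- inst[ri, ci, drop = FALSE]
  sub[stamp > 0] <- label
  inst[ri, ci] <- sub
  inst
}

# TRUE when the stamp, dilated by one pixel (so placed instances never
# touch even diagonally), meets no existing instance pixel
region_free <- function(inst, stamp, top, left) {
  H <- nrow(inst); W <- ncol(inst)
  sh <- nrow(stamp); sw <- ncol(stamp)
  dil <- matrix(0L, sh + 2L, sw + 2L)
  for (dr in 0:2) for (dc in 0:2)
    dil[dr + seq_len(sh), dc + seq_len(sw)] <-
      pmax(dil[dr + seq_len(sh), dc + seq_len(sw)], stamp)
  r0 <- top - 1L; c0 <- left - 1L
  rr <- (r0):(r0 + sh + 1L); cc <- (c0):(c0 + sw + 1L)
  keep_r <- rr >= 1L & rr <= H; keep_c <- cc >= 1L & cc <= W
  win <- inst[rr[keep_r], cc[keep_c], drop = FALSE]
  !any(win > 0 & dil[keep_r, keep_c, drop = FALSE] > 0)
}

#' Generate a synthetic culm section with instance ground truth
#'
#' Bundles are placed by sequential rejection sampling (at most 200
#' attempts per bundle). The default `"stratified"` proposal lays bundles
#' on jittered tangential rows whose spacing realizes the archetype's
#' local area-fraction profile — i.i.d. proposals cannot reach the dense
#' epidermal packing — while `"iid"` draws independent positions from the
#' density profile (optionally without overlap rejection), which is useful
#' for statistical checks of the sampler itself.
#'
#' @param archetype an [make_archetype()] object.
#' @param rows image rows; must be >= the archetype wall thickness. Rows
#'   beyond the wall render as bright pith cavity.
#' @param seed integer seed (default: the archetype's).
#' @param placement `"stratified"` (default) or `"iid"`.
#' @param reject_overlap keep the non-overlap rejection test (default TRUE;
#'   only `"iid"` placement may disable it).
#' @param noise_sd Gaussian pixel noise SD (default 0.05).
#' @param contrast intensity drop of bundle pixels below parenchyma
#'   (default 0.4).
#' @return list with `image` (a `section_image`: pixels in \[0,1\],
#'   `pixel_size_um`) and `truth` (a `ground_truth`: `instance_mask`,
#'   per-instance `params` data frame, `frame`).
#' @export
generate_section <- function(archetype, rows = archetype$wall_thickness_px,
                             seed = archetype$seed,
                             placement = c("stratified", "iid"),
                             reject_overlap = TRUE,
                             noise_sd = 0.05, contrast = 0.4) {
  stopifnot(inherits(archetype, "internode_archetype"))
  placement <- match.arg(placement)
  wall <- archetype$wall_thickness_px
  if (rows < wall) stop("rows (", rows, ") must be >= wall thickness ", wall)
  W <- archetype$tangential_width_px
  set.seed(seed)
  inst <- matrix(0L, rows, W)
  params <- list()
  label <- 0L
  add_bundle <- function(stamp, top, left, stage, t_area, t_aspect) {
    label <<- label + 1L
    inst <<- place_stamp(inst, stamp, top, left, label)
    params[[label]] <<- data.frame(
      label = label, stage = stage, target_area = t_area,
      target_aspect = t_aspect,
      centroid_row = top - 1 + (nrow(stamp) - 1) / 2,
      centroid_col = left - 1 + (ncol(stamp) - 1) / 2)
  }
  draw_bundle <- function(p) {
    # size variability grows toward the pith; epidermal bundles are nearly
    # uniform (tight quasi-regular packing)
    stage <- archetype$morphotype_profile(p)
    t_area <- archetype$area_profile(p) * exp(rnorm(1, 0, 0.04 + 0.10 * p))
    t_aspect <- archetype$aspect_profile(p) * exp(rnorm(1, 0, 0.03 + 0.04 * p))
    list(stamp = render_bundle(stage, t_area, t_aspect),
         stage = stage, area = t_area, aspect = t_aspect)
  }
  if (placement == "stratified") {
    # tangential rows from the epidermis inward; the pith margin gets its
    # own single row of tangentially elongated bundles
    pith_zone <- wall * 0.90
    y <- 1  # small epidermal margin so bundles do not touch the image edge
    row_idx <- 0L
    while (TRUE) {
      p <- min(1, y / wall)
      sc <- shape_constants(archetype$morphotype_profile(p))
      h <- sqrt(archetype$area_profile(p) /
                  (sc$k_area * archetype$aspect_profile(p)))
      p <- min(1, (y + h / 2) / wall)  # refine at the row's own center
      sc <- shape_constants(archetype$morphotype_profile(p))
      A <- archetype$area_profile(p)
      asp <- archetype$aspect_profile(p)
      h <- sqrt(A / (sc$k_area * asp)); wdt <- asp * h
      f <- min(archetype$fill_profile(p), 0.72)
      gam <- sqrt(sc$k_area / f)
      ch <- gam * h; cw <- gam * wdt
      if (y + ch > pith_zone) break
      row_idx <- row_idx + 1L
      n_cells <- floor(W / cw)
      x0 <- (W - n_cells * cw) / 2 + (row_idx %% 2L) * cw / 2
      for (i in seq_len(n_cells)) {
        cx <- x0 + (i - 1) * cw + cw / 2
        if (cx + cw / 2 > W) next
        placed <- FALSE
        for (att in seq_len(200L)) {
          d <- draw_bundle(p)
          sh <- nrow(d$stamp); sw <- ncol(d$stamp)
          sy <- (ch - sh) / 2; sx <- (cw - sw) / 2
          if (sy < 0 || sx < 0) next
          # rows sit flush against their outer edge (epidermal bundles abut
          # the epidermis); only a small downward jitter
          top <- round(y + runif(1, 0, min(2, 2 * sy))) + 1L
          left <- round(cx - sw / 2 + runif(1, -1, 1) * sx) + 1L
          top <- max(2L, min(top, wall - sh))   # stay inside the tissue band
          left <- max(2L, min(left, W - sw))
          if (!reject_overlap || region_free(inst, d$stamp, top, left)) {
            add_bundle(d$stamp, top, left, d$stage, d$area, d$aspect)
            placed <- TRUE
            break
          }
        }
        if (!placed && i == 1 && row_idx == 1)
          stop("could not place bundles; fill_profile too dense near the epidermis")
      }
      y <- y + ch
    }
    # single tangential row at the pith margin
    p <- 0.97
    A <- archetype$area_profile(1) * 0.85
    asp <- max(1.3, archetype$aspect_profile(1))
    sc <- shape_constants(4L)
    h <- sqrt(A / (sc$k_area * asp)); wdt <- asp * h
    f <- max(archetype$fill_profile(1), 0.30)
    cw <- sqrt(sc$k_area / f)^2 * wdt  # in-row spacing realizes fill f
    n_cells <- floor(W / cw)
    x0 <- (W - n_cells * cw) / 2
    for (i in seq_len(n_cells)) {
      cx <- x0 + (i - 1) * cw + cw / 2
      for (att in seq_len(200L)) {
        stage <- 4L
        t_area <- A * exp(rnorm(1, 0, 0.10))
        t_aspect <- asp * exp(rnorm(1, 0, 0.05))
        stamp <- render_bundle(stage, t_area, t_aspect)
        sh <- nrow(stamp); sw <- ncol(stamp)
        top <- wall - 2L - sh + 1L   # bottom edge adjoins the pith boundary
        left <- round(cx - sw / 2 + runif(1, -1, 1) * max(0, (cw - sw) / 2)) + 1L
        left <- max(2L, min(left, W - sw))
        if (top < 2L) break
        if (!reject_overlap || region_free(inst, stamp, top, left)) {
          add_bundle(stamp, top, left, stage, t_area, t_aspect)
          break
        }
      }
    }
  } else {
    # i.i.d. placement from the density profile
    pr <- archetype$density_profile((seq_len(wall) - 0.5) / wall)
    n_target <- round(sum(pr) * W)
    pr <- pr / sum(pr)
    for (bidx in seq_len(n_target)) {
      for (att in seq_len(200L)) {
        ry <- sample.int(wall, 1L, prob = pr)
        p <- (ry - 0.5) / wall
        d <- draw_bundle(p)
        sh <- nrow(d$stamp); sw <- ncol(d$stamp)
        top <- ry - sh %/% 2L
        left <- sample.int(W, 1L) - sw %/% 2L
        if (top < 1L || left < 1L || top + sh - 1L > wall || left + sw - 1L > W)
          next
        if (!reject_overlap || region_free(inst, d$stamp, top, left)) {
          add_bundle(d$stamp, top, left, d$stage, d$area, d$aspect)
          break
        }
      }
    }
  }
  if (label == 0L)
    stop("no bundles placed: area_profile/fill_profile incompatible with a ",
         rows, "x", W, " section")
  params <- do.call(rbind, params)
  frame <- tissue_frame(0, wall)
  # image formation: parenchyma texture, darker bundles, bright pith cavity
  coarse <- matrix(rnorm(ceiling(rows / 16) * ceiling(W / 16), 0, 0.03),
                   ceiling(rows / 16))
  texture <- coarse[rep(seq_len(nrow(coarse)), each = 16)[seq_len(rows)],
                    rep(seq_len(ncol(coarse)), each = 16)[seq_len(W)]]
  img <- 0.72 + texture
  if (rows > wall) img[(wall + 1):rows, ] <- 0.97
  img[inst > 0] <- img[inst > 0] - contrast
  img <- img + matrix(rnorm(rows * W, 0, noise_sd), rows, W)
  img <- matrix(pmin(1, pmax(0, img)), rows, W)
  image <- structure(list(pixels = img, pixel_size_um = 4.70),
                     class = "section_image")
  truth <- structure(list(instance_mask = inst, params = params,
                          frame = frame),
                     class = "ground_truth")
  list(image = image, truth = truth)
}

#' Write a section image as 8-bit grayscale PNG
#' @param image `section_image` or numeric matrix in \[0,1\].
#' @param path output path.
#' @export
write_section_png <- function(image, path) {
  img <- if (inherits(image, "section_image")) image$pixels else image
  png::writePNG(img, path)
}

#' Write an instance mask as 16-bit grayscale TIFF
#' @param truth `ground_truth` or integer label matrix.
#' @param path output path.
#' @export
write_mask_tiff <- function(truth, path) {
  m <- if (inherits(truth, "ground_truth")) truth$instance_mask else truth
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
}

#' Read an instance mask written by [write_mask_tiff()]
#' @param path TIFF path.
#' @return integer label matrix.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write / read an archetype as a YAML config
#'
#' Only the calibration constants, internode id and seed are stored; the
#' profile functions are rebuilt on read, so custom profile overrides do
#' not survive a round trip (constants do).
#'
#' @param archetype an `internode_archetype`.
#' @param path YAML path.
#' @export
write_archetype_yaml <- function(archetype, path) {
  yaml::write_yaml(list(schema = "culmorph/archetype/1",
                        internode_id = archetype$internode_id,
                        seed = archetype$seed,
                        constants = archetype$constants), path)
}

#' @rdname write_archetype_yaml
#' @return `read_archetype_yaml` returns an `internode_archetype`.
#' @export
read_archetype_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  make_archetype(y$internode_id, overrides = y$constants, seed = y$seed)
}
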