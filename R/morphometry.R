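# Per-bundle shape descriptors computed from first principles: pixel-count
# area, coordinate moments, moment eccentricity, monotone-chain convex hull
# over pixel corner points, Moore boundary-chain perimeter, bounding-box
# aspect and extent. Conventions (documented so oracles can match them):
#  - pixel centers sit at integer 0-based (row, col) coordinates;
#  - bounding boxes are half-open [min_row, max_row) x [min_col, max_col);
#  - aspect = bbox width / bbox height (tangential / radial with the
#    epidermis at row 0);
#  - perimeter = length of the closed 8-connected boundary chain through
#    boundary pixel centers, axial steps 1 and diagonal steps sqrt(2)
#    (a single-pixel region has perimeter 4 by convention).

#' Label connected components of a binary mask
#'
#' Components are numbered 1..K in raster-scan order of their first pixel
#' (top-to-bottom, left-to-right).
#'
#' @param mask binary matrix (0/1 or logical).
#' @param connectivity 4 or 8 (default 8: thin bridges connect regions,
#'   matching how merged-bundle errors arise).
#' @return integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  .cm_label_components(m, as.integer(connectivity))
}

hull_monotone_chain <- function(pts) {
  # pts: 2-col matrix (x, y); returns hull vertices counter-clockwise
  pts <- unique(pts)
  o <- order(pts[, 1], pts[, 2])
  pts <- pts[o, , drop = FALSE]
  n <- nrow(pts)
  if (n <= 2) return(pts)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ], pts[i, ]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  pts[c(lower[-length(lower)], upper[-length(upper)]), , drop = FALSE]
}

shoelace_area <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# Moore-neighbour boundary tracing over a logical matrix; returns the chain
# perimeter (axial 1, diagonal sqrt(2)).
chain_perimeter <- function(m) {
  H <- nrow(m); W <- ncol(m)
  if (sum(m) == 1) return(4)
  pm <- matrix(FALSE, H + 2, W + 2)
  pm[2:(H + 1), 2:(W + 1)] <- m
  # start: first foreground pixel in raster order
  hit <- which(t(pm))[1]  # row-major scan
  sr <- (hit - 1) %/% (W + 2) + 1
  sc <- (hit - 1) %% (W + 2) + 1
  # clockwise Moore order starting W
  dr <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dc <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  per <- 0
  cr <- sr; cc <- sc
  dir_from <- 1L  # entered scanning from W
  first_move <- NA_integer_
  steps <- 0L
  max_steps <- 8L * sum(m) + 16L
  repeat {
    found <- FALSE
    for (t in 0:7) {
      d <- (dir_from - 1L + t) %% 8L + 1L
      nr <- cr + dr[d]; nc <- cc + dc[d]
      if (pm[nr, nc]) {
        per <- per + if (dr[d] != 0 && dc[d] != 0) sqrt(2) else 1
        # next scan starts from the neighbour just before the one we moved to,
        # rotated to point back toward the previous pixel's side
        dir_from <- (d - 1L + 6L) %% 8L + 1L
        cr <- nr; cc <- nc
        found <- TRUE
        steps <- steps + 1L
        if (is.na(first_move)) first_move <- d
        break
      }
    }
    if (!found) return(4)  # isolated pixel reached via degenerate mask
    if (cr == sr && cc == sc && steps > 1L) break
    if (steps > max_steps) break
  }
  per
}

# core worker: descriptors from a region's 0-based pixel coordinates
measure_coords <- function(r, c, label, img_rows, img_cols) {
  area <- length(r)
  cr <- mean(r); cc <- mean(c)
  mu20 <- mean((r - cr)^2)
  mu02 <- mean((c - cc)^2)
  mu11 <- mean((r - cr) * (c - cc))
  disc <- sqrt(4 * mu11^2 + (mu20 - mu02)^2) / 2
  lam_max <- (mu20 + mu02) / 2 + disc
  lam_min <- (mu20 + mu02) / 2 - disc
  ecc <- if (lam_max <= 0) 0 else sqrt(max(0, 1 - lam_min / lam_max))
  bb <- c(min(r), min(c), max(r) + 1, max(c) + 1)
  bh <- bb[3] - bb[1]; bw <- bb[4] - bb[2]
  sub <- matrix(FALSE, bh, bw)
  sub[cbind(r - bb[1] + 1, c - bb[2] + 1)] <- TRUE
  # boundary pixels: those with a 4-neighbour outside the region
  interior <- sub
  interior[] <- FALSE
  if (bh > 2 && bw > 2)
    interior[2:(bh - 1), 2:(bw - 1)] <-
      sub[2:(bh - 1), 2:(bw - 1)] & sub[1:(bh - 2), 2:(bw - 1)] &
      sub[3:bh, 2:(bw - 1)] & sub[2:(bh - 1), 1:(bw - 2)] &
      sub[2:(bh - 1), 3:bw]
  bnd <- which(sub & !interior, arr.ind = TRUE)
  br <- bnd[, 1] - 1 + bb[1]; bc <- bnd[, 2] - 1 + bb[2]
  corners <- cbind(x = c(bc - 0.5, bc + 0.5, bc - 0.5, bc + 0.5),
                   y = c(br - 0.5, br - 0.5, br + 0.5, br + 0.5))
  hull <- hull_monotone_chain(corners)
  conv_area <- shoelace_area(hull)
  per <- chain_perimeter(sub)
  touches <- bb[1] == 0 || bb[2] == 0 || bb[3] == img_rows || bb[4] == img_cols
  data.frame(label = label, area_px = area, perimeter_px = per,
             convex_area_px = conv_area, eccentricity = ecc,
             aspect = bw / bh, extent = area / (bh * bw),
             centroid_row = cr, centroid_col = cc,
             bbox_min_row = bb[1], bbox_min_col = bb[2],
             bbox_max_row = bb[3], bbox_max_col = bb[4],
             touches_border = touches)
}

#' Measure one labeled region
#'
#' @param labels integer label matrix from [label_components()].
#' @param label region id to measure.
#' @return one-row data frame with area_px, perimeter_px, convex_area_px,
#'   eccentricity, aspect, extent, centroid_row, centroid_col, bbox columns
#'   (half-open, 0-based) and touches_border.
#' @export
measure_region <- function(labels, label) {
  idx <- which(labels == label, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("label ", label, " not present in label image")
  measure_coords(idx[, 1] - 1, idx[, 2] - 1, label, nrow(labels), ncol(labels))
}

#' Relative radial position of a centroid
#'
#' Maps a centroid row to the normalized epidermis (0) to pith-cavity (1)
#' coordinate, clamped to \[0,1\].
#'
#' @param centroid_row row coordinate (0-based pixel units).
#' @param frame a [tissue_frame()].
#' @return numeric in \[0,1\].
#' @export
relative_position <- function(centroid_row, frame) {
  stopifnot(inherits(frame, "tissue_frame"))
  p <- (centroid_row - frame$epidermis_row) /
    (frame$pith_row - frame$epidermis_row)
  pmin(1, pmax(0, p))
}

#' Measure every bundle in a label image
#'
#' @param labels integer label matrix.
#' @param frame optional [tissue_frame()]; when given, a `relative_position`
#'   column is added.
#' @return data frame with one row per label, ordered by label.
#' @export
measure_bundles <- function(labels, frame = NULL) {
  K <- max(labels)
  if (K == 0) {
    out <- measure_region(matrix(c(1L, 0L), 1), 1)[0, ]
  } else {
    fg <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[fg]
    rs <- split(fg[, 1] - 1, lab)
    cs <- split(fg[, 2] - 1, lab)
    out <- do.call(rbind, lapply(seq_len(K), function(k) {
      key <- as.character(k)
      if (is.null(rs[[key]])) stop("instance ids not consecutive: missing ", k)
      measure_coords(rs[[key]], cs[[key]], k, nrow(labels), ncol(labels))
    }))
  }
  if (!is.null(frame))
    out$relative_position <- relative_position(out$centroid_row, frame)
  out
}

#' Write bundle records as CSV
#' @param records data frame from [measure_bundles()].
#' @param path output path.
#' @export
write_bundles_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
}
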