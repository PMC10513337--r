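# Radial coordinate frame and profiles. The radial coordinate p runs from
# the epidermis (p = 0, image row `epidermis_row`) to the pith cavity
# boundary (p = 1, image row `pith_row`); rows are the radial axis and
# columns the tangential axis throughout the package.

#' Tissue frame: the rows bounding the culm-wall band
#'
#' @param epidermis_row 0-based row of the epidermis boundary.
#' @param pith_row 0-based row of the pith-cavity boundary (exclusive);
#'   must exceed `epidermis_row`.
#' @return object of class `tissue_frame`.
#' @export
tissue_frame <- function(epidermis_row, pith_row) {
  if (pith_row <= epidermis_row)
    stop("degenerate frame: pith_row must exceed epidermis_row")
  structure(list(epidermis_row = as.numeric(epidermis_row),
                 pith_row = as.numeric(pith_row)),
            class = "tissue_frame")
}

#' Locate the tissue band in a section
#'
#' From ground truth the stored boundary rows are returned exactly. From an
#' image, a row belongs to the band when more than `row_fraction` of its
#' pixels are tissue-like (darker than `fg_cutoff`, which separates the
#' bright pith cavity / background from parenchyma and bundles); the frame
#' spans the outermost and innermost such rows.
#'
#' @param x a `ground_truth`, a `section_image`, or a numeric image matrix.
#' @param fg_cutoff intensity below which a pixel counts as tissue.
#' @param row_fraction fraction of tissue pixels a row needs to be in-band.
#' @return a [tissue_frame()].
#' @export
build_frame <- function(x, fg_cutoff = 0.85, row_fraction = 0.5) {
  if (inherits(x, "ground_truth")) return(x$frame)
  img <- if (inherits(x, "section_image")) x$pixels else x
  frac <- rowMeans(img < fg_cutoff)
  rows <- which(frac > row_fraction)
  if (length(rows) == 0) stop("no tissue band found in image")
  tissue_frame(min(rows) - 1L, max(rows))
}

#' Radial area-fraction / count profile
#'
#' Splits the tissue band into `n_bins` bins of equal width in the relative
#' coordinate p and reports, per bin, the fraction of tissue pixels that are
#' bundle pixels. Bins with no tissue pixels get `NA`.
#'
#' @param mask binary bundle mask (matrix) or instance label matrix.
#' @param frame a [tissue_frame()].
#' @param n_bins number of equal-width bins (>= 2), default 20.
#' @return data frame with bin, p_lo, p_hi, p_mid, area_fraction,
#'   tissue_px, bundle_px.
#' @export
area_fraction_profile <- function(mask, frame, n_bins = 20L) {
  stopifnot(inherits(frame, "tissue_frame"))
  if (n_bins < 2) stop("n_bins must be >= 2")
  e <- frame$epidermis_row; q <- frame$pith_row
  bundle <- mask > 0
  W <- ncol(mask)
  edges <- seq(0, 1, length.out = n_bins + 1)
  out <- data.frame(bin = seq_len(n_bins), p_lo = edges[-(n_bins + 1)],
                    p_hi = edges[-1])
  out$p_mid <- (out$p_lo + out$p_hi) / 2
  # each tissue row is assigned to exactly one bin by its 0-based row index,
  # so refining bins partitions rows and preserves the weighted mean exactly
  tissue_rows <- seq.int(floor(e) + 1L, min(nrow(mask), ceiling(q)))  # 1-based
  rc <- tissue_rows - 1L
  tissue_rows <- tissue_rows[rc >= e & rc < q]
  rc <- tissue_rows - 1L
  bin_of <- pmin(n_bins, floor((rc - e) / (q - e) * n_bins) + 1L)
  row_bundle <- rowSums(bundle[tissue_rows, , drop = FALSE])
  tissue_px <- tabulate(bin_of, n_bins) * W
  bundle_px <- vapply(seq_len(n_bins),
                      function(b) sum(row_bundle[bin_of == b]), numeric(1))
  out$tissue_px <- as.integer(tissue_px)
  out$bundle_px <- as.integer(bundle_px)
  out$area_fraction <- ifelse(tissue_px > 0, bundle_px / tissue_px, NA_real_)
  out
}

#' Radial bundle-count profile
#'
#' Number of bundles per equal-width radial bin, from measured records.
#'
#' @param records data frame from [measure_bundles()] with
#'   `relative_position`.
#' @param n_bins number of bins, default 10.
#' @param include_border include border-touching bundles (default FALSE).
#' @return data frame with bin, p_lo, p_hi, p_mid, count.
#' @export
count_profile <- function(records, n_bins = 10L, include_border = FALSE) {
  if (!include_border) records <- records[!records$touches_border, ]
  edges <- seq(0, 1, length.out = n_bins + 1)
  b <- pmin(n_bins, findInterval(records$relative_position, edges,
                                 rightmost.closed = TRUE))
  data.frame(bin = seq_len(n_bins), p_lo = edges[-(n_bins + 1)],
             p_hi = edges[-1],
             p_mid = (edges[-(n_bins + 1)] + edges[-1]) / 2,
             count = as.integer(tabulate(b, n_bins)))
}

#' Moving-window descriptor profile
#'
#' Sliding windows of exactly `window` consecutive records (records must be
#' sorted by position); reports the window-mean position and the mean and
#' population SD of the chosen descriptor — the moving average +/- SD
#' presentation used for radial fluctuation plots.
#'
#' @param records data frame of bundle records.
#' @param descriptor column name to profile (e.g. "area_px", "aspect").
#' @param window window length (default 25).
#' @param position positioning column: "relative" uses `relative_position`,
#'   "absolute_px" uses `centroid_row` (pixels from the epidermis).
#' @return data frame with p, mean, sd, window.
#' @export
moving_profile <- function(records, descriptor, window = 25L,
                           position = c("relative", "absolute_px")) {
  position <- match.arg(position)
  pos_col <- if (position == "relative") "relative_position" else "centroid_row"
  if (!descriptor %in% names(records)) stop("unknown descriptor: ", descriptor)
  n <- nrow(records)
  if (window > n)
    stop("window (", window, ") exceeds record count (", n, ")")
  o <- order(records[[pos_col]])
  x <- records[[descriptor]][o]
  p <- records[[pos_col]][o]
  k <- n - window + 1L
  out <- data.frame(p = numeric(k), mean = numeric(k), sd = numeric(k))
  for (i in seq_len(k)) {
    w <- i:(i + window - 1L)
    out$p[i] <- mean(p[w])
    out$mean[i] <- mean(x[w])
    out$sd[i] <- sqrt(mean((x[w] - mean(x[w]))^2))  # population SD
  }
  out$window <- window
  out
}

#' Whole-wall bundle area ratio
#'
#' Bundle pixels divided by tissue pixels over the entire band, the
#' culm-level statistic used to compare internodes.
#'
#' @param mask binary bundle mask or instance label matrix.
#' @param frame a [tissue_frame()].
#' @return numeric scalar in \[0,1\].
#' @export
area_ratio <- function(mask, frame) {
  stopifnot(inherits(frame, "tissue_frame"))
  rows <- (floor(frame$epidermis_row) + 1):ceiling(frame$pith_row)
  rows <- rows[rows >= 1 & rows <= nrow(mask)]
  if (length(rows) == 0) stop("frame contains no tissue rows")
  band <- mask[rows, , drop = FALSE]
  mean(band > 0)
}

#' Write a profile data frame as CSV
#' @param profile data frame from a profile function.
#' @param path output path.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(profile, path, row.names = FALSE)
}
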