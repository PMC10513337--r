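# Independent brute-force oracles used to validate the package's own
# implementations. These deliberately use different algorithms/primitives:
# stack-based flood fill for labeling, direct coordinate sums plus
# grDevices::chull for region descriptors.

# flood-fill connected-component labeling (stack-based, small masks only)
oracle_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  if (connectivity == 8L) {
    moves <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                   dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    moves <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] == 0 || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (m in seq_len(nrow(moves))) {
        r <- p[1] + moves[m, 1]; c <- p[2] + moves[m, 2]
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] != 0 && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# descriptors straight from coordinate lists; hull via grDevices::chull
oracle_measure <- function(labels, label) {
  idx <- which(labels == label, arr.ind = TRUE)
  r <- idx[, 1] - 1; c <- idx[, 2] - 1
  n <- length(r)
  cr <- sum(r) / n; cc <- sum(c) / n
  mu20 <- sum((r - cr)^2) / n
  mu02 <- sum((c - cc)^2) / n
  mu11 <- sum((r - cr) * (c - cc)) / n
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  lam_max <- tr / 2 + sqrt(max(0, tr^2 / 4 - det))
  lam_min <- tr / 2 - sqrt(max(0, tr^2 / 4 - det))
  ecc <- if (lam_max <= 0) 0 else sqrt(max(0, 1 - lam_min / lam_max))
  px <- c(c - 0.5, c + 0.5, c - 0.5, c + 0.5)
  py <- c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)
  h <- grDevices::chull(px, py)
  hx <- px[h]; hy <- py[h]
  m <- length(h); j <- c(2:m, 1)
  conv <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  bw <- max(c) - min(c) + 1; bh <- max(r) - min(r) + 1
  list(area = n, centroid = c(cr, cc), eccentricity = ecc,
       convex_area = conv, aspect = bw / bh, extent = n / (bw * bh))
}

# random blob: thresholded smooth noise, largest 8-connected component
random_blob_mask <- function(side = 28L, seed = 1L) {
  set.seed(seed)
  z <- matrix(rnorm(side * side), side, side)
  k <- 5L
  sm <- z
  for (rep in 1:3) {
    pad <- rbind(sm[1, , drop = FALSE], sm, sm[side, , drop = FALSE])
    sm <- (pad[1:side, ] + pad[2:(side + 1), ] + pad[3:(side + 2), ]) / 3
    pad <- cbind(sm[, 1, drop = FALSE], sm, sm[, side, drop = FALSE])
    sm <- (pad[, 1:side] + pad[, 2:(side + 1)] + pad[, 3:(side + 2)]) / 3
  }
  m <- (sm > stats::quantile(sm, 0.7)) * 1L
  lab <- oracle_label(m, 8L)
  if (max(lab) == 0) return(random_blob_mask(side, seed + 1000L))
  sizes <- tabulate(lab[lab > 0])
  (lab == which.max(sizes)) * 1L
}

# axis-aligned filled ellipse mask (pixel centers), with 1-px margin
ellipse_mask <- function(a_col, b_row) {
  H <- 2 * b_row + 3; W <- 2 * a_col + 3
  rr <- matrix(seq_len(H) - (H + 1) / 2, H, W)
  cc <- matrix(seq_len(W) - (W + 1) / 2, H, W, byrow = TRUE)
  ((cc / a_col)^2 + (rr / b_row)^2 <= 1) * 1L
}

# independent boundary-chain length: counterclockwise Moore tracing (the
# package traces clockwise), axial steps 1 and diagonal steps sqrt(2)
oracle_chain_perimeter <- function(m) {
  m <- m > 0
  H <- nrow(m); W <- ncol(m)
  if (sum(m) == 1) return(4)
  pm <- matrix(FALSE, H + 2, W + 2)
  pm[2:(H + 1), 2:(W + 1)] <- m
  hit <- which(t(pm))[1]
  sr <- (hit - 1) %/% (W + 2) + 1
  sc <- (hit - 1) %% (W + 2) + 1
  # counterclockwise scan order: the row-reflection of the clockwise table
  dr <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dc <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  per <- 0; cr <- sr; cc <- sc
  dir_from <- 1L; steps <- 0L
  max_steps <- 8L * sum(m) + 16L
  repeat {
    found <- FALSE
    for (t in 0:7) {
      d <- (dir_from - 1L + t) %% 8L + 1L
      nr <- cr + dr[d]; nc <- cc + dc[d]
      if (pm[nr, nc]) {
        per <- per + if (dr[d] != 0 && dc[d] != 0) sqrt(2) else 1
        dir_from <- (d - 1L + 6L) %% 8L + 1L
        cr <- nr; cc <- nc
        found <- TRUE; steps <- steps + 1L
        break
      }
    }
    if (!found) return(4)
    if (cr == sr && cc == sc && steps > 1L) break
    if (steps > max_steps) break
  }
  per
}

# permutation oracle for DSCF p-values. DSCF refers each pairwise statistic
# to the studentized-range distribution over k groups, i.e. a familywise
# reference, so the permutation analogue is max-T: permute all group labels
# jointly and record the maximum pairwise statistic. Returns the null draws
# so each observed statistic can be referred to them.
oracle_dscf_maxT <- function(groups, n_perm = 20000L, seed = 1L) {
  pool <- unlist(groups)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  pairs <- utils::combn(length(groups), 2)
  set.seed(seed)
  replicate(n_perm, {
    idx <- sample(length(pool))
    perm <- lapply(seq_along(sizes), function(i) pool[idx[starts[i]:ends[i]]])
    max(vapply(seq_len(ncol(pairs)), function(j) {
      q <- culmorph:::dscf_statistic(perm[[pairs[1, j]]], perm[[pairs[2, j]]])
      if (is.na(q)) 0 else q
    }, numeric(1)))
  })
}
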