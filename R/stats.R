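# Group-comparison machinery for internode contrasts: one-way ANOVA with
# Tukey HSD, Kruskal-Wallis with the Dwass-Steel-Critchlow-Fligner (DSCF)
# all-pairs rank post-hoc, and compact letter displays. Tukey and DSCF
# p-values come from the studentized-range distribution (stats::ptukey);
# the Kruskal-Wallis global test is stats::kruskal.test. DSCF is
# implemented here because no installed package provides it.

check_groups <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' The global test is the ordinary one-way ANOVA F. Pairwise comparisons
#' use the studentized-range statistic
#' q_ij = |mean_i - mean_j| / sqrt(MSE (1/n_i + 1/n_j) / 2)
#' with p-values from the studentized-range distribution with k groups and
#' N - k error degrees of freedom (the Tukey-Kramer procedure for unequal
#' n).
#'
#' @param groups named list of numeric vectors (>= 2 values each).
#' @param alpha significance level (default 0.05).
#' @return list with `F`, `p_global`, `df`, and `pairwise` (data frame:
#'   group_i, group_j, statistic, p_value, significant).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  mse <- ss_within / df2
  Fval <- (ss_between / df1) / mse
  p_global <- pf(Fval, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(k, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(idx) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    se <- sqrt(mse * (1 / n[i] + 1 / n[j]) / 2)
    q <- abs(means[i] - means[j]) / se
    p <- ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    data.frame(group_i = names(groups)[i], group_j = names(groups)[j],
               statistic = q, p_value = p, significant = p < alpha)
  }))
  rownames(pw) <- NULL
  list(F = Fval, p_global = p_global, df = c(df1, df2), pairwise = pw,
       alpha = alpha)
}

#' Kruskal-Wallis test with DSCF pairwise comparisons
#'
#' Global test: tie-corrected Kruskal-Wallis H (via [stats::kruskal.test]).
#' For each pair (i, j) the DSCF procedure ranks the two groups jointly;
#' with W the rank sum of group i, m = n_i (n_i + n_j + 1) / 2 and
#' variance n_i n_j / 12 * ((N + 1) - sum(t^3 - t) / (N (N - 1))) over the
#' tied-value multiplicities t (N = n_i + n_j), the statistic
#' q = sqrt(2) |W - m| / sd is referred to the studentized-range
#' distribution with k groups and infinite degrees of freedom. A pair whose
#' values are all tied gets p = 1.
#'
#' @inheritParams anova_tukey
#' @return list with `H`, `p_global`, and `pairwise` as in [anova_tukey()].
#' @export
kruskal_dscf <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  k <- length(groups)
  kw <- kruskal.test(groups)
  pairs <- utils::combn(k, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(idx) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    q <- dscf_statistic(groups[[i]], groups[[j]])
    p <- if (is.na(q)) 1 else ptukey(q, nmeans = k, df = Inf,
                                     lower.tail = FALSE)
    data.frame(group_i = names(groups)[i], group_j = names(groups)[j],
               statistic = ifelse(is.na(q), 0, q), p_value = p,
               significant = p < alpha)
  }))
  rownames(pw) <- NULL
  list(H = unname(kw$statistic), p_global = kw$p.value, pairwise = pw,
       alpha = alpha)
}

# sqrt(2) |W - E[W]| / sd(W) for one pair; NA when the variance is zero
# (all values tied across the pair)
dscf_statistic <- function(x, y) {
  ni <- length(x); nj <- length(y); N <- ni + nj
  r <- rank(c(x, y))
  W <- sum(r[seq_len(ni)])
  m <- ni * (N + 1) / 2
  t <- table(c(x, y))
  tie <- sum(t^3 - t)
  v <- ni * nj / 12 * ((N + 1) - tie / (N * (N - 1)))
  if (v <= 0) return(NA_real_)
  sqrt(2) * abs(W - m) / sqrt(v)
}

#' Compact letter display from pairwise results
#'
#' Insert-and-absorb letter assignment: starting from one letter shared by
#' all groups, each significant pair splits every letter set containing
#' both members; duplicate sets absorbed. Two groups share a letter if and
#' only if they are not significantly different in the supplied pairwise
#' set (letter-count minimality is not guaranteed).
#'
#' @param pairwise data frame with group_i, group_j, significant (as
#'   produced by [anova_tukey()] / [kruskal_dscf()]); must cover all pairs.
#' @param groups optional character vector fixing the group order.
#' @return named character vector: group id -> letter string.
#' @export
compact_letters <- function(pairwise, groups = NULL) {
  if (is.null(groups))
    groups <- sort(unique(c(pairwise$group_i, pairwise$group_j)))
  if (length(groups) < 2)
    stop("pairwise results must cover all group pairs (need >= 2 groups)")
  key <- paste(pmin(pairwise$group_i, pairwise$group_j),
               pmax(pairwise$group_i, pairwise$group_j))
  if (anyDuplicated(key)) {
    agg <- tapply(pairwise$significant, key, function(s) length(unique(s)))
    if (any(agg > 1)) stop("pair listed twice with conflicting significance")
    pairwise <- pairwise[!duplicated(key), ]
    key <- key[!duplicated(key)]
  }
  need <- utils::combn(sort(groups), 2)
  need_key <- paste(need[1, ], need[2, ])
  if (!all(need_key %in% key))
    stop("pairwise results must cover all group pairs; missing: ",
         paste(setdiff(need_key, key), collapse = ", "))
  sets <- list(groups)
  for (r in which(pairwise$significant)) {
    a <- pairwise$group_i[r]; b <- pairwise$group_j[r]
    new_sets <- list()
    for (s in sets) {
      if (all(c(a, b) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (u in seq_along(new_sets)) {
      for (v in seq_along(new_sets)) {
        if (u != v && keep[u] && keep[v] &&
            all(new_sets[[u]] %in% new_sets[[v]]) &&
            (length(new_sets[[u]]) < length(new_sets[[v]]) || u > v))
          keep[u] <- FALSE
      }
    }
    sets <- new_sets[keep]
  }
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  # stable letter order: sets sorted by their earliest member
  first_member <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_member)]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- setNames(rep("", length(groups)), groups)
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) out[g] <- paste0(out[g], letters_pool[s])
  }
  out
}

#' Write pairwise results and letters as CSV
#' @param result output of [anova_tukey()] or [kruskal_dscf()].
#' @param path output path.
#' @export
write_stats_csv <- function(result, path) {
  pw <- result$pairwise
  letters <- compact_letters(pw)
  pw$letters_i <- letters[pw$group_i]
  pw$letters_j <- letters[pw$group_j]
  write.csv(pw, path, row.names = FALSE)
}
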