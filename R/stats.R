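#' Diameter class bounds
#'
#' The three stem diameter classes used to pool specimens before group
#' comparisons: narrow 1.8-3.9 mm, medium 3.9-5.9 mm, large above 5.9 mm.
#' Because the printed class edges overlap, the boundary rule is fixed here:
#' 3.9 mm falls in medium and large is strictly above 5.9 mm. Diameters below
#' the narrow lower bound receive the `"below"` label and are excluded
#' downstream.
#'
#' @param narrow_min,narrow_max,medium_max Class edges in mm.
#' @return An object of class `class_bounds`.
#' @export
diameter_class_bounds <- function(narrow_min = 1.8, narrow_max = 3.9,
                                  medium_max = 5.9) {
  stopifnot(narrow_min < narrow_max, narrow_max < medium_max)
  structure(list(narrow_min = narrow_min, narrow_max = narrow_max,
                 medium_max = medium_max),
            class = "class_bounds")
}

#' Assign stems to diameter classes
#'
#' @param d Diameters (mm), positive.
#' @param bounds A [diameter_class_bounds()].
#' @return Factor with levels `below`, `narrow`, `medium`, `large`.
#' @export
assign_diameter_class <- function(d, bounds = diameter_class_bounds()) {
  stopifnot(all(d > 0))
  cls <- ifelse(d < bounds$narrow_min, "below",
         ifelse(d < bounds$narrow_max, "narrow",
         ifelse(d <= bounds$medium_max, "medium", "large")))
  factor(cls, levels = c("below", "narrow", "medium", "large"))
}

# split values by group, dropping groups below the minimum size
split_groups <- function(values, groups, min_group_size) {
  stopifnot(length(values) == length(groups))
  if (any(!is.finite(values))) stop("group values must be finite")
  g <- split(values, factor(groups))
  sizes <- lengths(g)
  keep <- sizes >= min_group_size
  excluded <- tibble::tibble(
    group = names(g)[!keep],
    n = unname(sizes[!keep]),
    reason = sprintf("n = %d below minimum group size %d",
                     unname(sizes[!keep]), min_group_size)
  )
  list(groups = g[keep], excluded = excluded)
}

#' Kruskal-Wallis test over stem categories
#'
#' Tie-corrected Kruskal-Wallis test on mid-ranks, with the small-group
#' exclusion rule applied before testing: groups with fewer than
#' `min_group_size` observations are dropped and recorded with a reason (the
#' field analysis excluded one undersized category the same way). The H
#' statistic, degrees of freedom and chi-squared p-value are computed with
#' [stats::kruskal.test()]; the fully tied degenerate case (all values equal)
#' is reported as H = 0, p = 1.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`.
#' @param min_group_size Minimum observations per group (default 3).
#' @return An object of class `kw_result`: list with `H`, `df`, `p_value`,
#'   `n`, `group_sizes`, and an `excluded` tibble.
#' @export
kruskal_wallis <- function(values, groups, min_group_size = 3L) {
  sp <- split_groups(values, groups, min_group_size)
  if (length(sp$groups) < 2L) {
    stop("need at least 2 groups of size >= ", min_group_size,
         " after exclusions")
  }
  v <- unlist(sp$groups, use.names = FALSE)
  g <- factor(rep(names(sp$groups), lengths(sp$groups)))
  k <- nlevels(g)
  if (length(unique(v)) == 1L) {
    res <- list(H = 0, df = k - 1L, p_value = 1)
  } else {
    kt <- stats::kruskal.test(v, g)
    res <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p_value = kt$p.value)
  }
  structure(
    c(res, list(n = length(v), group_sizes = lengths(sp$groups),
                excluded = sp$excluded)),
    class = "kw_result"
  )
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$H, x$df, x$p_value, x$n))
  if (nrow(x$excluded)) {
    cat("  excluded groups:",
        paste(x$excluded$group, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Dunn's post-hoc test on mean ranks
#'
#' Pairwise z-tests following a Kruskal-Wallis test, on the mid-ranks of the
#' pooled sample with tie correction:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(T)/(12(N-1))) (1/n_i + 1/n_j))`
#' where `T = t^3 - t` over tie groups. Two-sided p-values come from the
#' standard normal; an optional multiplicity adjustment (any method of
#' [stats::p.adjust()]) is applied across the pairs.
#'
#' @inheritParams kruskal_wallis
#' @param adjust Multiplicity adjustment method (default `"none"`).
#' @param min_group_size Groups smaller than this are excluded (size-0 groups
#'   can never appear in a pair); default 1 so all non-empty groups enter.
#' @return An object of class `dunn_result`: list with `pairs` (tibble:
#'   group1, group2, z, p_value, p_adjusted), symmetric matrices `z` and `p`
#'   (adjusted), group mean ranks, and the adjustment used.
#' @export
dunn_posthoc <- function(values, groups, adjust = "none",
                         min_group_size = 1L) {
  sp <- split_groups(values, groups, min_group_size)
  g <- sp$groups
  if (length(g) < 2L) stop("need at least 2 non-empty groups")
  v <- unlist(g, use.names = FALSE)
  N <- length(v)
  r <- rank(v)  # mid-ranks
  sizes <- lengths(g)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  mean_ranks <- vapply(seq_along(g),
                       function(i) mean(r[starts[i]:ends[i]]), numeric(1))
  names(mean_ranks) <- names(g)
  ties <- table(v)
  tie_sum <- sum(ties^3 - ties)
  var_factor <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  nm <- names(g)
  combs <- utils::combn(seq_along(g), 2L)
  z <- p_raw <- numeric(ncol(combs))
  for (c_i in seq_len(ncol(combs))) {
    i <- combs[1, c_i]; j <- combs[2, c_i]
    se <- sqrt(var_factor * (1 / sizes[i] + 1 / sizes[j]))
    z[c_i] <- (mean_ranks[i] - mean_ranks[j]) / se
    p_raw[c_i] <- 2 * stats::pnorm(-abs(z[c_i]))
  }
  p_adj <- stats::p.adjust(p_raw, method = adjust)
  zmat <- pmat <- matrix(NA_real_, length(g), length(g),
                         dimnames = list(nm, nm))
  diag(pmat) <- 1; diag(zmat) <- 0
  for (c_i in seq_len(ncol(combs))) {
    i <- combs[1, c_i]; j <- combs[2, c_i]
    zmat[i, j] <- z[c_i]; zmat[j, i] <- -z[c_i]
    pmat[i, j] <- pmat[j, i] <- p_adj[c_i]
  }
  structure(
    list(pairs = tibble::tibble(group1 = nm[combs[1, ]],
                                group2 = nm[combs[2, ]],
                                z = z, p_value = p_raw, p_adjusted = p_adj),
         z = zmat, p = pmat, mean_ranks = mean_ranks,
         adjust = adjust, excluded = sp$excluded),
    class = "dunn_result"
  )
}

#' @export
print.dunn_result <- function(x, ...) {
  cat("Dunn's post-hoc test (adjustment:", x$adjust, ")\n")
  print(as.data.frame(x$pairs), row.names = FALSE)
  invisible(x)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb letter assignment: starting from a single letter shared
#' by all groups, each significant pair splits every letter column containing
#' both members, and columns whose group set is contained in another are
#' absorbed. The result satisfies both directions of the display contract:
#' two groups share a letter if and only if their pairwise p-value is at
#' least `alpha`. Non-transitive significance patterns are represented by
#' groups carrying several letters.
#'
#' @param p Symmetric matrix of pairwise p-values with group names on both
#'   dimensions (diagonal ignored).
#' @param alpha Significance level (default 0.05).
#' @return Named character vector: the letters of each group.
#' @export
compact_letter_display <- function(p, alpha = 0.05) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p), !is.null(rownames(p)))
  nm <- rownames(p)
  cols <- list(nm)
  pairs <- utils::combn(nm, 2L, simplify = FALSE)
  for (pr in pairs) {
    if (is.na(p[pr[1], pr[2]]) || p[pr[1], pr[2]] >= alpha) next
    new_cols <- list()
    for (col in cols) {
      if (all(pr %in% col)) {
        new_cols <- c(new_cols, list(setdiff(col, pr[1])),
                      list(setdiff(col, pr[2])))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    new_cols <- new_cols[lengths(new_cols) > 0L]
    # absorb: drop any column contained in another (keep first of duplicates)
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i == j || !keep[i]) next
        if (all(new_cols[[i]] %in% new_cols[[j]]) &&
            (length(new_cols[[i]]) < length(new_cols[[j]]) || j < i)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }
  # stable letter order: by first member's position in nm
  ord <- order(vapply(cols, function(col) min(match(col, nm)), numeric(1)))
  cols <- cols[ord]
  out <- vapply(nm, function(g) {
    paste0(letters[which(vapply(cols, function(col) g %in% col, logical(1)))],
           collapse = "")
  }, character(1))
  out
}

#' Spearman t-statistic transform
#'
#' `t = R_s * sqrt((n - 2) / (1 - R_s^2))`: the t-statistic (df = n - 2) of a
#' Spearman rank correlation coefficient. `|R_s| = 1` maps to a signed
#' infinity.
#'
#' @param r_s Spearman coefficient in `[-1, 1]`.
#' @param n Number of pairs, >= 3.
#' @return The t value.
#' @export
spearman_t_statistic <- function(r_s, n) {
  stopifnot(abs(r_s) <= 1, n >= 3)
  if (abs(r_s) == 1) return(sign(r_s) * Inf)
  r_s * sqrt((n - 2) / (1 - r_s^2))
}

#' Spearman rank correlation with t-statistic
#'
#' Pearson correlation of mid-ranks, with the t approximation for the
#' two-sided p-value (df = n - 2); at the sample sizes of pooled field
#' cohorts (hundreds of stem segments) the t approximation is the standard
#' choice. A perfect monotone relation is flagged and reported with p = 0 and
#' unbounded t.
#'
#' @param x,y Paired numeric vectors, finite, length >= 3, non-constant.
#' @return An object of class `spearman_result`: list with `r_s`, `n`, `t`,
#'   `p_value`, `perfect`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  r_s <- stats::cor(rank(x), rank(y))
  n <- length(x)
  t <- spearman_t_statistic(r_s, n)
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df = n - 2)
  structure(list(r_s = r_s, n = n, t = t, p_value = p,
                 perfect = is.infinite(t)),
            class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: R_s = %.4f (n = %d), t = %.4g, p = %.4g%s\n",
              x$r_s, x$n, x$t, x$p_value,
              if (x$perfect) " [perfect monotone]" else ""))
  invisible(x)
}
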