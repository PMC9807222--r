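# Independent brute-force oracles, deliberately written from first principles
# (no rank(), no package internals) so they can cross-check the implementation.

# mid-ranks by counting
oracle_midranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# tie-corrected Kruskal-Wallis H on a list of group vectors
oracle_kw_H <- function(groups) {
  v <- unlist(groups)
  N <- length(v)
  r <- oracle_midranks(v)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  H <- 0
  for (i in seq_along(groups)) {
    Rbar <- mean(r[starts[i]:ends[i]])
    H <- H + sizes[i] * (Rbar - (N + 1) / 2)^2
  }
  H <- 12 * H / (N * (N + 1))
  tie_tab <- table(v)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  unname(H / corr)
}

# Dunn z for one pair of a list of group vectors (pooled tie correction)
oracle_dunn_z <- function(groups, i, j) {
  v <- unlist(groups)
  N <- length(v)
  r <- oracle_midranks(v)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  Ri <- mean(r[starts[i]:ends[i]])
  Rj <- mean(r[starts[j]:ends[j]])
  tie_tab <- table(v)
  var_factor <- N * (N + 1) / 12 -
    sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  unname((Ri - Rj) / sqrt(var_factor * (1 / sizes[i] + 1 / sizes[j])))
}

# exact permutation p-value of the KW statistic (small total n only):
# enumerate every partition of the pooled values into groups of the given
# sizes and count partitions with H at least as large as observed
oracle_kw_perm_p <- function(groups) {
  v <- unlist(groups)
  sizes <- lengths(groups)
  H_obs <- oracle_kw_H(groups)
  n <- length(v)
  idx1 <- utils::combn(n, sizes[1], simplify = FALSE)
  count <- 0L
  total <- 0L
  for (i1 in idx1) {
    rest <- setdiff(seq_len(n), i1)
    if (length(sizes) == 2L) {
      splits <- list(list(rest))
    } else if (length(sizes) == 3L) {
      splits <- lapply(utils::combn(length(rest), sizes[2], simplify = FALSE),
                       function(k) list(rest[k], rest[-k]))
    } else {
      stop("oracle supports 2 or 3 groups")
    }
    for (sp in splits) {
      gs <- c(list(v[i1]), lapply(sp, function(k) v[k]))
      total <- total + 1L
      if (oracle_kw_H(gs) >= H_obs - 1e-12) count <- count + 1L
    }
  }
  count / total
}

# brute-force centroid and per-tissue second moments of a label matrix
oracle_section_moments <- function(labels, p) {
  ys <- c(); lab_v <- c()
  rows <- nrow(labels); cols <- ncol(labels)
  sx <- 0; sy <- 0; n <- 0
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      if (labels[i, j] > 0) {
        sx <- sx + (j - 0.5) * p
        sy <- sy + (i - 0.5) * p
        n <- n + 1
        ys <- c(ys, (i - 0.5) * p)
        lab_v <- c(lab_v, labels[i, j])
      }
    }
  }
  ybar <- sy / n
  I <- numeric(4)
  for (k in seq_along(ys)) {
    I[lab_v[k]] <- I[lab_v[k]] + (ys[k] - ybar)^2 * p^2 + p^4 / 12
  }
  list(centroid = c(x = sx / n, y = ybar), I = I)
}

# closed-form OLS slope of y on x
oracle_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# reconstruct the significance relation implied by a letter display:
# TRUE where two groups share at least one letter
letters_share_matrix <- function(lett) {
  nm <- names(lett)
  sets <- strsplit(lett, "")
  out <- matrix(NA, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      out[i, j] <- length(intersect(sets[[i]], sets[[j]])) > 0
    }
  }
  out
}

# random symmetric p-value matrix for letter-display property tests
random_p_matrix <- function(k) {
  p <- matrix(1, k, k, dimnames = list(LETTERS[1:k], LETTERS[1:k]))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p[i, j] <- p[j, i] <- stats::runif(1)
    }
  }
  p
}
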