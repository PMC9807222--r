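test_that("diameter classes follow the pooled class bounds", {
  cls <- assign_diameter_class(c(3.0, 3.9, 6.2, 1.0, 5.9, 1.8))
  expect_equal(as.character(cls),
               c("narrow", "medium", "large", "below", "medium", "narrow"))
  expect_error(assign_diameter_class(-1), "d > 0")
})

test_that("Kruskal-Wallis matches the brute-force mid-rank oracle", {
  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  v <- unlist(groups)
  g <- rep(names(groups), lengths(groups))
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$H, oracle_kw_H(groups), tolerance = 1e-12)
  expect_equal(kw$df, 2L)
  expect_equal(kw$p_value, stats::pchisq(kw$H, 2, lower.tail = FALSE))
  # with ties
  groups_t <- list(a = c(1, 2, 2, 3), b = c(2, 4, 4), c = c(5, 5, 6))
  kw_t <- kruskal_wallis(unlist(groups_t),
                         rep(names(groups_t), lengths(groups_t)))
  expect_equal(kw_t$H, oracle_kw_H(groups_t), tolerance = 1e-12)
})

test_that("identical groups give H = 0, p = 1 and small groups are excluded", {
  v <- rep(5, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$H, 0)
  expect_equal(kw$p_value, 1)
  # undersized group dropped with a recorded reason
  kw2 <- kruskal_wallis(c(1, 2, 3, 4, 5, 6, 99), c(rep(c("a", "b"), 3), "c"))
  expect_equal(nrow(kw2$excluded), 1L)
  expect_equal(kw2$excluded$group, "c")
  expect_match(kw2$excluded$reason, "minimum group size")
  expect_error(kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b")),
               "at least 2 groups")
})

test_that("chi-squared p is close to the exact permutation null at small n", {
  groups <- list(a = c(1.2, 3.4, 2.2), b = c(4.1, 5.0, 3.9), c = c(0.5, 2.8))
  kw <- kruskal_wallis(unlist(groups),
                       rep(names(groups), lengths(groups)),
                       min_group_size = 2)
  p_exact <- oracle_kw_perm_p(groups)
  expect_lt(abs(kw$p_value - p_exact), 0.02)
})

test_that("Dunn z matches the direct formula and adjustments behave", {
  groups <- list(a = c(1, 2, 2, 3), b = c(2, 4, 5), c = c(6, 7, 7, 9))
  v <- unlist(groups)
  g <- rep(names(groups), lengths(groups))
  dn <- dunn_posthoc(v, g)
  for (row in seq_len(nrow(dn$pairs))) {
    i <- match(dn$pairs$group1[row], names(groups))
    j <- match(dn$pairs$group2[row], names(groups))
    expect_equal(dn$pairs$z[row], oracle_dunn_z(groups, i, j),
                 tolerance = 1e-12)
    expect_equal(dn$pairs$p_value[row],
                 2 * pnorm(-abs(dn$pairs$z[row])), tolerance = 1e-12)
  }
  # two identical groups: z = 0, p = 1
  dn0 <- dunn_posthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(dn0$pairs$z, 0)
  expect_equal(dn0$pairs$p_value, 1)
  # Bonferroni equals min(1, m * p_raw)
  dnb <- dunn_posthoc(v, g, adjust = "bonferroni")
  m <- nrow(dnb$pairs)
  expect_equal(dnb$pairs$p_adjusted,
               pmin(1, m * dnb$pairs$p_value), tolerance = 1e-12)
})

test_that("Kruskal-Wallis reduces to the squared Dunn z for two groups", {
  set.seed(3)
  for (rep in 1:5) {
    v <- c(sample(1:8, 5, replace = TRUE), sample(3:10, 6, replace = TRUE))
    g <- rep(c("a", "b"), c(5, 6))
    if (length(unique(v)) == 1) next
    kw <- kruskal_wallis(v, g)
    dn <- dunn_posthoc(v, g)
    expect_equal(kw$H, dn$pairs$z^2, tolerance = 1e-9)
  }
})

test_that("compact letter displays encode the thresholded p-matrix", {
  nm <- c("A", "B", "C")
  mk <- function(pAB, pAC, pBC) {
    p <- diag(3); p[] <- 1; dimnames(p) <- list(nm, nm)
    p["A", "B"] <- p["B", "A"] <- pAB
    p["A", "C"] <- p["C", "A"] <- pAC
    p["B", "C"] <- p["C", "B"] <- pBC
    p
  }
  # all non-significant: single shared letter
  expect_equal(unname(compact_letter_display(mk(0.5, 0.5, 0.5))),
               c("a", "a", "a"))
  # all significant: three distinct letters
  expect_equal(unname(compact_letter_display(mk(0.01, 0.01, 0.01))),
               c("a", "b", "c"))
  # chain A~B, B~C, A != C
  expect_equal(unname(compact_letter_display(mk(0.5, 0.01, 0.5))),
               c("a", "ab", "b"))
})

test_that("letter sharing reconstructs significance for random patterns", {
  set.seed(99)
  for (rep in 1:25) {
    k <- sample(3:5, 1)
    p <- random_p_matrix(k)
    lett <- compact_letter_display(p, alpha = 0.05)
    share <- letters_share_matrix(lett)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        expect_identical(unname(share[i, j]), unname(p[i, j] >= 0.05))
      }
    }
  }
})

test_that("Spearman t transform reproduces published-scale statistics", {
  expect_equal(round(spearman_t_statistic(0.7503, 269), 2), 18.54)
  expect_lt(abs(spearman_t_statistic(-0.5720, 269) - (-11.40)), 0.01)
  # t transform inverts exactly
  for (r in c(-0.9, -0.3, 0.2, 0.75)) {
    t <- spearman_t_statistic(r, 50)
    r_back <- t / sqrt(48 + t^2)
    expect_equal(r_back, r, tolerance = 1e-12)
  }
})

test_that("spearman_test handles perfect, constant and monotone cases", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  res <- spearman_test(x, x + 1)
  expect_equal(res$r_s, 1)
  expect_true(res$perfect)
  expect_equal(res$p_value, 0)
  expect_error(spearman_test(x, rep(2, 6)), "constant")
  # rank invariance under strictly monotone transforms
  y <- c(2, 7, 1, 9, 4, 5)
  r1 <- spearman_test(x, y)
  r2 <- spearman_test(exp(x), log(y + 1))
  expect_equal(r1$r_s, r2$r_s, tolerance = 1e-12)
  expect_equal(r1$t, r2$t, tolerance = 1e-12)
  # and KW is rank-invariant too
  v <- c(1, 5, 2, 8, 9, 3, 7, 4, 6)
  g <- rep(c("a", "b", "c"), each = 3)
  expect_equal(kruskal_wallis(v, g)$H, kruskal_wallis(exp(v), g)$H,
               tolerance = 1e-12)
})
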