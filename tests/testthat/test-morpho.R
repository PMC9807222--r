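test_that("tissue areas are pixel counts times squared pixel size", {
  lab <- matrix(1L, 100, 100)
  sec <- labeled_section(lab, pixel_size = 0.1)
  ar <- tissue_areas(sec)
  expect_equal(unname(ar[["pith"]]), 100)
  expect_equal(unname(ar[["wood2"]]), 0)  # absent tissue reports zero
  expect_error(labeled_section(matrix(0L, 5, 5), 0.1), "empty")
})

test_that("centroid is the mean of non-background pixel centers", {
  # two-pixel section at rows 1 and 3 of one column: midpoint at row 2
  lab <- matrix(0L, 5, 5)
  lab[1, 3] <- 1L; lab[3, 3] <- 1L
  ctr <- section_centroid(labeled_section(lab, 1))
  expect_equal(unname(ctr["y"]), 1.5)  # pixel centers at 0.5 and 2.5
  expect_equal(unname(ctr["x"]), 2.5)
  # centered ellipse: centroid at canvas center within half a pixel
  l <- build_layout(layout_spec("fixed", 4, c(0.3, 0.3, 0.1, 0.3),
                                ellipse_ratio = 0.9))
  sec <- rasterize(l, 0.02)
  ctr2 <- section_centroid(sec)
  expect_lt(abs(ctr2[["x"]] - ncol(sec$labels) * 0.02 / 2), 0.01)
  expect_lt(abs(ctr2[["y"]] - nrow(sec$labels) * 0.02 / 2), 0.01)
})

test_that("centroid and per-tissue I match the brute-force oracle", {
  l <- build_layout(layout_spec("climbing", 3, c(0.3, 0.35, 0.05, 0.3),
                                wood2_mode = "lobes", lobe_count = 3,
                                lobe_arc = 35, lobe_phase = 55,
                                ellipse_ratio = 0.9))
  sec <- rasterize(l, 3 / 40)  # coarse on purpose: oracle is O(pixels)
  oracle <- oracle_section_moments(sec$labels, sec$pixel_size)
  expect_equal(section_centroid(sec), oracle$centroid, tolerance = 1e-12)
  expect_equal(unname(tissue_second_moments(sec)), oracle$I,
               tolerance = 1e-12)
})

test_that("pixel-integrated I converges to ellipse closed forms", {
  # full ellipse a = 2, b = 1: I = (pi/4) a^3 b = 2 pi
  l <- build_layout(layout_spec("fixed", 4, c(1, 0, 0, 0),
                                ellipse_ratio = 0.5))
  sec <- rasterize(l, 0.005)
  m <- measure_section(sec)
  expect_lt(abs(m$I_total / (2 * pi) - 1), 0.005)
  # elliptical annulus (cortex ring) against the closed-form oracle
  l2 <- build_layout(layout_spec("fixed", 4, c(0.2, 0.3, 0.1, 0.4),
                                 ellipse_ratio = 0.8))
  sec2 <- rasterize(l2, 0.005)
  I_meas <- tissue_second_moments(sec2)
  I_ref <- ellipse_annulus_I(l2$a[4], l2$b[4], l2$a[3], l2$b[3])
  expect_lt(abs(I_meas[["cortex"]] / I_ref - 1), 0.005)
})

test_that("per-tissue I about the common axis is exactly additive", {
  l <- build_layout(layout_spec("climbing", 3, c(0.3, 0.3, 0.1, 0.3)))
  sec <- rasterize(l, 0.01)
  I_t <- tissue_second_moments(sec)
  whole <- sec
  whole$labels[whole$labels > 0L] <- 1L
  I_whole <- tissue_second_moments(whole)
  expect_equal(sum(I_t), sum(I_whole), tolerance = 1e-12)
})

test_that("ellipse_annulus_I closed forms and raster cross-check", {
  expect_equal(ellipse_annulus_I(1, 1), pi / 4)
  expect_equal(ellipse_annulus_I(2, 2, 1, 1), (pi / 4) * 15)
  expect_error(ellipse_annulus_I(1, 1, 2, 2), "exceed")
  # raster oracle cross-check of the same annulus
  l <- build_layout(layout_spec("fixed", 4, c(0.25, 0, 0, 0.75)))
  sec <- rasterize(l, 0.005)
  I_meas <- tissue_second_moments(sec)[["cortex"]]
  expect_lt(abs(I_meas / ellipse_annulus_I(2, 2, 1, 1) - 1), 0.005)
})

test_that("percent contributions normalize and rank outer annuli highest", {
  # single-tissue section: 100% for that tissue
  l <- build_layout(layout_spec("self-supporting", 3, c(1, 0, 0, 0)))
  m <- measure_section(rasterize(l, 0.01))
  expect_equal(unname(m$pct_area[["pith"]]), 100)
  expect_equal(unname(m$pct_I[["pith"]]), 100)
  # equal-area four-ring layout: outer annuli dominate I
  l4 <- build_layout(layout_spec("fixed", 4, c(0.25, 0.25, 0.25, 0.25)))
  m4 <- measure_section(rasterize(l4, 0.01))
  expect_true(m4$pct_I[["cortex"]] > m4$pct_I[["wood2"]])
  expect_true(m4$pct_I[["wood2"]] > m4$pct_I[["wood1"]])
  expect_true(m4$pct_I[["wood1"]] > m4$pct_I[["pith"]])
  expect_equal(sum(m4$pct_area), 100, tolerance = 1e-6)
  expect_equal(sum(m4$pct_I), 100, tolerance = 1e-6)
})

test_that("central pith contributes far less to I than to area", {
  f <- c(33.62, 32.35, 0.67, 33.36)
  m <- measure_section(rasterize(build_layout(
    layout_spec("self-supporting", 3.22, f / sum(f))), 3.22 / 400))
  expect_lt(m$pct_I[["pith"]], 0.5 * m$pct_area[["pith"]])
})

test_that("metrics are invariant to rotation and canvas padding", {
  l <- build_layout(layout_spec("fixed", 4, c(0.3, 0.3, 0.1, 0.3)))
  sec <- rasterize(l, 0.01)
  m <- measure_section(sec)
  # 90-degree rotation of a circular section
  rot <- labeled_section(t(sec$labels)[ncol(sec$labels):1, ],
                         sec$pixel_size)
  m_rot <- measure_section(rot)
  expect_lt(abs(m_rot$I_total / m$I_total - 1), 0.005)
  # padding the canvas changes nothing
  pad <- cbind(matrix(0L, nrow(sec$labels) + 10, 5),
               rbind(matrix(0L, 10, ncol(sec$labels)), sec$labels))
  m_pad <- measure_section(labeled_section(pad, sec$pixel_size))
  expect_equal(m_pad$I, m$I, tolerance = 1e-12)
  expect_equal(m_pad$area, m$area, tolerance = 1e-12)
})
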