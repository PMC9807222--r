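test_that("fit_slope recovers exact and offset lines, flags nonlinearity", {
  d <- c(1, 2, 3, 4, 5, 6)
  f1 <- fit_slope(0.06 * d, d)
  expect_equal(f1$slope, 0.06, tolerance = 1e-12)
  expect_equal(f1$r_squared, 1, tolerance = 1e-12)
  expect_false(f1$linearity_warning)
  # intercept absorbed
  f2 <- fit_slope(0.06 * d + 0.5, d)
  expect_equal(f2$slope, 0.06, tolerance = 1e-12)
  expect_equal(f2$intercept, 0.5, tolerance = 1e-12)
  # strongly curved data trips the linearity warning
  f3 <- fit_slope(c(0.1, 0.2, 1, 4, 9, 20), d)
  expect_true(f3$linearity_warning)
  expect_error(fit_slope(c(1, 2, 3), c(1, 1, 1)), "variance")
})

test_that("noisy slope matches the closed-form OLS oracle", {
  set.seed(42)
  for (rep in 1:5) {
    d_true <- seq(0.4, 2.4, length.out = 6)
    d_obs <- d_true + rnorm(6, 0, 0.02)
    F <- 0.06 * d_true
    fit <- fit_slope(F, d_obs)
    expect_equal(fit$slope, oracle_ols_slope(d_obs, F), tolerance = 1e-12)
    expect_lt(abs(fit$slope / 0.06 - 1), 0.05)
  }
})

test_that("flexural stiffness, ellipse I and Young's modulus closed forms", {
  expect_equal(flexural_stiffness(1, 48), 1)
  expect_equal(flexural_stiffness(200, 0.06), 10000)
  expect_equal(ellipse_I(c(1, 1, 1), c(1, 1, 1)), pi / 4)
  expect_equal(ellipse_I(c(2, 2, 2), c(1, 1, 1)), 2 * pi)
  expect_error(ellipse_I(c(1, -1, 1), c(1, 1, 1)), "positive")
  expect_equal(youngs_modulus(10000, 4), 2500)
  expect_equal(youngs_modulus(1, 1), 1)
  expect_error(youngs_modulus(1, 0), "positive")
})

test_that("reduce_test composes the closed-form chain", {
  bt <- bending_test(span = 200, a = rep(2, 3), b = rep(1.5, 3),
                     force = 0.06 * c(5, 10, 15, 20),
                     deflection = c(5, 10, 15, 20))
  tr <- reduce_test(bt)
  expect_equal(tr$slope, 0.06, tolerance = 1e-12)
  expect_equal(tr$EI, 200^3 * 0.06 / 48, tolerance = 1e-12)
  expect_equal(tr$I, (pi / 4) * 8 * 1.5, tolerance = 1e-12)
  expect_equal(tr$E, tr$EI / tr$I, tolerance = 1e-12)
  expect_equal(tr$diameter, (4 + 3) / 2)
  expect_equal(tr$span_to_depth, 200 / 4)
  # dimensional consistency
  expect_equal(tr$E * tr$I, tr$EI, tolerance = 1e-9)
})

test_that("invalid bending records are rejected at validation", {
  expect_error(bending_test(200, rep(2, 3), rep(2, 3),
                            force = c(3, 2, 1), deflection = c(1, 2, 3)),
               "strictly increasing")
  expect_error(bending_test(200, rep(2, 3), rep(2, 3),
                            force = c(1, 2), deflection = c(1, 2)),
               "at least 3")
  expect_error(bending_test(200, c(2, 0, 2), rep(2, 3),
                            force = 1:3, deflection = 1:3),
               "positive")
})

test_that("scaling lengths by k scales I by k^4 and leaves E unchanged", {
  for (k in c(0.5, 2, 3)) {
    I1 <- ellipse_I(rep(2, 3), rep(1.5, 3))
    Ik <- ellipse_I(rep(2 * k, 3), rep(1.5 * k, 3))
    expect_equal(Ik / I1, k^4, tolerance = 1e-12)
    E <- 3000
    bt <- simulate_bending(E * Ik, span = 80 * k,
                           masses = rep(E * Ik * 2 / ((80 * k)^3 / 48) / (9.81 * 5), 5),
                           a = 2 * k, b = 1.5 * k)
    expect_equal(reduce_test(bt)$E, E, tolerance = 1e-9)
  }
})

test_that("span-to-depth screening finds the shear plateau", {
  EI <- 10000; a <- 2.5; b <- 2.5
  spans <- c(10, 20, 30, 40, 60) * (2 * a)
  shear <- list(E_over_G = 20, shear_factor = 10 / 9)
  mk <- function(span, sh) {
    Ff <- 2 * 48 * EI / span^3
    simulate_bending(EI, span, rep(Ff / (9.81 * 5), 5), a, b, shear = sh,
                     elastic_window = c(0, Inf))
  }
  # shear-free: apparent E constant, smallest tested ratio returned
  res0 <- span_to_depth_analysis(lapply(spans, mk, sh = NULL))
  expect_true(res0$plateau_reached)
  expect_equal(res0$threshold_ratio, 10)
  # with shear: apparent E strictly increasing, threshold at 20 or above
  res <- span_to_depth_analysis(lapply(spans, mk, sh = shear))
  expect_true(all(diff(res$table$apparent_E) > 0))
  expect_gte(res$threshold_ratio, 20)
  # all tested spans still rising: flagged, no ratio
  strong <- list(E_over_G = 400, shear_factor = 10 / 9)
  res2 <- span_to_depth_analysis(lapply(c(4, 6, 8) * (2 * a), mk, sh = strong))
  expect_false(res2$plateau_reached)
  expect_true(is.na(res2$threshold_ratio))
  expect_error(span_to_depth_analysis(lapply(c(100, 100, 200), mk, sh = NULL)),
               "distinct")
})
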