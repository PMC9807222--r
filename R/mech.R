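#' Three-point bending test record
#'
#' One bending test of a stem segment: the span between supports, caliper
#' semi-axis measurements taken at the segment center and 25% proximally and
#' distally (vertical `a`, in the load direction, and horizontal `b`), and the
#' sequence of cumulative applied forces with the midspan deflections they
#' produced.
#'
#' @param span Span between supports (mm).
#' @param a Three vertical semi-axis measurements (mm).
#' @param b Three horizontal semi-axis measurements (mm).
#' @param force Applied forces (N), strictly increasing, length >= 3.
#' @param deflection Midspan deflections (mm), same length as `force`.
#' @param specimen_id Optional identifier.
#' @param elastic_window Deflection window (mm) regarded as safely elastic;
#'   deflections outside it set the `elastic_warning` flag (the record is kept,
#'   not rejected).
#' @return An object of class `bending_test`.
#' @export
bending_test <- function(span, a, b, force, deflection,
                         specimen_id = NULL,
                         elastic_window = c(0.2, 5)) {
  stopifnot(is.numeric(span), length(span) == 1L, span > 0)
  if (length(a) != 3L || length(b) != 3L) {
    stop("`a` and `b` must each hold three caliper measurements")
  }
  if (any(a <= 0) || any(b <= 0)) stop("all radii must be positive")
  if (length(force) != length(deflection)) {
    stop("`force` and `deflection` must have equal length")
  }
  if (length(force) < 3L) stop("a bending test needs at least 3 loading points")
  if (any(diff(force) <= 0)) stop("forces must be strictly increasing")
  if (any(!is.finite(force)) || any(!is.finite(deflection))) {
    stop("forces and deflections must be finite")
  }
  structure(
    list(specimen_id = specimen_id,
         span = span, a = as.numeric(a), b = as.numeric(b),
         force = as.numeric(force), deflection = as.numeric(deflection),
         elastic_warning = any(deflection < elastic_window[1] |
                               deflection > elastic_window[2])),
    class = "bending_test"
  )
}

#' @export
print.bending_test <- function(x, ...) {
  cat("Bending test", if (!is.null(x$specimen_id)) paste0("'", x$specimen_id, "'"),
      sprintf("span %.4g mm, %d loading points%s\n", x$span, length(x$force),
              if (x$elastic_warning) " [elastic-window warning]" else ""))
  invisible(x)
}

#' Slope of the force-deflection curve
#'
#' Ordinary least-squares fit of force against deflection with a fitted
#' intercept (pannier settling offsets are absorbed by the intercept; only the
#' slope is used downstream). An R-squared below 0.99 raises the
#' `linearity_warning` flag, suggesting loading beyond the elastic limit.
#'
#' @param force Forces (N), or a [bending_test()] in which case `deflection`
#'   is taken from the record.
#' @param deflection Deflections (mm), all positive.
#' @return List with `slope` (N/mm), `intercept` (N), `r_squared`, and
#'   `linearity_warning`.
#' @export
fit_slope <- function(force, deflection = NULL) {
  if (inherits(force, "bending_test")) {
    deflection <- force$deflection
    force <- force$force
  }
  stopifnot(length(force) == length(deflection), length(force) >= 3L)
  if (any(deflection <= 0)) stop("deflections must be positive")
  if (stats::var(deflection) == 0) {
    stop("zero deflection variance: cannot fit a slope")
  }
  fit <- stats::lm.fit(cbind(1, deflection), force)
  slope <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((force - mean(force))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = slope,
       intercept = unname(fit$coefficients[1]),
       r_squared = r2,
       linearity_warning = r2 < 0.99)
}

#' Flexural stiffness from span and slope
#'
#' `EI = l^3 * b / 48` for a three-point bending test of span `l` (mm) with
#' force-deflection slope `b` (N/mm).
#'
#' @param span Span (mm), > 0.
#' @param slope Slope of the force-deflection curve (N/mm), > 0.
#' @return Flexural stiffness EI in N mm^2.
#' @export
flexural_stiffness <- function(span, slope) {
  stopifnot(span > 0, slope > 0)
  span^3 * slope / 48
}

#' Second moment of area of the stem approximated as an ellipse
#'
#' `I = (pi/4) * a_bar^3 * b_bar` with `a_bar`, `b_bar` the arithmetic means
#' of the three vertical (load-direction) and horizontal semi-axis
#' measurements.
#'
#' @param a Three vertical semi-axis measurements (mm), positive.
#' @param b Three horizontal semi-axis measurements (mm), positive.
#' @return Second moment of area in mm^4.
#' @export
ellipse_I <- function(a, b) {
  stopifnot(length(a) == 3L, length(b) == 3L)
  if (any(a <= 0) || any(b <= 0)) stop("all radii must be positive")
  (pi / 4) * mean(a)^3 * mean(b)
}

#' Young's modulus from flexural stiffness and second moment of area
#'
#' `E = EI / I`; with EI in N mm^2 and I in mm^4 the result is in
#' N/mm^2 = MPa (equivalently MN m^-2).
#'
#' @param EI Flexural stiffness (N mm^2).
#' @param I Second moment of area (mm^4), > 0.
#' @return Young's modulus in MPa.
#' @export
youngs_modulus <- function(EI, I) {
  if (I <= 0) stop("second moment of area must be positive")
  EI / I
}

#' Reduce one bending test to mechanical traits
#'
#' Composition of the reduction chain: slope of the force-deflection curve,
#' `EI = l^3 b / 48`, `I = (pi/4) a_bar^3 b_bar` from the caliper means, and
#' `E = EI / I`. The reported diameter is the mean of the vertical and
#' horizontal caliper diameters; the span-to-depth ratio uses the vertical
#' (load-direction) diameter as depth.
#'
#' @param test A [bending_test()].
#' @return One-row tibble with columns `specimen_id`, `span`, `slope`,
#'   `r_squared`, `EI`, `I`, `E`, `diameter`, `span_to_depth`,
#'   `elastic_warning`, `linearity_warning`.
#' @export
reduce_test <- function(test) {
  stopifnot(inherits(test, "bending_test"))
  fit <- fit_slope(test)
  EI <- flexural_stiffness(test$span, fit$slope)
  I <- ellipse_I(test$a, test$b)
  E <- youngs_modulus(EI, I)
  abar <- mean(test$a)
  bbar <- mean(test$b)
  tibble::tibble(
    specimen_id = if (is.null(test$specimen_id)) NA_character_
                  else as.character(test$specimen_id),
    span = test$span,
    slope = fit$slope,
    r_squared = fit$r_squared,
    EI = EI, I = I, E = E,
    diameter = (2 * abar + 2 * bbar) / 2,
    span_to_depth = test$span / (2 * abar),
    elastic_warning = test$elastic_warning,
    linearity_warning = fit$linearity_warning
  )
}

#' Span-to-depth screening analysis
#'
#' Given bending tests of the same specimen region at several distinct spans,
#' computes the apparent Young's modulus per span and returns the smallest
#' tested span-to-depth ratio whose apparent E reaches at least `plateau`
#' (default 95%) of the value at the largest tested span. When shear
#' deflection is appreciable, apparent E rises with span toward its true
#' value; a specimen where only the largest tested span qualifies has not
#' demonstrated a plateau and is flagged with no ratio returned.
#'
#' @param tests List of [bending_test()]s at >= 3 distinct spans.
#' @param plateau Fraction of the largest-span apparent E that counts as
#'   converged (default 0.95).
#' @return List with `table` (tibble of span, span_to_depth, apparent E),
#'   `threshold_ratio` (smallest adequate span-to-depth, or `NA`), and
#'   `plateau_reached` (logical).
#' @export
span_to_depth_analysis <- function(tests, plateau = 0.95) {
  stopifnot(is.list(tests), length(tests) >= 3L)
  traits <- do.call(rbind, lapply(tests, reduce_test))
  if (anyDuplicated(traits$span)) stop("spans must be distinct")
  traits <- traits[order(traits$span_to_depth), ]
  ref <- traits$E[nrow(traits)]
  ok <- traits$E >= plateau * ref
  first_ok <- which(ok)[1]
  plateau_reached <- first_ok < nrow(traits)
  list(
    table = tibble::tibble(span = traits$span,
                           span_to_depth = traits$span_to_depth,
                           apparent_E = traits$E),
    threshold_ratio = if (plateau_reached) traits$span_to_depth[first_ok] else NA_real_,
    plateau_reached = plateau_reached
  )
}
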