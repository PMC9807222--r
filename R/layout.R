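#' Specification of a synthetic stem cross-section layout
#'
#' A `layout_spec` describes one stem cross-section as a set of target tissue
#' area fractions to be realized as nested elliptical annuli: pith at the
#' center, then early dense wood (TYPE I), then compliant lianoid wood
#' (TYPE II, either absent, a set of discontinuous lobes, or a complete ring),
#' then the cortex.
#'
#' @param category Stem growth category, one of `"self-supporting"`,
#'   `"pendulous"`, `"climbing"`, `"fixed"`.
#' @param outer_diameter Outer vertical diameter of the section in mm
#'   (the vertical direction is the load direction in bending).
#' @param target_fractions Numeric length-4 vector of area fractions in the
#'   order pith, wood1, wood2, cortex; each in `[0, 1]`, summing to 1 within
#'   `1e-9`.
#' @param ellipse_ratio Ratio of horizontal to vertical semi-axis of the outer
#'   boundary, in `(0, 1]`; 1 gives a circular section.
#' @param wood2_mode How the TYPE II wood fraction is arranged: `"none"`
#'   (fraction must be 0), `"lobes"` (discontinuous arcs), or `"ring"`
#'   (complete annulus). When omitted it defaults to `"ring"` for a positive
#'   TYPE II fraction and `"none"` otherwise.
#' @param lobe_count Number of TYPE II lobes (lobes mode only).
#' @param lobe_arc Angular width of each lobe in degrees; the total coverage
#'   `lobe_count * lobe_arc` must not exceed 360.
#' @param lobe_phase Angular position (degrees) of the first lobe center;
#'   lobes are uniformly spaced from there.
#'
#' @return An object of class `layout_spec`.
#' @seealso [build_layout()]
#' @export
layout_spec <- function(category,
                        outer_diameter,
                        target_fractions,
                        ellipse_ratio = 1,
                        wood2_mode = c("none", "lobes", "ring"),
                        lobe_count = 0L,
                        lobe_arc = 0,
                        lobe_phase = 0) {
  category <- match.arg(category, stem_categories())
  auto_mode <- missing(wood2_mode)
  wood2_mode <- match.arg(wood2_mode)
  if (auto_mode && length(target_fractions) == 4L &&
      is.finite(target_fractions[3]) && target_fractions[3] > 1e-9) {
    wood2_mode <- "ring"
  }
  stopifnot(is.numeric(outer_diameter), length(outer_diameter) == 1L,
            outer_diameter > 0)
  if (length(target_fractions) != 4L || any(!is.finite(target_fractions))) {
    stop("`target_fractions` must be four finite numbers (pith, wood1, wood2, cortex)")
  }
  if (any(target_fractions < 0) || any(target_fractions > 1)) {
    stop("tissue fractions must lie in [0, 1]")
  }
  if (abs(sum(target_fractions) - 1) > 1e-9) {
    stop("tissue fractions must sum to 1 (within 1e-9); got ",
         format(sum(target_fractions), digits = 12))
  }
  stopifnot(ellipse_ratio > 0, ellipse_ratio <= 1)
  if (wood2_mode == "none" && target_fractions[3] > 1e-9) {
    stop("wood2_mode = \"none\" requires a zero TYPE II wood fraction")
  }
  if (wood2_mode == "lobes") {
    if (lobe_count < 1) stop("lobes mode requires lobe_count >= 1")
    if (lobe_arc <= 0) stop("lobes mode requires lobe_arc > 0")
    if (lobe_count * lobe_arc > 360 + 1e-9) {
      stop("lobe_count * lobe_arc must not exceed 360 degrees")
    }
  }
  fr <- as.numeric(target_fractions)
  names(fr) <- tissue_names()
  structure(
    list(category = category,
         outer_diameter = outer_diameter,
         target_fractions = fr,
         ellipse_ratio = ellipse_ratio,
         wood2_mode = wood2_mode,
         lobe_count = as.integer(lobe_count),
         lobe_arc = lobe_arc,
         lobe_phase = lobe_phase),
    class = "layout_spec"
  )
}

#' Tissue and category name constants
#'
#' @return `tissue_names()` returns the four tissue labels in raster label
#'   order (labels 1--4); `stem_categories()` the four trellis stem growth
#'   categories.
#' @export
tissue_names <- function() c("pith", "wood1", "wood2", "cortex")

#' @rdname tissue_names
#' @export
stem_categories <- function() c("self-supporting", "pendulous", "climbing", "fixed")

#' Realize a layout specification as nested elliptical boundaries
#'
#' Solves for the semi-axes of the four nested elliptical boundaries
#' (pith/wood1, wood1/wood2, wood2/cortex, cortex/outside) whose annulus areas
#' reproduce the target tissue fractions. All boundaries share the outer
#' ellipse's aspect ratio, so for vertical semi-axis `a_i` the enclosed area is
#' `pi * ratio * a_i^2` and nesting reduces to cumulative-area square roots.
#'
#' In lobes mode the TYPE II wood occupies `lobe_count` arcs of `lobe_arc`
#' degrees of the wood2 annulus and the remainder of that annulus is assigned
#' to TYPE I wood; the annulus is widened so the arcs alone carry the full
#' TYPE II target fraction. This is infeasible when the TYPE I fraction is too
#' small to absorb the remainder, in which case an error is raised.
#'
#' @param spec A [layout_spec()].
#' @return An object of class `tissue_layout` with elements `a` and `b`
#'   (length-4 vectors of vertical/horizontal semi-axes in mm, strictly
#'   nondecreasing), the lobe geometry, and the originating spec.
#' @export
build_layout <- function(spec) {
  stopifnot(inherits(spec, "layout_spec"))
  f <- spec$target_fractions
  R <- spec$outer_diameter / 2
  q <- spec$ellipse_ratio
  if (spec$wood2_mode == "lobes" && f[["wood2"]] > 0) {
    kappa <- spec$lobe_count * spec$lobe_arc / 360
    a1 <- R * sqrt(f[["pith"]])
    a3 <- R * sqrt(f[["pith"]] + f[["wood1"]] + f[["wood2"]])
    a2_sq <- a3^2 - f[["wood2"]] * R^2 / kappa
    if (a2_sq < a1^2 - 1e-12 * R^2) {
      stop("infeasible layout: TYPE I wood fraction (", signif(f[["wood1"]], 4),
           ") cannot absorb the non-lobe remainder of the TYPE II annulus at ",
           "coverage ", signif(kappa, 4),
           "; need wood1 >= wood2 * (1/coverage - 1)")
    }
    a2 <- sqrt(max(a2_sq, a1^2))
    a <- c(a1, a2, a3, R)
  } else {
    cum <- unname(cumsum(f))
    a <- R * sqrt(pmin(cum, 1))
    a[4] <- R
  }
  centers <- if (spec$wood2_mode == "lobes" && f[["wood2"]] > 0) {
    (spec$lobe_phase + (seq_len(spec$lobe_count) - 1) * 360 / spec$lobe_count) %% 360
  } else {
    numeric(0)
  }
  structure(
    list(a = a, b = q * a,
         ellipse_ratio = q,
         wood2_mode = if (f[["wood2"]] > 0) spec$wood2_mode else "none",
         lobe_centers = centers,
         lobe_arc = spec$lobe_arc,
         spec = spec),
    class = "tissue_layout"
  )
}

#' @export
print.tissue_layout <- function(x, ...) {
  cat("Tissue layout (", x$spec$category, "), outer diameter ",
      format(2 * x$a[4]), " mm\n", sep = "")
  cat("  boundary semi-axes a (mm):", format(signif(x$a, 5)), "\n")
  cat("  wood TYPE II mode:", x$wood2_mode,
      if (x$wood2_mode == "lobes") sprintf("(%d lobes of %g deg)",
                                           length(x$lobe_centers), x$lobe_arc),
      "\n")
  invisible(x)
}

# fraction of the wood2 annulus covered by lobes (1 for ring, 0 for none)
lobe_coverage <- function(layout) {
  switch(layout$wood2_mode,
         ring = 1,
         lobes = length(layout$lobe_centers) * layout$lobe_arc / 360,
         none = 0)
}

#' Analytic tissue areas of a layout
#'
#' Exact areas (mm^2) of the four tissue regions implied by the nested
#' elliptical boundaries, before any rasterization.
#'
#' @param layout A [build_layout()] result.
#' @return Named numeric vector over [tissue_names()] plus `total`.
#' @export
layout_tissue_areas <- function(layout) {
  stopifnot(inherits(layout, "tissue_layout"))
  q <- layout$ellipse_ratio
  a <- layout$a
  ann <- pi * q * diff(c(0, a^2))  # pith, ring1, ring2, ring3
  kappa <- lobe_coverage(layout)
  areas <- c(
    pith   = ann[1],
    wood1  = ann[2] + (1 - kappa) * ann[3],
    wood2  = kappa * ann[3],
    cortex = ann[4]
  )
  c(areas, total = sum(areas))
}

# integral of cos^2(theta) over [t0, t1] (radians)
.int_cos2 <- function(t0, t1) {
  (t1 - t0) / 2 + (sin(2 * t1) - sin(2 * t0)) / 4
}

#' Analytic second moments of area of a layout
#'
#' Exact second moments of area (mm^4) of each tissue region about the
#' horizontal axis through the section center (the bending axis; the load acts
#' vertically). For an elliptical annulus with vertical semi-axes `a_in`,
#' `a_out` and aspect ratio `q` the full-annulus value is
#' `(pi/4) * q * (a_out^4 - a_in^4)`; lobe arcs are integrated in scaled polar
#' coordinates, where the angular factor reduces to the integral of
#' `cos^2(theta)` over the covered arcs.
#'
#' @inheritParams layout_tissue_areas
#' @return Named numeric vector over [tissue_names()] plus `total`.
#' @export
layout_tissue_I <- function(layout) {
  stopifnot(inherits(layout, "tissue_layout"))
  q <- layout$ellipse_ratio
  a <- layout$a
  full <- (pi / 4) * q * diff(c(0, a^4))  # pith, ring1, ring2, ring3
  if (layout$wood2_mode == "lobes") {
    half <- layout$lobe_arc * pi / 360
    centers <- layout$lobe_centers * pi / 180
    ang <- sum(vapply(centers, function(ct) .int_cos2(ct - half, ct + half),
                      numeric(1)))
    I2 <- q * (a[3]^4 - a[2]^4) / 4 * ang
  } else {
    I2 <- lobe_coverage(layout) * full[3]
  }
  I <- c(
    pith   = full[1],
    wood1  = full[2] + (full[3] - I2),
    wood2  = I2,
    cortex = full[4]
  )
  c(I, total = sum(I))
}

#' Rasterize a tissue layout into a labeled section
#'
#' Labels each pixel by membership of its center point: 0 background, 1 pith,
#' 2 wood TYPE I, 3 wood TYPE II, 4 cortex. Rows run vertically (row 1 at the
#' top, y increasing downward) with pixel centers at half-integer multiples of
#' the pixel size; the canvas pads the section by at least 2 pixels on every
#' side. Boundary pixels whose centers fall exactly on an elliptical boundary
#' belong to the inner region.
#'
#' @param layout A [build_layout()] result.
#' @param pixel_size Pixel edge length in mm; must not exceed 1/20 of the
#'   outer diameter.
#' @return A [labeled_section()].
#' @export
rasterize <- function(layout, pixel_size) {
  stopifnot(inherits(layout, "tissue_layout"))
  d <- 2 * layout$a[4]
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (mm)")
  }
  if (pixel_size > d / 20) {
    stop("pixel_size too coarse: need pixel_size <= outer_diameter/20 = ",
         format(d / 20), " mm")
  }
  p <- pixel_size
  a <- layout$a
  q <- layout$ellipse_ratio
  nrow_ <- ceiling(2 * a[4] / p) + 4L
  ncol_ <- ceiling(2 * layout$b[4] / p) + 4L
  cy <- nrow_ * p / 2
  cx <- ncol_ * p / 2
  yc <- (seq_len(nrow_) - 0.5) * p - cy
  xc <- (seq_len(ncol_) - 0.5) * p - cx
  # effective radius in scaled polar coordinates (x scaled by 1/q)
  rho <- sqrt(outer(yc^2, (xc / q)^2, `+`))
  lab <- matrix(0L, nrow_, ncol_)
  lab[rho <= a[4]] <- 4L
  in3 <- rho <= a[3]
  if (layout$wood2_mode == "lobes") {
    theta <- atan2(outer(rep(1, nrow_), xc), outer(yc, rep(1, ncol_))) * 180 / pi
    in_lobe <- matrix(FALSE, nrow_, ncol_)
    for (ct in layout$lobe_centers) {
      dang <- ((theta - ct + 180) %% 360) - 180
      in_lobe <- in_lobe | abs(dang) <= layout$lobe_arc / 2
    }
    lab[in3 & in_lobe] <- 3L
    lab[in3 & !in_lobe] <- 2L
  } else if (layout$wood2_mode == "ring") {
    lab[in3] <- 3L
  } else {
    lab[in3] <- 2L
  }
  lab[rho <= a[2]] <- 2L
  lab[rho <= a[1]] <- 1L
  labeled_section(lab, pixel_size = p, id = NULL)
}
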