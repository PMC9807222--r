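#' Per-category tissue fraction profiles
#'
#' Mean and SD of the percent area of each tissue (pith, wood TYPE I, wood
#' TYPE II, cortex) for the four trellis stem categories, as observed in the
#' narrow-diameter field sample of the study system; means are normalized to
#' sum to 1. These are the default targets of the cohort generator.
#'
#' @return A tibble with columns `category`, `tissue`, `mean_fraction`,
#'   `sd_fraction`.
#' @export
category_fraction_profiles <- function() {
  cats <- stem_categories()
  # percent area mean / sd per tissue, order: pith, wood1, wood2, cortex
  means <- rbind(
    `self-supporting` = c(33.62, 32.35, 0.67, 33.36),
    pendulous         = c(27.75, 38.92, 1.39, 31.95),
    climbing          = c(27.45, 26.35, 10.17, 36.02),
    fixed             = c(28.44, 22.57, 12.54, 36.45)
  )
  sds <- rbind(
    `self-supporting` = c(8.42, 8.62, 2.24, 3.98),
    pendulous         = c(6.21, 8.55, 2.89, 4.42),
    climbing          = c(8.45, 10.46, 8.96, 4.19),
    fixed             = c(8.76, 9.59, 8.31, 3.65)
  )
  means <- means / rowSums(means)
  tibble::tibble(
    category = rep(cats, each = 4L),
    tissue = rep(tissue_names(), times = 4L),
    mean_fraction = as.vector(t(means[cats, ])),
    sd_fraction = as.vector(t(sds[cats, ])) / 100
  )
}

#' Default ground-truth tissue moduli
#'
#' Young's modulus (MPa) assigned to each tissue when composing the
#' ground-truth flexural stiffness of synthetic stems:
#' `EI = sum_t E_t * I_t`. Dense TYPE I wood is the stiffness driver; lianoid
#' TYPE II wood is markedly softer; pith and cortex are soft. The values put
#' composite stem moduli in the 1500-3000 MPa regime typical of young liana
#' trellis stems.
#'
#' @return Named numeric vector over [tissue_names()].
#' @export
default_tissue_moduli <- function() {
  c(pith = 50, wood1 = 6500, wood2 = 800, cortex = 300)
}

#' Configuration of a synthetic cohort
#'
#' @param counts Named integer vector of specimen counts per category
#'   (defaults mirror a balanced sample of the four categories).
#' @param diameter_range Outer-diameter sampling range (mm), uniform.
#' @param threshold_rule If `TRUE` (default), self-supporting and pendulous
#'   stems are capped at `threshold_diameter`, reproducing the observed
#'   developmental cutoff above which only attached stems keep growing.
#' @param threshold_diameter Cap diameter (mm), default 5.9.
#' @param moduli Ground-truth tissue moduli (MPa), see
#'   [default_tissue_moduli()].
#' @param noise List with `deflection_sd` and `radius_sd` (mm); both 0 for a
#'   noiseless cohort.
#' @param shear `NULL` for pure bending, or a list with `E_over_G` and
#'   `shear_factor` (see [simulate_bending()]).
#' @param span_to_depth Target span-to-depth ratio of the simulated tests
#'   (default 40).
#' @param tests_range Range of bending tests per specimen (default 1 to 3).
#' @param rasterize If `TRUE`, each specimen also gets a rasterized labeled
#'   section.
#' @param pixels_per_diameter Raster resolution: pixel size is
#'   `diameter / pixels_per_diameter` (default 400).
#' @param fraction_jitter Multiplier on the per-category fraction SDs (1 =
#'   field-like spread, 0 = every specimen exactly at the category mean).
#' @param seed Integer seed fixing the full cohort bit-for-bit.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(counts = c(`self-supporting` = 13, pendulous = 13,
                                     climbing = 13, fixed = 13),
                          diameter_range = c(1.8, 10),
                          threshold_rule = TRUE,
                          threshold_diameter = 5.9,
                          moduli = default_tissue_moduli(),
                          noise = list(deflection_sd = 0, radius_sd = 0),
                          shear = NULL,
                          span_to_depth = 40,
                          tests_range = c(1L, 3L),
                          rasterize = TRUE,
                          pixels_per_diameter = 400,
                          fraction_jitter = 1,
                          seed = 1L) {
  stopifnot(all(counts >= 0), all(names(counts) %in% stem_categories()))
  stopifnot(length(diameter_range) == 2L, diameter_range[1] > 0,
            diameter_range[2] >= diameter_range[1])
  stopifnot(is.null(noise) ||
              (noise$deflection_sd >= 0 && noise$radius_sd >= 0))
  stopifnot(all(tissue_names() %in% names(moduli)), all(moduli > 0))
  stopifnot(span_to_depth > 0, fraction_jitter >= 0)
  structure(
    list(counts = counts, diameter_range = diameter_range,
         threshold_rule = threshold_rule,
         threshold_diameter = threshold_diameter,
         moduli = moduli[tissue_names()], noise = noise, shear = shear,
         span_to_depth = span_to_depth,
         tests_range = as.integer(tests_range),
         rasterize = rasterize,
         pixels_per_diameter = pixels_per_diameter,
         fraction_jitter = fraction_jitter,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# draw one specimen's tissue fractions around its category profile
draw_fractions <- function(mu, sd, jitter) {
  f <- stats::rnorm(4, mu, sd * jitter)
  f[f < 0] <- 0
  # keep structural tissues present; wood2 may be exactly absent
  f[c(1, 2, 4)] <- pmax(f[c(1, 2, 4)], 0.02)
  if (f[3] < 0.004) f[3] <- 0
  f / sum(f)
}

#' Generate a synthetic cohort with known ground truth
#'
#' For each specimen: draws a diameter (uniform over the configured range,
#' capped for unattached categories when the developmental threshold rule is
#' on), draws tissue fractions around the category profile, builds the nested
#' elliptical layout (TYPE II wood as lobes when its fraction is small, as a
#' complete ring otherwise), computes the analytic per-tissue areas and second
#' moments, composes the ground-truth flexural stiffness
#' `EI = sum_t E_t I_t` and composite modulus `E = EI / I_total`, simulates
#' 1-3 bending tests at the configured span-to-depth ratio, and (optionally)
#' rasterizes the layout into a labeled section.
#'
#' The generator is fully deterministic under the configured seed.
#'
#' @param config A [cohort_config()].
#' @return An object of class `stem_cohort`: list with `specimens` (tibble of
#'   per-specimen ground truth: category, diameter, fractions, analytic areas
#'   and second moments, `EI_true`, `I_true`, `E_true`), `sections` (named
#'   list of [labeled_section()]s, or `NULL`), `tests` (named list of lists of
#'   [bending_test()]s), `layouts` (named list of layouts), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  profiles <- category_fraction_profiles()
  rows <- list()
  sections <- list()
  tests <- list()
  layouts <- list()
  idx <- 0L
  for (cat in names(config$counts)) {
    n <- config$counts[[cat]]
    if (n == 0L) next
    prof <- profiles[profiles$category == cat, ]
    mu <- prof$mean_fraction
    sd <- prof$sd_fraction
    for (k in seq_len(n)) {
      idx <- idx + 1L
      id <- sprintf("%s_%03d", gsub("-", "", cat), k)
      dr <- config$diameter_range
      if (config$threshold_rule && cat %in% c("self-supporting", "pendulous")) {
        dr[2] <- min(dr[2], config$threshold_diameter)
      }
      d <- stats::runif(1, dr[1], dr[2])
      f <- draw_fractions(mu, sd, config$fraction_jitter)
      q <- stats::runif(1, 0.85, 1)
      mode <- "ring"
      lobe_count <- 0L; lobe_arc <- 0; phase <- 0
      if (f[3] == 0) {
        mode <- "none"
      } else if (f[3] < 0.05) {
        lobe_count <- sample(3:6, 1)
        lobe_arc <- stats::runif(1, 20, 40)
        phase <- stats::runif(1, 0, 360)
        kappa <- lobe_count * lobe_arc / 360
        if (f[2] >= f[3] * (1 / kappa - 1) + 1e-6) mode <- "lobes"
      }
      spec <- layout_spec(category = cat, outer_diameter = d,
                          target_fractions = f, ellipse_ratio = q,
                          wood2_mode = mode, lobe_count = lobe_count,
                          lobe_arc = lobe_arc, lobe_phase = phase)
      layout <- build_layout(spec)
      areas <- layout_tissue_areas(layout)
      Is <- layout_tissue_I(layout)
      EI_true <- sum(config$moduli * Is[tissue_names()])
      I_true <- Is[["total"]]
      E_true <- EI_true / I_true
      layouts[[id]] <- layout
      if (config$rasterize) {
        sec <- rasterize(layout, pixel_size = d / config$pixels_per_diameter)
        sec$id <- id
        sections[[id]] <- sec
      }
      span <- config$span_to_depth * d
      n_tests <- sample(seq(config$tests_range[1], config$tests_range[2]), 1)
      tlist <- vector("list", n_tests)
      for (j in seq_len(n_tests)) {
        n_steps <- sample(5:6, 1)
        target_defl <- stats::runif(1, 1, 3)
        F_final <- target_defl * 48 * EI_true / span^3
        masses <- rep(F_final / (9.81 * n_steps), n_steps)
        tlist[[j]] <- simulate_bending(
          EI = EI_true, span = span, masses = masses,
          a = d / 2, b = q * d / 2,
          shear = config$shear, noise = config$noise,
          specimen_id = id
        )
      }
      tests[[id]] <- tlist
      rows[[idx]] <- tibble::tibble(
        specimen_id = id, category = cat, diameter = d, ellipse_ratio = q,
        wood2_mode = mode,
        frac_pith = f[1], frac_wood1 = f[2], frac_wood2 = f[3],
        frac_cortex = f[4],
        area_pith = areas[["pith"]], area_wood1 = areas[["wood1"]],
        area_wood2 = areas[["wood2"]], area_cortex = areas[["cortex"]],
        area_total = areas[["total"]],
        I_pith = Is[["pith"]], I_wood1 = Is[["wood1"]],
        I_wood2 = Is[["wood2"]], I_cortex = Is[["cortex"]],
        EI_true = EI_true, I_true = I_true, E_true = E_true,
        n_tests = n_tests
      )
    }
  }
  if (idx == 0L) stop("empty cohort: all category counts are zero")
  structure(
    list(specimens = do.call(rbind, rows),
         sections = if (config$rasterize) sections else NULL,
         tests = tests,
         layouts = layouts,
         config = config),
    class = "stem_cohort"
  )
}

#' @export
print.stem_cohort <- function(x, ...) {
  cat("Synthetic stem cohort:", nrow(x$specimens), "specimens,",
      sum(x$specimens$n_tests), "bending tests",
      if (!is.null(x$sections)) sprintf("(rasterized at d/%g)",
                                        x$config$pixels_per_diameter),
      "\n")
  print(table(x$specimens$category))
  invisible(x)
}
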