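#' Per-test specimen records from a cohort
#'
#' Joins the mechanical reduction of every bending test with the morphometric
#' measurement of the specimen's cross-section. When the cohort carries
#' rasterized sections the percent contributions come from pixel integration
#' ([measure_section()]); otherwise the analytic layout values stored with
#' the cohort are used. The aggregation unit defaults to the stem segment
#' (one record per bending test, matching how field samples are counted);
#' `aggregate = "individual"` averages the trait rows of each specimen first.
#'
#' @param cohort A [generate_cohort()] result, or a compatible list with
#'   `specimens`, `tests` and optionally `sections`.
#' @param bounds Diameter class bounds for pooling.
#' @param aggregate `"segment"` (default) or `"individual"`.
#' @return Tibble with one row per record: identifiers, category, caliper
#'   `diameter`, diameter `class`, mechanical traits (`E`, `EI`, `I`, ...),
#'   section area, and per-tissue `pct_area_*` / `pct_I_*` columns.
#' @export
specimen_records <- function(cohort,
                             bounds = diameter_class_bounds(),
                             aggregate = c("segment", "individual")) {
  aggregate <- match.arg(aggregate)
  sp <- cohort$specimens
  if (is.null(sp) || nrow(sp) == 0L) stop("empty cohort")
  if (any(is.na(sp$category)) || !all(sp$category %in% stem_categories())) {
    bad <- sp$specimen_id[is.na(sp$category) |
                          !sp$category %in% stem_categories()]
    stop("specimens with missing or unknown category: ",
         paste(bad, collapse = ", "))
  }
  rows <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    id <- sp$specimen_id[i]
    if (!is.null(cohort$sections) && !is.null(cohort$sections[[id]])) {
      m <- measure_section(cohort$sections[[id]])
      morph <- tibble::tibble(
        area_cs = m$area_total,
        pct_area_pith = m$pct_area[["pith"]],
        pct_area_wood1 = m$pct_area[["wood1"]],
        pct_area_wood2 = m$pct_area[["wood2"]],
        pct_area_cortex = m$pct_area[["cortex"]],
        pct_I_pith = m$pct_I[["pith"]],
        pct_I_wood1 = m$pct_I[["wood1"]],
        pct_I_wood2 = m$pct_I[["wood2"]],
        pct_I_cortex = m$pct_I[["cortex"]]
      )
    } else {
      at <- sp$area_total[i]
      It <- sp$I_pith[i] + sp$I_wood1[i] + sp$I_wood2[i] + sp$I_cortex[i]
      morph <- tibble::tibble(
        area_cs = at,
        pct_area_pith = 100 * sp$area_pith[i] / at,
        pct_area_wood1 = 100 * sp$area_wood1[i] / at,
        pct_area_wood2 = 100 * sp$area_wood2[i] / at,
        pct_area_cortex = 100 * sp$area_cortex[i] / at,
        pct_I_pith = 100 * sp$I_pith[i] / It,
        pct_I_wood1 = 100 * sp$I_wood1[i] / It,
        pct_I_wood2 = 100 * sp$I_wood2[i] / It,
        pct_I_cortex = 100 * sp$I_cortex[i] / It
      )
    }
    traits <- do.call(rbind, lapply(cohort$tests[[id]], reduce_test))
    n_t <- nrow(traits)
    rows[[i]] <- tibble::tibble(
      specimen_id = id,
      test = seq_len(n_t),
      category = sp$category[i],
      traits[, c("diameter", "span", "span_to_depth", "slope", "r_squared",
                 "EI", "I", "E", "elastic_warning", "linearity_warning")],
      morph[rep(1L, n_t), ]
    )
  }
  rec <- do.call(rbind, rows)
  if (aggregate == "individual") {
    num <- vapply(rec, is.numeric, logical(1))
    num[names(rec) %in% c("test")] <- FALSE
    agg <- lapply(split(seq_len(nrow(rec)), rec$specimen_id), function(ii) {
      one <- rec[ii[1], ]
      one[, num] <- lapply(rec[ii, num, drop = FALSE], mean)
      one$test <- NA_integer_
      one
    })
    rec <- do.call(rbind, agg[unique(rec$specimen_id)])
  }
  rec$class <- assign_diameter_class(rec$diameter, bounds)
  rec
}

# the Table-1-style trait set, in reporting order
pipeline_traits <- function() {
  c("diameter", "area_cs",
    "pct_area_cortex", "pct_area_wood1", "pct_area_wood2", "pct_area_pith",
    "I", "E", "EI",
    "pct_I_cortex", "pct_I_wood1", "pct_I_wood2", "pct_I_pith")
}

#' Run the full analysis pipeline on a cohort
#'
#' Computes per-record traits ([specimen_records()]), pools records into
#' diameter classes, and for every trait and class compares the four stem
#' categories with a tie-corrected Kruskal-Wallis test followed by Dunn's
#' post-hoc test and a compact letter display. Also assembles the standard
#' scatter exports: diameter vs E per category, and the percent contribution
#' of each wood type to the second moment of area vs E with pooled Spearman
#' rank correlations.
#'
#' @param cohort A [generate_cohort()] result (or compatible list).
#' @param bounds Diameter class bounds.
#' @param alpha Significance level for the letter display.
#' @param adjust Multiplicity adjustment for Dunn p-values (default
#'   `"none"`).
#' @param min_group_size Minimum category size per trait and class for
#'   inclusion in the Kruskal-Wallis test (default 3).
#' @param aggregate Aggregation unit, see [specimen_records()].
#' @return An object of class `stem_pipeline`: list with `records`, `summary`
#'   (trait x class x category means, SDs, n and letters), `kw` (trait x
#'   class H/df/p with exclusion notes), `scatter` (`fig_diameter_E`,
#'   `fig_woodI_E`, `fig_woodII_E`), `correlations` (Spearman results for the
#'   two wood scatter plots), `exclusions`, and the call parameters.
#' @export
run_pipeline <- function(cohort,
                         bounds = diameter_class_bounds(),
                         alpha = 0.05,
                         adjust = "none",
                         min_group_size = 3L,
                         aggregate = "segment") {
  records <- specimen_records(cohort, bounds, aggregate)
  pooled <- records[records$class != "below", , drop = FALSE]
  pooled$class <- droplevels(pooled$class)
  summary_rows <- list()
  kw_rows <- list()
  excl_rows <- list()
  for (cls in levels(pooled$class)) {
    sub <- pooled[pooled$class == cls, , drop = FALSE]
    if (nrow(sub) == 0L) next
    for (trait in pipeline_traits()) {
      v <- sub[[trait]]
      g <- sub$category
      sizes <- table(factor(g, levels = stem_categories()))
      kw <- tryCatch(kruskal_wallis(v, g, min_group_size = min_group_size),
                     error = function(e) NULL)
      letters_out <- stats::setNames(rep(NA_character_,
                                         length(stem_categories())),
                                     stem_categories())
      if (!is.null(kw)) {
        keep <- names(kw$group_sizes)
        if (length(keep) >= 2L) {
          dn <- dunn_posthoc(v[g %in% keep], g[g %in% keep], adjust = adjust)
          letters_out[keep] <- compact_letter_display(dn$p, alpha = alpha)
        }
        kw_rows[[length(kw_rows) + 1L]] <- tibble::tibble(
          trait = trait, class = cls, H = kw$H, df = kw$df,
          p_value = kw$p_value, n = kw$n,
          note = if (nrow(kw$excluded))
            paste0("excluded: ", paste(kw$excluded$group, "(",
                                       kw$excluded$reason, ")",
                                       collapse = "; "))
          else NA_character_
        )
        if (nrow(kw$excluded)) {
          excl_rows[[length(excl_rows) + 1L]] <-
            tibble::tibble(trait = trait, class = cls, kw$excluded)
        }
      } else {
        kw_rows[[length(kw_rows) + 1L]] <- tibble::tibble(
          trait = trait, class = cls, H = NA_real_, df = NA_integer_,
          p_value = NA_real_, n = sum(sizes),
          note = "Kruskal-Wallis not performed: fewer than 2 groups of minimum size"
        )
      }
      for (cat in stem_categories()) {
        vals <- v[g == cat]
        summary_rows[[length(summary_rows) + 1L]] <- tibble::tibble(
          trait = trait, class = cls, category = cat,
          mean = if (length(vals)) mean(vals) else NA_real_,
          sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
          n = length(vals),
          letter = letters_out[[cat]]
        )
      }
    }
  }
  cor_w1 <- spearman_test(pooled$pct_I_wood1, pooled$E)
  cor_w2 <- spearman_test(pooled$pct_I_wood2, pooled$E)
  structure(
    list(records = records,
         summary = do.call(rbind, summary_rows),
         kw = do.call(rbind, kw_rows),
         scatter = list(
           fig_diameter_E = pooled[, c("specimen_id", "category",
                                       "diameter", "E")],
           fig_woodI_E = pooled[, c("specimen_id", "category",
                                    "pct_I_wood1", "E")],
           fig_woodII_E = pooled[, c("specimen_id", "category",
                                     "pct_I_wood2", "E")]
         ),
         correlations = list(woodI_E = cor_w1, woodII_E = cor_w2),
         exclusions = if (length(excl_rows)) do.call(rbind, excl_rows)
                      else NULL,
         alpha = alpha, adjust = adjust,
         min_group_size = min_group_size,
         bounds = bounds),
    class = "stem_pipeline"
  )
}

#' @export
print.stem_pipeline <- function(x, ...) {
  cat("Stem trellis analysis pipeline:",
      nrow(x$records), "records,",
      length(unique(x$records$specimen_id)), "specimens\n")
  cat(sprintf("  wood TYPE I %%I vs E : R_s = %.4f (t = %.2f)\n",
              x$correlations$woodI_E$r_s, x$correlations$woodI_E$t))
  cat(sprintf("  wood TYPE II %%I vs E: R_s = %.4f (t = %.2f)\n",
              x$correlations$woodII_E$r_s, x$correlations$woodII_E$t))
  invisible(x)
}

#' Diameter threshold report per category
#'
#' Reports, per stem category, the number of records, the maximum diameter,
#' and the count of records above a threshold diameter (default 5.9 mm, the
#' developmental cutoff above which only attached stems keep growing in the
#' study system).
#'
#' @param records A [specimen_records()] tibble (or `stem_pipeline` records).
#' @param threshold Threshold diameter in mm (default 5.9).
#' @return Tibble with columns `category`, `n`, `max_diameter`,
#'   `n_above_threshold`, `threshold`.
#' @export
classify_threshold_report <- function(records, threshold = 5.9) {
  if (inherits(records, "stem_pipeline")) records <- records$records
  stopifnot(nrow(records) >= 1L)
  cats <- stem_categories()
  out <- lapply(cats, function(cat) {
    d <- records$diameter[records$category == cat]
    tibble::tibble(category = cat, n = length(d),
                   max_diameter = if (length(d)) max(d) else NA_real_,
                   n_above_threshold = sum(d > threshold),
                   threshold = threshold)
  })
  do.call(rbind, out)
}
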