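#' Write a labeled section as PNG with a JSON sidecar
#'
#' The label raster (0 background, 1 pith, 2 wood TYPE I, 3 wood TYPE II,
#' 4 cortex) is stored losslessly as an 8-bit grayscale PNG with pixel value
#' equal to the label; a JSON sidecar (`<path>.json`) carries the physical
#' pixel size and the label legend.
#'
#' @param section A [labeled_section()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_labeled_section <- function(section, path) {
  stopifnot(inherits(section, "labeled_section"))
  png::writePNG(section$labels / 255, target = path)
  sidecar <- list(
    pixel_size_mm = section$pixel_size,
    specimen_id = section$id,
    labels = list(background = 0, pith = 1, wood1 = 2, wood2 = 3, cortex = 4)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a labeled section written by [write_labeled_section()]
#'
#' @param path PNG path; the JSON sidecar is expected at `<path>.json`.
#' @return A [labeled_section()].
#' @export
read_labeled_section <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  lab <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labeled_section(lab, pixel_size = sidecar$pixel_size_mm,
                  id = sidecar$specimen_id)
}

#' Write bending tests to CSV
#'
#' One row per loading step with columns `specimen_id`, `test`, `span_mm`,
#' `a1_mm..a3_mm`, `b1_mm..b3_mm`, `step`, `force_N`, `deflection_mm`.
#'
#' @param tests A list of [bending_test()]s, or a named list of such lists
#'   (one per specimen, as in a cohort).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bending_tests <- function(tests, path) {
  if (length(tests) && inherits(tests[[1]], "bending_test")) {
    tests <- list(tests)
  }
  rows <- list()
  for (tl in tests) {
    for (j in seq_along(tl)) {
      tst <- tl[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = if (is.null(tst$specimen_id)) NA_character_
                      else tst$specimen_id,
        test = j,
        span_mm = tst$span,
        a1_mm = tst$a[1], a2_mm = tst$a[2], a3_mm = tst$a[3],
        b1_mm = tst$b[1], b2_mm = tst$b[2], b3_mm = tst$b[3],
        step = seq_along(tst$force),
        force_N = tst$force,
        deflection_mm = tst$deflection
      )
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read bending tests from CSV
#'
#' Inverse of [write_bending_tests()].
#'
#' @param path CSV path.
#' @param elastic_window Passed to [bending_test()].
#' @return Named list (by specimen id) of lists of [bending_test()]s.
#' @export
read_bending_tests <- function(path, elastic_window = c(0.2, 5)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("specimen_id", "test", "span_mm", "a1_mm", "a2_mm", "a3_mm",
              "b1_mm", "b2_mm", "b3_mm", "step", "force_N", "deflection_mm")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("bending CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  out <- list()
  for (id in unique(df$specimen_id)) {
    sub <- df[df$specimen_id == id, ]
    out[[id]] <- lapply(sort(unique(sub$test)), function(j) {
      s <- sub[sub$test == j, ]
      s <- s[order(s$step), ]
      bending_test(span = s$span_mm[1],
                   a = unlist(s[1, c("a1_mm", "a2_mm", "a3_mm")]),
                   b = unlist(s[1, c("b1_mm", "b2_mm", "b3_mm")]),
                   force = s$force_N, deflection = s$deflection_mm,
                   specimen_id = id, elastic_window = elastic_window)
    })
  }
  out
}

#' Write a cohort to a directory
#'
#' Writes the specimen manifest (`specimens.csv`), the bending records
#' (`bending_tests.csv`), the generator configuration (`config.yaml`) and,
#' when present, one PNG + JSON sidecar per labeled section under
#' `sections/`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "stem_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$specimens, file.path(dir, "specimens.csv"),
                   row.names = FALSE)
  write_bending_tests(cohort$tests, file.path(dir, "bending_tests.csv"))
  write_cohort_config(cohort$config, file.path(dir, "config.yaml"))
  if (!is.null(cohort$sections)) {
    sdir <- file.path(dir, "sections")
    dir.create(sdir, showWarnings = FALSE)
    for (id in names(cohort$sections)) {
      write_labeled_section(cohort$sections[[id]],
                            file.path(sdir, paste0(id, ".png")))
    }
  }
  invisible(dir)
}

#' Write / read a cohort configuration as YAML
#'
#' @param config A [cohort_config()].
#' @param path YAML path.
#' @return For the writer, `path` invisibly; for the reader, a
#'   [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  out <- unclass(config)
  # named vectors must go out as maps, not bare sequences
  out$counts <- as.list(config$counts)
  out$moduli <- as.list(config$moduli)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort_config(
    counts = unlist(raw$counts),
    diameter_range = as.numeric(raw$diameter_range),
    threshold_rule = raw$threshold_rule,
    threshold_diameter = raw$threshold_diameter,
    moduli = unlist(raw$moduli),
    noise = raw$noise,
    shear = raw$shear,
    span_to_depth = raw$span_to_depth,
    tests_range = as.integer(raw$tests_range),
    rasterize = raw$rasterize,
    pixels_per_diameter = raw$pixels_per_diameter,
    fraction_jitter = raw$fraction_jitter,
    seed = raw$seed
  )
}

#' Write the pipeline summary and scatter exports to a directory
#'
#' Emits `summary.csv` (trait x class x category means, SDs, n, letters),
#' `kruskal_wallis.csv`, `records.csv`, the three scatter CSVs, and
#' `correlations.json`.
#'
#' @param pipeline A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "stem_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(pipeline$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(pipeline$kw, file.path(dir, "kruskal_wallis.csv"),
                   row.names = FALSE)
  utils::write.csv(pipeline$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(pipeline$scatter$fig_diameter_E,
                   file.path(dir, "scatter_diameter_E.csv"), row.names = FALSE)
  utils::write.csv(pipeline$scatter$fig_woodI_E,
                   file.path(dir, "scatter_woodI_E.csv"), row.names = FALSE)
  utils::write.csv(pipeline$scatter$fig_woodII_E,
                   file.path(dir, "scatter_woodII_E.csv"), row.names = FALSE)
  cors <- lapply(pipeline$correlations, function(cr) {
    list(r_s = cr$r_s, n = cr$n, t = cr$t, p_value = cr$p_value)
  })
  jsonlite::write_json(cors, file.path(dir, "correlations.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
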