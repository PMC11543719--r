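#' Run the full screening analysis end to end
#'
#' Drives the pipeline in its published order: detection-limit processing,
#' per-element distance models, geogenic correction of the selected
#' candidates, and the near/far screening report. Optionally writes the
#' result bundle (`table1.tsv`, `corrections.tsv`, `screening.tsv`,
#' `curves/<element>.tsv`, `exceedances.json`, `manifest.json`) to a
#' directory; outputs are deterministic given identical inputs and
#' configuration.
#'
#' @param panel Long panel tibble (from [read_panel()] or
#'   [simulate_panel()]).
#' @param meta Element metadata tibble.
#' @param reference Optional reference-percentile tibble for exceedance
#'   flags.
#' @param out_dir Optional output directory; created if needed.
#' @param exclusion_fraction Censoring threshold for
#'   [apply_detection_limits()].
#' @param grid_fractions Tolerance grid fractions for [tolerance_grid()].
#' @param min_nstar_frac Overfitting control for [fit_npr()].
#' @param basis Basis element for geogenic correction (skipped if absent
#'   from the processed panel).
#' @param r2_threshold Candidate-selection threshold.
#' @param cutoff_km Near/far boundary for the screening report.
#' @param elements Elements to model; default all retained.
#' @return A list with `fits` (Table-1-style tibble), `corrections`,
#'   `screening`, `exceedances` (or `NULL`), `excluded`, and `manifest`.
#' @export
run_full_analysis <- function(panel, meta, reference = NULL, out_dir = NULL,
                              exclusion_fraction = 0.20,
                              grid_fractions = seq(0.05, 1, by = 0.05),
                              min_nstar_frac = 0.05,
                              basis = "Al", r2_threshold = 0.30,
                              cutoff_km = 1, elements = NULL) {
  dl <- apply_detection_limits(panel, meta, exclusion_fraction)
  if (!nrow(dl$panel)) {
    stop("detection-limit processing excluded every element; nothing to fit",
         call. = FALSE)
  }
  elements <- elements %||% unique(dl$panel$element)

  fits <- fit_panel_npr(dl$panel, elements, min_nstar_frac = min_nstar_frac)
  ranges <- group_and_summarize(dl$panel, cutoff_km, elements) |>
    dplyr::select("element", "group", "min", "max") |>
    tidyr::pivot_wider(names_from = "group", values_from = c("min", "max"),
                       names_glue = "{group}_{.value}")
  table1 <- fits |>
    dplyr::select("element", "xr2", "ave_n_star", "tolerance") |>
    dplyr::left_join(ranges, by = "element")

  corrections <- NULL
  if (basis %in% unique(dl$panel$element)) {
    corrections <- correct_geogenic(
      dl$panel, basis = basis,
      elements = setdiff(elements, basis),
      r2_threshold = r2_threshold, min_nstar_frac = min_nstar_frac
    )
  }

  screening <- group_and_summarize(dl$panel, cutoff_km, elements)
  exceed <- if (!is.null(reference)) {
    exceedance_flags(dl$panel, reference, cutoff_km, elements)
  }

  manifest <- list(
    n_samples = length(unique(dl$panel$sample_id)),
    n_elements = length(elements),
    excluded_elements = as.list(dl$excluded$element),
    log_base = 10,
    exclusion_fraction = exclusion_fraction,
    grid_fractions = grid_fractions,
    min_nstar_frac = min_nstar_frac,
    basis = basis,
    r2_threshold = r2_threshold,
    cutoff_km = cutoff_km
  )

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "curves"), recursive = TRUE,
               showWarnings = FALSE)
    readr::write_tsv(table1, file.path(out_dir, "table1.tsv"))
    if (!is.null(corrections)) {
      readr::write_tsv(
        dplyr::select(corrections, "element", "basis", "method", "basis_r2",
                      "raw_xr2", "adjusted_xr2", "selected"),
        file.path(out_dir, "corrections.tsv")
      )
    }
    readr::write_tsv(screening, file.path(out_dir, "screening.tsv"))
    for (i in seq_len(nrow(fits))) {
      curve <- predict_curve(fits$fit[[i]])
      readr::write_tsv(
        tibble::tibble(distance_km = 10^curve$x,
                       predicted_ppm = 10^curve$pred),
        file.path(out_dir, "curves", paste0(fits$element[i], ".tsv"))
      )
    }
    if (!is.null(exceed)) {
      jsonlite::write_json(exceed, file.path(out_dir, "exceedances.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(fits = table1, fit_objects = fits, corrections = corrections,
       screening = screening, exceedances = exceed, excluded = dl$excluded,
       manifest = manifest)
}

#' Compare a model table against published values
#'
#' Per-element deltas between a computed Table-1-style summary and a
#' published reference table, with pass/fail at stated tolerances.
#'
#' @param table Computed tibble with `element`, `xr2`, `ave_n_star`,
#'   `tolerance`.
#' @param published Reference tibble with the same columns.
#' @param tolerances Named numeric vector of absolute tolerances per
#'   compared column.
#' @return A tibble with one row per element and column: `element`,
#'   `metric`, `computed`, `published`, `delta`, `tolerance`, `pass`.
#' @export
compare_to_published <- function(table, published,
                                 tolerances = c(xr2 = 0.02, ave_n_star = 2,
                                                tolerance = 0.13)) {
  metrics <- intersect(names(tolerances),
                       intersect(names(table), names(published)))
  joined <- dplyr::inner_join(
    tidyr::pivot_longer(table[, c("element", metrics)], -"element",
                        names_to = "metric", values_to = "computed"),
    tidyr::pivot_longer(published[, c("element", metrics)], -"element",
                        names_to = "metric", values_to = "published"),
    by = c("element", "metric")
  )
  joined |>
    dplyr::mutate(
      delta = .data$computed - .data$published,
      tolerance = unname(tolerances[.data$metric]),
      pass = abs(.data$delta) <= .data$tolerance
    )
}
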