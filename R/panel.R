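#' Read a per-element metadata table
#'
#' The companion table to a concentration panel: one row per element with
#' its method detection limit (MDL, ppm) and a category used downstream
#' (`profile` for the point-source emissions profile, `ree` for rare earth
#' elements, `reference` for crustal reference elements such as Al, `other`
#' otherwise).
#'
#' @param path CSV file with columns `element`, `mdl_ppm`, and optionally
#'   `category` and `notes`.
#' @return A tibble with columns `element`, `category`, `mdl_ppm`, `notes`.
#' @export
read_element_meta <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("element", "mdl_ppm") %in% names(meta))) {
    stop("element metadata must have columns `element` and `mdl_ppm`",
         call. = FALSE)
  }
  if (!"category" %in% names(meta)) meta$category <- "other"
  if (!"notes" %in% names(meta)) meta$notes <- NA_character_
  validate_element_meta(
    tibble::as_tibble(meta)[, c("element", "category", "mdl_ppm", "notes")]
  )
}

validate_element_meta <- function(meta) {
  if (anyDuplicated(meta$element)) {
    stop("duplicate element symbols in metadata: ",
         paste(unique(meta$element[duplicated(meta$element)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- meta$element[!is.na(meta$mdl_ppm) & meta$mdl_ppm <= 0]
  if (length(bad)) {
    stop("non-positive MDL for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ok <- c("profile", "ree", "other", "reference")
  meta$category[is.na(meta$category)] <- "other"
  if (!all(meta$category %in% ok)) {
    stop("element category must be one of ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  meta
}

#' Read a wide sample-by-element concentration panel
#'
#' Reads the canonical panel layout: one row per sample with columns
#' `sample_id`, `distance_km`, optionally `replicate_group`, and one column
#' per element holding concentrations in ppm dry weight. Cells below the
#' detection limit are encoded `"<value"` (e.g. `"<0.01"`); they are parsed
#' as the stated limit value and flagged censored, ready for
#' [apply_detection_limits()].
#'
#' @param path CSV file in the wide layout.
#' @param meta Optional element metadata tibble; if supplied, element
#'   columns are checked against it and unknown symbols rejected.
#' @return A long tibble with columns `sample_id`, `distance_km`,
#'   `replicate_group`, `element`, `conc_ppm`, `censored`.
#' @export
read_panel <- function(path, meta = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("sample_id", "distance_km") %in% names(raw))) {
    stop("panel must have `sample_id` and `distance_km` columns", call. = FALSE)
  }
  id_cols <- intersect(c("sample_id", "distance_km", "replicate_group"), names(raw))
  el_cols <- setdiff(names(raw), id_cols)
  if (!length(el_cols)) stop("panel has no element columns", call. = FALSE)
  if (!is.null(meta)) {
    unknown <- setdiff(el_cols, meta$element)
    if (length(unknown)) {
      stop("element column(s) not in metadata: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  long <- tidyr::pivot_longer(raw, dplyr::all_of(el_cols),
                              names_to = "element", values_to = "cell")
  long$censored <- !is.na(long$cell) & startsWith(trimws(long$cell), "<")
  long$conc_ppm <- as.numeric(sub("^\\s*<", "", long$cell))
  long$distance_km <- as.numeric(long$distance_km)
  if (!"replicate_group" %in% names(long)) long$replicate_group <- NA_character_
  panel <- tibble::as_tibble(
    long[, c("sample_id", "distance_km", "replicate_group", "element",
             "conc_ppm", "censored")]
  )
  validate_panel(panel)
}

validate_panel <- function(panel) {
  bad_dist <- unique(panel$sample_id[is.na(panel$distance_km) |
                                       panel$distance_km <= 0])
  if (length(bad_dist)) {
    stop("missing or non-positive distance for sample(s): ",
         paste(bad_dist, collapse = ", "), call. = FALSE)
  }
  neg <- panel[!is.na(panel$conc_ppm) & panel$conc_ppm < 0, ]
  if (nrow(neg)) {
    stop(sprintf("negative concentration for sample %s, element %s",
                 neg$sample_id[1], neg$element[1]), call. = FALSE)
  }
  panel
}

# shortest decimal representation that round-trips the double exactly
fmt_roundtrip <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

#' Write a panel in the canonical wide CSV layout
#'
#' Inverse of [read_panel()]: censored cells are written back as
#' `"<value"`. Numeric values are written with enough digits to round-trip
#' exactly.
#'
#' @param panel Long panel tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- dplyr::mutate(
    panel,
    cell = ifelse(.data$censored, paste0("<", fmt_roundtrip(.data$conc_ppm)),
                  fmt_roundtrip(.data$conc_ppm))
  )
  wide <- tidyr::pivot_wider(
    dplyr::mutate(panel, distance_km = fmt_roundtrip(.data$distance_km)),
    id_cols = c("sample_id", "distance_km", "replicate_group"),
    names_from = "element", values_from = "cell"
  )
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

#' Apply detection-limit processing to a panel
#'
#' Implements the standard censoring rule for trace-element panels: for each
#' element, if the fraction of censored observations (below the MDL) is no
#' more than `exclusion_fraction`, every censored cell is substituted with
#' half the method detection limit (MDL/2); elements censored in strictly
#' more than that fraction of samples are dropped from the panel entirely.
#' The boundary (exactly 20% censored by default) is retained, matching the
#' "more than 20% excluded" convention.
#'
#' @param panel Long panel tibble with `censored` flags populated.
#' @param meta Element metadata with `mdl_ppm` for every censored element.
#' @param exclusion_fraction Censored-fraction threshold above which an
#'   element is excluded. Default 0.20.
#' @return A list with `panel` (retained elements, censored cells set to
#'   MDL/2) and `excluded` (tibble of dropped elements with their censored
#'   fractions).
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(seed = 1))
#' dl <- apply_detection_limits(sim$panel, sim$meta)
#' dl$excluded
apply_detection_limits <- function(panel, meta, exclusion_fraction = 0.20) {
  stopifnot(exclusion_fraction >= 0, exclusion_fraction <= 1)
  need_mdl <- unique(panel$element[panel$censored])
  mdl <- stats::setNames(meta$mdl_ppm, meta$element)
  missing_mdl <- need_mdl[!need_mdl %in% meta$element |
                            is.na(mdl[need_mdl])]
  if (length(missing_mdl)) {
    stop("censored cells but no MDL for: ",
         paste(missing_mdl, collapse = ", "), call. = FALSE)
  }
  frac <- panel |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(censored_fraction = mean(.data$censored), .groups = "drop")
  excluded <- dplyr::filter(frac, .data$censored_fraction > exclusion_fraction)
  kept <- dplyr::filter(panel, !.data$element %in% excluded$element)
  kept$conc_ppm <- ifelse(kept$censored, unname(mdl[kept$element]) / 2,
                          kept$conc_ppm)
  list(panel = kept, excluded = excluded)
}

#' Extract the log10 model vector for one element
#'
#' The regression input: x = log10 distance (km), y = log10 concentration
#' (ppm). Requires strictly positive concentrations (guaranteed after
#' half-MDL substitution).
#'
#' @param panel Processed long panel tibble.
#' @param element One element symbol present in the panel.
#' @return A tibble with columns `sample_id`, `x`, `y`.
#' @export
to_model_vector <- function(panel, element) {
  sub <- panel[panel$element == element, ]
  if (!nrow(sub)) stop("element not in panel: ", element, call. = FALSE)
  if (any(is.na(sub$conc_ppm) | sub$conc_ppm <= 0)) {
    stop("zero, negative or missing concentration for ", element,
         "; run apply_detection_limits() first", call. = FALSE)
  }
  tibble::tibble(sample_id = sub$sample_id,
                 x = log10(sub$distance_km),
                 y = log10(sub$conc_ppm))
}
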