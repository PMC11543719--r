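#' Default priority elements for stakeholder screening
#'
#' Eight trace elements conventionally prioritised in urban moss screening
#' for their toxicity: As, Cd, Cr, Co, Hg, Mo, Ni, Pb. An override list can
#' be supplied and is validated against the known panel when given.
#'
#' @param override Optional character vector replacing the default list.
#' @param known Optional character vector of valid symbols (e.g. the panel's
#'   elements); overrides outside it are rejected.
#' @return Character vector of element symbols.
#' @export
priority_elements <- function(override = NULL, known = NULL) {
  default <- c("As", "Cd", "Cr", "Co", "Hg", "Mo", "Ni", "Pb")
  out <- override %||% default
  if (!is.null(known)) {
    bad <- setdiff(out, known)
    if (length(bad)) {
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  out
}

#' Near/far group summaries of element concentrations
#'
#' Splits samples into a near group (distance strictly less than
#' `cutoff_km`) and a far group (at or beyond the cutoff) and summarises
#' untransformed concentrations (ppm) per element and group with the
#' five-number summary. Quartiles use linear interpolation between order
#' statistics (quantile type 7) so outputs are reproducible bit-for-bit.
#'
#' @param panel Detection-limit-processed long panel tibble.
#' @param cutoff_km Near/far boundary in km; a sample exactly at the cutoff
#'   is "far". Default 1.
#' @param elements Elements to summarise; default all in the panel.
#' @return A tibble with columns `element`, `group`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`, carrying attributes `cutoff_km` and
#'   `empty_groups` (character vector naming any group with no samples).
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(seed = 3))
#' dl <- apply_detection_limits(sim$panel, sim$meta)
#' group_and_summarize(dl$panel, cutoff_km = 1, elements = c("Hg", "Pb"))
group_and_summarize <- function(panel, cutoff_km = 1, elements = NULL) {
  stopifnot(is.numeric(cutoff_km), cutoff_km > 0)
  elements <- elements %||% unique(panel$element)
  sub <- dplyr::filter(panel, .data$element %in% elements)
  sub$group <- ifelse(sub$distance_km < cutoff_km, "near", "far")
  groups <- tidyr::expand_grid(element = elements, group = c("near", "far"))
  summ <- sub |>
    dplyr::group_by(.data$element, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$conc_ppm),
      q1 = stats::quantile(.data$conc_ppm, 0.25, type = 7, names = FALSE),
      median = stats::quantile(.data$conc_ppm, 0.5, type = 7, names = FALSE),
      q3 = stats::quantile(.data$conc_ppm, 0.75, type = 7, names = FALSE),
      max = max(.data$conc_ppm),
      .groups = "drop"
    )
  out <- dplyr::left_join(groups, summ, by = c("element", "group"))
  out$n[is.na(out$n)] <- 0L
  empty <- unique(out$group[out$n == 0L])
  if (length(empty)) {
    warning("empty group(s) at cutoff ", cutoff_km, " km: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  attr(out, "cutoff_km") <- cutoff_km
  attr(out, "empty_groups") <- empty
  out
}

#' Read a reference-percentile table
#'
#' Reference concentrations (e.g. the 95th percentiles of a prior city-wide
#' moss survey) used as context for flagging extreme values. Supplied by the
#' user, never computed here.
#'
#' @param path CSV with columns `element`, `reference_ppm`, and optionally
#'   `label`.
#' @return A tibble with `element`, `reference_ppm`, `label`.
#' @export
read_reference_table <- function(path) {
  ref <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("element", "reference_ppm") %in% names(ref))) {
    stop("reference table must have columns `element` and `reference_ppm`",
         call. = FALSE)
  }
  if (any(ref$reference_ppm <= 0)) {
    stop("reference values must be positive", call. = FALSE)
  }
  if (!"label" %in% names(ref)) ref$label <- "reference"
  tibble::as_tibble(ref[, c("element", "reference_ppm", "label")])
}

#' Flag samples exceeding reference concentrations
#'
#' One record per (sample, element) whose concentration strictly exceeds
#' the element's reference value, tagged with its near/far group. Elements
#' without a reference value are reported in the `missing_reference`
#' attribute rather than treated as errors.
#'
#' @param panel Detection-limit-processed long panel tibble.
#' @param reference Reference tibble (see [read_reference_table()]).
#' @param cutoff_km Near/far boundary, as in [group_and_summarize()].
#' @param elements Elements to screen; default the intersection of the panel
#'   and the reference table.
#' @return A tibble of exceedance records: `sample_id`, `element`,
#'   `distance_km`, `group`, `conc_ppm`, `reference_ppm`; attribute
#'   `missing_reference` lists requested elements absent from the table.
#' @export
exceedance_flags <- function(panel, reference, cutoff_km = 1, elements = NULL) {
  elements <- elements %||% unique(panel$element)
  missing_ref <- setdiff(elements, reference$element)
  elements <- intersect(elements, reference$element)
  recs <- panel |>
    dplyr::filter(.data$element %in% elements) |>
    dplyr::inner_join(reference[, c("element", "reference_ppm")], by = "element") |>
    dplyr::filter(.data$conc_ppm > .data$reference_ppm) |>
    dplyr::mutate(group = ifelse(.data$distance_km < cutoff_km, "near", "far")) |>
    dplyr::select("sample_id", "element", "distance_km", "group",
                  "conc_ppm", "reference_ppm") |>
    dplyr::arrange(.data$element, .data$distance_km)
  attr(recs, "missing_reference") <- missing_ref
  recs
}

#' Boxplot-style screening figure
#'
#' Concentration distributions for the chosen elements split into near and
#' far groups, with optional reference lines, on a log10 concentration
#' scale.
#'
#' @inheritParams exceedance_flags
#' @param reference Optional reference tibble; drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_screening <- function(panel, elements = NULL, cutoff_km = 1,
                           reference = NULL) {
  elements <- elements %||% priority_elements(known = unique(panel$element))
  dat <- panel |>
    dplyr::filter(.data$element %in% elements) |>
    dplyr::mutate(group = factor(ifelse(.data$distance_km < cutoff_km,
                                        "near", "far"),
                                 levels = c("near", "far")))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$conc_ppm)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~element, scales = "free_y") +
    ggplot2::labs(x = sprintf("distance group (cutoff %g km)", cutoff_km),
                  y = "concentration (ppm, log scale)")
  if (!is.null(reference)) {
    refdat <- dplyr::filter(reference, .data$element %in% elements)
    p <- p + ggplot2::geom_hline(
      data = refdat,
      ggplot2::aes(yintercept = .data$reference_ppm),
      linetype = "dashed", colour = "firebrick"
    )
  }
  p
}
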