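#' Residualize an element on a geogenic basis element
#'
#' Removes the soil-dust (geogenic) component of an element's signal by
#' regressing its log10 concentration on the log10 concentration of a
#' crustal basis element and keeping the residuals. Two basis models are
#' supported:
#' \describe{
#'   \item{`"npr"`}{kernel regression via [fit_npr()] on the basis element
#'     (the usual choice for Al); residuals are leave-one-out by default,
#'     consistent with the cross-validated framing, or in-sample via
#'     `residual_type = "insample"`.}
#'   \item{`"linear"`}{ordinary least squares with intercept (the usual
#'     choice for Ce, where rare-earth ratios are strongly linear);
#'     residuals are the classical OLS residuals, which sum to zero and are
#'     orthogonal to the basis.}
#' }
#'
#' @param y Numeric response vector (log10 ppm of the element).
#' @param basis Numeric vector of the basis element on the same samples
#'   (log10 ppm).
#' @param method `"npr"` or `"linear"`.
#' @param residual_type For `method = "npr"`: `"loo"` (default) or
#'   `"insample"`.
#' @param ... Passed to [fit_npr()] when `method = "npr"`.
#' @return A list with `fit` (an `npr_fit`, or a list with `intercept`,
#'   `slope`, `r_squared` for the linear method), `residuals`, and `method`.
#' @export
residualize_on_basis <- function(y, basis,
                                 method = c("npr", "linear"),
                                 residual_type = c("loo", "insample"), ...) {
  method <- match.arg(method)
  residual_type <- match.arg(residual_type)
  stopifnot(length(y) == length(basis))
  if (diff(range(basis)) <= 0) {
    stop("basis element is constant; residualization undefined", call. = FALSE)
  }
  if (method == "linear") {
    fit <- stats::lm.fit(cbind(1, basis), y)
    res <- unname(fit$residuals)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
    out_fit <- list(intercept = unname(fit$coefficients[1]),
                    slope = unname(fit$coefficients[2]), r_squared = r2)
  } else {
    out_fit <- fit_npr(basis, y, predictor = "basis", ...)
    res <- if (residual_type == "loo") {
      out_fit$loo$residual
    } else {
      curve <- predict_curve(out_fit, at = basis)
      y - curve$pred
    }
  }
  list(fit = out_fit, residuals = res, method = method)
}

#' Does a fitted distance model show a declining trend?
#'
#' Operationalizes "some apparent declining relationship to distance": the
#' fitted curve evaluated at the 10th percentile of the predictor must
#' exceed its value at the 90th percentile.
#'
#' @param fit An `npr_fit` of log10 concentration on log10 distance.
#' @return `TRUE` if the curve declines from near to far.
#' @export
declining_trend <- function(fit) {
  qs <- stats::quantile(fit$x, c(0.1, 0.9), names = FALSE)
  curve <- predict_curve(fit, at = qs)
  isTRUE(curve$pred[1] > curve$pred[2])
}

#' Select elements eligible for geogenic correction
#'
#' An element is a correction candidate when (a) its cross-validated fit on
#' the basis element is fairly strong (basis xR2 strictly greater than
#' `r2_threshold`) and (b) its raw distance model shows a declining trend
#' ([declining_trend()]). Correcting elements with weak basis relationships
#' would change nothing, so they are left alone.
#'
#' @param basis_fits Named list (by element) of `npr_fit`s of each element
#'   on the basis.
#' @param distance_fits Named list (by element) of raw `npr_fit`s on
#'   distance, same names.
#' @param r2_threshold Strict lower bound on basis xR2. Default 0.30.
#' @return Character vector of selected element symbols.
#' @export
select_correction_candidates <- function(basis_fits, distance_fits,
                                         r2_threshold = 0.30) {
  stopifnot(setequal(names(basis_fits), names(distance_fits)))
  els <- names(basis_fits)
  keep <- purrr::map_lgl(els, function(el) {
    basis_fits[[el]]$xr2 > r2_threshold && declining_trend(distance_fits[[el]])
  })
  els[keep]
}

#' Refit basis residuals against distance
#'
#' The second stage of a geogenic correction: the residuals from
#' [residualize_on_basis()] are regressed on log10 distance with the same
#' engine and settings as the raw fits.
#'
#' @param residuals Numeric residual vector.
#' @param x log10 distance vector, same samples.
#' @param ... Passed to [fit_npr()].
#' @return An `npr_fit` of the adjusted variable on distance.
#' @export
adjust_and_refit <- function(residuals, x, ...) {
  if (anyNA(residuals)) stop("residuals contain NA", call. = FALSE)
  fit_npr(x, residuals, ...)
}

#' Geogenic correction across a panel
#'
#' Runs the full correction workflow for a set of elements against a basis
#' element (Al by kernel regression, or Ce by linear regression): fits each
#' element on the basis, selects candidates (strong basis fit plus declining
#' raw distance trend), residualizes, and refits the residuals against
#' distance.
#'
#' @param panel Detection-limit-processed long panel tibble.
#' @param basis Basis element symbol, e.g. `"Al"` or `"Ce"`.
#' @param elements Elements to assess; default all except the basis itself.
#' @param method Basis model: `"npr"` (default, for Al) or `"linear"` (for
#'   Ce).
#' @param r2_threshold Candidate-selection threshold on the basis fit R2.
#' @param residual_type `"loo"` or `"insample"` residuals for the npr basis.
#' @param min_nstar_frac Overfitting control passed to [fit_npr()].
#' @return A tibble with one row per element: basis fit strength, raw and
#'   adjusted distance xR2, the `selected` flag, and list-columns with the
#'   underlying fits. Adjusted fits are computed for every assessed element
#'   so that non-candidates can still be inspected.
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(seed = 7))
#' dl <- apply_detection_limits(sim$panel, sim$meta)
#' correct_geogenic(dl$panel, basis = "Al", elements = c("Cr", "Ce"))
correct_geogenic <- function(panel, basis = "Al", elements = NULL,
                             method = if (basis == "Ce") "linear" else "npr",
                             r2_threshold = 0.30,
                             residual_type = "loo",
                             min_nstar_frac = 0.05) {
  elements <- elements %||% setdiff(unique(panel$element), basis)
  bv <- to_model_vector(panel, basis)
  rows <- purrr::map_dfr(elements, function(el) {
    mv <- to_model_vector(panel, el)
    stopifnot(identical(mv$sample_id, bv$sample_id))
    raw_fit <- fit_npr(mv$x, mv$y, response = el,
                       min_nstar_frac = min_nstar_frac)
    resz <- residualize_on_basis(mv$y, bv$y, method = method,
                                 residual_type = residual_type,
                                 response = el,
                                 min_nstar_frac = min_nstar_frac)
    basis_r2 <- if (method == "linear") resz$fit$r_squared else resz$fit$xr2
    adj_fit <- adjust_and_refit(resz$residuals, mv$x,
                                response = paste0(el, "|", basis),
                                min_nstar_frac = min_nstar_frac)
    tibble::tibble(
      element = el, basis = basis, method = method,
      basis_r2 = basis_r2,
      raw_xr2 = raw_fit$xr2,
      adjusted_xr2 = adj_fit$xr2,
      declining = declining_trend(raw_fit),
      selected = basis_r2 > r2_threshold && declining_trend(raw_fit),
      raw_fit = list(raw_fit),
      basis_fit = list(resz$fit),
      adjusted_fit = list(adj_fit),
      residuals = list(resz$residuals)
    )
  })
  rows
}
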