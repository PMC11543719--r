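#' Gaussian kernel weights
#'
#' Weight of each observation for a local fit centred at `target_x`. The
#' kernel is Gaussian with standard deviation `tolerance` (the smoothing
#' parameter, in predictor units — log10 km when the predictor is distance):
#' \deqn{w_i = \exp\{-(x_i - x_0)^2 / (2\sigma^2)\}}
#' so a sample sitting exactly at the target has weight 1 and weights decay
#' smoothly with distance in predictor space.
#'
#' @param x Numeric vector of predictor values.
#' @param target_x Single numeric value at which the local model is centred.
#' @param tolerance Positive numeric; kernel standard deviation.
#' @return Numeric vector of weights in (0, 1], same length as `x`.
#' @export
#' @examples
#' gaussian_weights(c(0, 0.5, 1), target_x = 0.5, tolerance = 0.5)
gaussian_weights <- function(x, target_x, tolerance) {
  stopifnot(is.numeric(x), length(target_x) == 1L, is.finite(target_x))
  if (!is.numeric(tolerance) || length(tolerance) != 1L || !is.finite(tolerance) ||
      tolerance <= 0) {
    stop("`tolerance` must be a single positive number", call. = FALSE)
  }
  exp(-((x - target_x)^2) / (2 * tolerance^2))
}

# Closed-form weighted least squares line through (x, y) with weights w.
# Returns intercept/slope, falling back to the weighted mean (slope 0) when
# the weighted spread of x is numerically nil, and NA when the total weight
# itself underflows to nothing.
wls_line <- function(x, y, w) {
  s0 <- sum(w)
  if (!is.finite(s0) || s0 <= 0) {
    return(list(intercept = NA_real_, slope = NA_real_, weight_sum = 0,
                degenerate = TRUE))
  }
  xbar <- sum(w * x) / s0
  ybar <- sum(w * y) / s0
  sxx <- sum(w * (x - xbar)^2)
  sxy <- sum(w * (x - xbar) * (y - ybar))
  scale <- max(sum(w * x^2) / s0, 1)
  if (sxx <= 1e-12 * scale) {
    return(list(intercept = ybar, slope = 0, weight_sum = s0, degenerate = TRUE))
  }
  slope <- sxy / sxx
  list(intercept = ybar - slope * xbar, slope = slope, weight_sum = s0,
       degenerate = FALSE)
}

#' Local-linear kernel estimate at a single target point
#'
#' Fits a weighted straight line to `(x, y)` with Gaussian kernel weights
#' centred at `target_x` and evaluates it there. When the weighted design is
#' singular (effectively all weight on one x value) the estimate falls back
#' to the local weighted mean and is flagged as degenerate; when the total
#' weight underflows the estimate is `NA`.
#'
#' @param x,y Numeric vectors (the model vector, typically log10 distance and
#'   log10 concentration).
#' @param target_x Point at which to evaluate the local fit.
#' @param tolerance Kernel standard deviation, predictor units.
#' @param exclude Optional integer index of one sample to leave out (used by
#'   leave-one-out cross-validation).
#' @return A list with `estimate`, `intercept`, `slope`, `weight_sum`
#'   (the neighborhood size N* at this target), and `degenerate`.
#' @export
local_linear_estimate <- function(x, y, target_x, tolerance, exclude = NULL) {
  stopifnot(length(x) == length(y))
  if (!is.null(exclude)) {
    x <- x[-exclude]
    y <- y[-exclude]
  }
  if (length(x) < 2L) {
    stop("need at least 2 samples for a local fit", call. = FALSE)
  }
  w <- gaussian_weights(x, target_x, tolerance)
  fit <- wls_line(x, y, w)
  est <- if (is.na(fit$intercept)) NA_real_ else fit$intercept + fit$slope * target_x
  list(estimate = est, intercept = fit$intercept, slope = fit$slope,
       weight_sum = fit$weight_sum, degenerate = fit$degenerate)
}

# Vectorised leave-one-out machinery. For every sample i, fits the local
# linear model at x_i from all other samples and records the prediction and
# the neighborhood size N*_i = sum_{j != i} w_j(x_i). O(n^2) in matrix ops.
loo_engine <- function(x, y, tolerance) {
  d <- outer(x, x, "-")                # d[j, i] = x_j - x_i, centred at target
  W <- exp(-(d^2) / (2 * tolerance^2))
  diag(W) <- 0                          # leave self out
  s0 <- colSums(W)
  dbar <- colSums(W * d) / s0
  ybar <- colSums(W * y) / s0
  dc <- sweep(d, 2, dbar)               # weighted-mean-centred, two-pass
  sxx <- colSums(W * dc * dc)
  sxy <- colSums(W * dc * sweep(matrix(y, length(y), length(y)), 2, ybar))
  scale <- pmax(colSums(W * d * d) / s0, 1)
  degen <- !is.finite(sxx) | sxx <= 1e-12 * scale
  slope <- ifelse(degen, 0, sxy / sxx)
  # regression of y on (x - x_i); the prediction at x_i is the intercept
  pred <- ybar - slope * dbar
  dead <- !is.finite(s0) | s0 <= 0
  pred[dead] <- NA_real_
  list(pred = pred, n_star = s0, degenerate = degen & !dead, undefined = dead)
}

#' Leave-one-out predictions and neighborhood sizes
#'
#' For each sample i, predicts y at x_i from a local-linear Gaussian-kernel
#' fit to all *other* samples, and reports the neighborhood size
#' \eqn{N^*_i = \sum_{j \ne i} w_j(x_i)} — the effective number of samples
#' supporting the estimate.
#'
#' @inheritParams local_linear_estimate
#' @return A tibble with one row per sample: `pred` (the leave-one-out
#'   prediction), `n_star`, and `degenerate` (fell back to a local weighted
#'   mean).
#' @export
loo_predictions <- function(x, y, tolerance) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (tolerance <= 0) stop("`tolerance` must be positive", call. = FALSE)
  eng <- loo_engine(x, y, tolerance)
  tibble::tibble(pred = eng$pred, n_star = eng$n_star,
                 degenerate = eng$degenerate | eng$undefined)
}

#' Cross-validated R-squared (xR2)
#'
#' The leave-one-out analogue of R-squared:
#' \deqn{xR^2 = 1 - \sum_i (y_i - \hat y_{(-i)})^2 / \sum_i (y_i - \bar y)^2.}
#' Because each prediction is made with the focal observation held out, xR2
#' is penalised for overfitting and can be negative when the model predicts
#' worse than the grand mean.
#'
#' @param y Observed responses.
#' @param loo Leave-one-out predictions, same length as `y`.
#' @return A single number, at most 1 and possibly negative.
#' @export
cross_validated_r2 <- function(y, loo) {
  stopifnot(length(y) == length(loo))
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) {
    stop("cross-validated R2 is undefined for constant y (zero total sum of squares)",
         call. = FALSE)
  }
  1 - sum((y - loo)^2) / sst
}

#' Tolerance grid as fractions of the predictor range
#'
#' Candidate smoothing parameters for model selection, expressed as fixed
#' fractions of the observed predictor range (default 5% steps from 0.05 to
#' 1.00). With a transect spanning ~0.1–32 km this yields tolerances on the
#' order of 0.13–2.5 log10 km.
#'
#' @param x Predictor values whose range anchors the grid.
#' @param fractions Strictly increasing proportions in (0, 1].
#' @return A tibble with columns `fraction` and `tolerance`.
#' @export
tolerance_grid <- function(x, fractions = seq(0.05, 1, by = 0.05)) {
  stopifnot(is.numeric(fractions), length(fractions) > 0,
            all(fractions > 0), !is.unsorted(fractions, strictly = TRUE))
  rng <- diff(range(x))
  if (rng <= 0) stop("predictor has zero range; no tolerance grid possible",
                     call. = FALSE)
  tibble::tibble(fraction = fractions, tolerance = fractions * rng)
}

#' Fit a nonparametric regression with cross-validated smoothing selection
#'
#' The core fitting routine: evaluates the leave-one-out cross-validated
#' R-squared (xR2) of a local-linear Gaussian-kernel regression at every
#' tolerance on a grid, discards tolerances whose average neighborhood size
#' N* falls below an overfitting-control floor, and selects the admissible
#' tolerance maximising xR2 (ties broken toward the larger, smoother
#' tolerance). The best xR2 is reported as-is, including negative values.
#'
#' @param x,y Numeric model vectors (e.g. log10 distance, log10 ppm).
#' @param grid A tibble from [tolerance_grid()], or `NULL` to build the
#'   default 5%-step grid from `x`.
#' @param min_nstar_frac Overfitting control: grid points with average
#'   N* below `min_nstar_frac * n` are inadmissible. Default 0.05.
#' @param response Optional label (element symbol) stored on the fit.
#' @param predictor Optional predictor label, default `"distance"`.
#' @return An object of class `npr_fit`: a list with the selected
#'   `tolerance`, `xr2`, `ave_n_star`, per-sample `loo` tibble, the full
#'   `grid` trace (tolerance, xr2, average N*, admissibility), and the data.
#' @seealso [predict_curve()], [tidy.npr_fit()], [glance.npr_fit()]
#' @export
#' @examples
#' set.seed(1)
#' x <- log10(rexp(30, 1 / 4) + 0.1)
#' y <- 1 - 0.5 * x + rnorm(30, sd = 0.1)
#' fit <- fit_npr(x, y)
#' glance(fit)
fit_npr <- function(x, y, grid = NULL, min_nstar_frac = 0.05,
                    response = NULL, predictor = "distance") {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("`x` and `y` must be finite and non-missing", call. = FALSE)
  }
  if (is.null(grid)) grid <- tolerance_grid(x)
  n <- length(x)
  trace <- purrr::pmap_dfr(grid, function(fraction, tolerance) {
    eng <- loo_engine(x, y, tolerance)
    tibble::tibble(
      fraction = fraction,
      tolerance = tolerance,
      xr2 = cross_validated_r2(y, eng$pred),
      ave_n_star = mean(eng$n_star),
      n_degenerate = sum(eng$degenerate)
    )
  })
  trace$admissible <- trace$ave_n_star >= min_nstar_frac * n
  adm <- trace[trace$admissible & is.finite(trace$xr2), , drop = FALSE]
  if (nrow(adm) == 0L) {
    stop("no admissible tolerance on the grid; relax `min_nstar_frac` or widen the grid",
         call. = FALSE)
  }
  best_xr2 <- max(adm$xr2)
  # ties (within numerical noise) resolved toward the smoothest model
  cand <- adm[adm$xr2 >= best_xr2 - 1e-9, , drop = FALSE]
  sel <- cand[which.max(cand$tolerance), ]
  eng <- loo_engine(x, y, sel$tolerance)
  fit <- list(
    response = response %||% "y",
    predictor = predictor,
    x = x, y = y, n = n,
    tolerance = sel$tolerance,
    fraction = sel$fraction,
    xr2 = sel$xr2,
    ave_n_star = sel$ave_n_star,
    loo = tibble::tibble(x = x, y = y, pred = eng$pred,
                         residual = y - eng$pred, n_star = eng$n_star,
                         degenerate = eng$degenerate | eng$undefined),
    grid = trace,
    control = list(min_nstar_frac = min_nstar_frac)
  )
  class(fit) <- "npr_fit"
  fit
}

#' Evaluate the fitted regression curve
#'
#' Evaluates the selected local-linear model (no leave-one-out exclusion) at
#' a grid of predictor values, for plotting or trend assessment. Points where
#' the local fit is undefined are returned as `NA` and flagged.
#'
#' @param fit An `npr_fit`.
#' @param at Numeric predictor values; defaults to an even 100-point grid
#'   over the observed range.
#' @return A tibble with columns `x`, `pred`, and `degenerate`.
#' @export
predict_curve <- function(fit, at = NULL) {
  stopifnot(inherits(fit, "npr_fit"))
  if (is.null(at)) at <- seq(min(fit$x), max(fit$x), length.out = 100)
  res <- purrr::map(at, function(x0) {
    w <- gaussian_weights(fit$x, x0, fit$tolerance)
    ln <- wls_line(fit$x, fit$y, w)
    est <- if (is.na(ln$intercept)) NA_real_ else ln$intercept + ln$slope * x0
    list(pred = est, degenerate = ln$degenerate)
  })
  tibble::tibble(
    x = at,
    pred = purrr::map_dbl(res, "pred"),
    degenerate = purrr::map_lgl(res, "degenerate")
  )
}

#' @export
print.npr_fit <- function(x, ...) {
  cat(sprintf(
    "Nonparametric regression: %s ~ %s\n  n = %d, tolerance = %.4g (%.0f%% of range), xR2 = %.4g, ave N* = %.4g\n",
    x$response, x$predictor, x$n, x$tolerance, 100 * x$fraction, x$xr2,
    x$ave_n_star
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Grid trace of a nonparametric regression fit
#'
#' One row per candidate tolerance with its cross-validated R2, average
#' neighborhood size and admissibility under the overfitting control.
#'
#' @param x An `npr_fit`.
#' @param ... Unused.
#' @method tidy npr_fit
#' @export
tidy.npr_fit <- function(x, ...) {
  dplyr::mutate(x$grid, selected = .data$tolerance == x$tolerance)
}

#' One-row summary of a nonparametric regression fit
#'
#' @param x An `npr_fit`.
#' @param ... Unused.
#' @method glance npr_fit
#' @export
glance.npr_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response, predictor = x$predictor, n = x$n,
    xr2 = x$xr2, ave_n_star = x$ave_n_star, tolerance = x$tolerance,
    fraction = x$fraction
  )
}

#' Per-sample leave-one-out predictions and residuals
#'
#' @param x An `npr_fit`.
#' @param ... Unused.
#' @method augment npr_fit
#' @export
augment.npr_fit <- function(x, ...) {
  x$loo
}

#' Plot a nonparametric regression fit
#'
#' Observed points with the fitted kernel-regression curve, both on the
#' (log10, log10) scale the model is fitted on.
#'
#' @param object An `npr_fit`.
#' @param ... Unused.
#' @method autoplot npr_fit
#' @export
autoplot.npr_fit <- function(object, ...) {
  curve <- predict_curve(object)
  ggplot2::ggplot(tibble::tibble(x = object$x, y = object$y),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$x, y = .data$pred),
                       colour = "steelblue", linewidth = 0.8, na.rm = TRUE) +
    ggplot2::labs(
      x = sprintf("log10 %s", object$predictor),
      y = sprintf("log10 %s", object$response),
      title = sprintf("%s: xR2 = %.3f, tolerance = %.3f", object$response,
                      object$xr2, object$tolerance)
    )
}

#' Fit distance models for every retained element of a panel
#'
#' Maps [fit_npr()] over the elements of a detection-limit-processed panel
#' and returns a summary table in the conventional reporting layout:
#' element, xR2, average N*, selected tolerance.
#'
#' @param panel A long panel tibble (see [read_panel()]), already processed
#'   with [apply_detection_limits()].
#' @param elements Character vector of element symbols, or `NULL` for all.
#' @param ... Passed to [fit_npr()] (e.g. `min_nstar_frac`).
#' @return A tibble with one row per element and a list-column `fit` holding
#'   each `npr_fit`.
#' @export
fit_panel_npr <- function(panel, elements = NULL, ...) {
  elements <- elements %||% unique(panel$element)
  fits <- purrr::map(elements, function(el) {
    mv <- to_model_vector(panel, el)
    fit_npr(mv$x, mv$y, response = el, ...)
  })
  dplyr::bind_cols(
    purrr::map_dfr(fits, glance),
    tibble::tibble(fit = fits)
  ) |>
    dplyr::rename(element = "response")
}
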