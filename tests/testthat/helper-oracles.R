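# Independent reference implementations used to cross-check the engine.
# These deliberately take the slow route (refitting weighted lm() from
# scratch) so they share no code with the package internals.

# weighted-least-squares prediction at t0 via stats::lm
oracle_wls_at <- function(x, y, t0, tolerance) {
  w <- exp(-(x - t0)^2 / (2 * tolerance^2))
  fit <- stats::lm(y ~ x, weights = w)
  unname(stats::predict(fit, newdata = data.frame(x = t0)))
}

# leave-one-out predictions by n full refits
oracle_loo <- function(x, y, tolerance) {
  vapply(seq_along(x), function(i) {
    oracle_wls_at(x[-i], y[-i], x[i], tolerance)
  }, numeric(1))
}

# closed-form leave-one-out R2 of global simple linear regression,
# via the hat-matrix identity e_(-i) = e_i / (1 - h_ii)
oracle_slr_loo_r2 <- function(x, y) {
  fit <- stats::lm(y ~ x)
  h <- stats::hatvalues(fit)
  press <- sum((stats::residuals(fit) / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

# a small random model vector on a plausible transect scale
random_model_vector <- function(n) {
  x <- sort(stats::runif(n, -1, 1.5))
  y <- 1 - 0.6 * x + stats::rnorm(n, sd = 0.3)
  list(x = x, y = y)
}

# tiny in-memory panel: 3 samples x 2 elements, one censored Hg cell
toy_panel_csv <- function(dir = tempdir()) {
  path <- file.path(dir, "toy_panel.csv")
  writeLines(c(
    "sample_id,distance_km,replicate_group,Hg,Pb",
    "S1,0.4,,0.62,12.5",
    "S2,2,,<0.01,3.25",
    "S3,16,,0.05,1.75"
  ), path)
  path
}

toy_meta <- function() {
  tibble::tibble(
    element = c("Hg", "Pb"),
    category = c("profile", "profile"),
    mdl_ppm = c(0.01, 0.05),
    notes = NA_character_
  )
}
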