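test_that("gaussian weights take their closed-form values", {
  x <- c(1, 1.3, 1.6, 3)
  w <- gaussian_weights(x, target_x = 1, tolerance = 0.3)
  expect_equal(w[1], 1)
  expect_equal(w[2], exp(-0.5))   # one tolerance away
  expect_equal(w[3], exp(-2))     # two tolerances away
  expect_true(all(diff(w) < 0))   # strictly decreasing in |x - target|
  expect_error(gaussian_weights(x, 1, 0), "positive")
})

test_that("local linear estimate reproduces exact lines and the flat-weight limit", {
  x <- c(0, 0.5, 1, 1.5, 2)
  y_lin <- 2 * x + 1
  for (tol in c(0.1, 0.5, 5)) {
    est <- local_linear_estimate(x, y_lin, target_x = 0.7, tolerance = tol)
    expect_equal(est$estimate, 2 * 0.7 + 1)
  }
  # huge tolerance: weights flat, estimate equals the global OLS prediction
  y <- c(2.0, 1.4, 1.1, 1.0, 0.9)
  ols <- stats::lm(y ~ x)
  est <- local_linear_estimate(x, y, target_x = 1.2, tolerance = 1e6)
  expect_equal(est$estimate,
               unname(stats::predict(ols, data.frame(x = 1.2))),
               tolerance = 1e-8)
})

test_that("local linear estimate matches the frozen weighted-least-squares oracle", {
  x <- c(0, 0.5, 1, 1.5, 2)
  y <- c(2.0, 1.4, 1.1, 1.0, 0.9)
  est <- local_linear_estimate(x, y, target_x = 1.0, tolerance = 0.5)
  expect_equal(est$estimate, 1.186982347585, tolerance = 1e-10)
})

test_that("leave-one-out predictions match a brute-force refit oracle", {
  x <- c(0, 0.5, 1, 1.5, 2)
  y <- c(2.0, 1.4, 1.1, 1.0, 0.9)
  loo <- loo_predictions(x, y, tolerance = 0.5)
  expect_equal(loo$pred,
               c(1.667884231676, 1.577326689353, 1.245606380952,
                 1.016908451141, 0.865743485802),
               tolerance = 1e-10)
  expect_equal(mean(loo$n_star), 1.141872777706, tolerance = 1e-10)

  set.seed(2024)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    mv <- random_model_vector(n)
    tol <- stats::runif(1, 0.2, 2)
    got <- loo_predictions(mv$x, mv$y, tol)$pred
    expect_equal(got, oracle_loo(mv$x, mv$y, tol), tolerance = 1e-10)
  }
})

test_that("leave-one-out predictions are exact on affine data", {
  set.seed(11)
  x <- sort(stats::runif(10, 0, 3))
  y <- 0.4 - 1.7 * x
  for (tol in c(0.2, 0.9, 4)) {
    loo <- loo_predictions(x, y, tol)
    expect_equal(loo$pred, y, tolerance = 1e-9)
    expect_equal(cross_validated_r2(y, loo$pred), 1, tolerance = 1e-9)
  }
})

test_that("cross-validated R2 honours its identities and signals constant y", {
  y <- c(1, 2, 3, 5)
  expect_equal(cross_validated_r2(y, y), 1)
  expect_equal(cross_validated_r2(y, rep(mean(y), 4)), 0)
  worse <- rep(mean(y), 4) + c(3, -3, 3, -3)
  expect_lt(cross_validated_r2(y, worse), 0)
  expect_error(cross_validated_r2(rep(2, 4), rep(2, 4)), "constant")
})

test_that("in the flat-kernel limit xR2 matches closed-form linear-regression LOO", {
  set.seed(5)
  for (rep in 1:10) {
    mv <- random_model_vector(sample(8:20, 1))
    loo <- loo_predictions(mv$x, mv$y, tolerance = 1e6)
    xr2 <- cross_validated_r2(mv$y, loo$pred)
    expect_equal(xr2, oracle_slr_loo_r2(mv$x, mv$y), tolerance = 1e-6)
  }
})

test_that("model selection maximises xR2, keeps negatives, ties to the smoothest", {
  # noisy monotone data: the selected grid point must attain the max xR2
  set.seed(31)
  mv <- random_model_vector(30)
  fit <- fit_npr(mv$x, mv$y)
  adm <- fit$grid[fit$grid$admissible, ]
  expect_equal(fit$xr2, max(adm$xr2))
  expect_true(fit$tolerance %in% adm$tolerance)
  expect_lte(fit$xr2, 1)

  # pure noise: the best cross-validated fit may be negative and must not
  # be floored at zero
  set.seed(99)
  x <- sort(stats::runif(20, 0, 2))
  y <- stats::rnorm(20)
  fit_noise <- fit_npr(x, y)
  expect_equal(fit_noise$xr2, max(fit_noise$grid$xr2[fit_noise$grid$admissible]))

  # exact line: every tolerance gives xR2 = 1; tie-break returns the
  # largest admissible tolerance
  x <- seq(0, 2, length.out = 12)
  y <- 3 - 0.5 * x
  fit_lin <- fit_npr(x, y)
  expect_equal(fit_lin$xr2, 1, tolerance = 1e-9)
  expect_equal(fit_lin$tolerance,
               max(fit_lin$grid$tolerance[fit_lin$grid$admissible]))
})

test_that("average neighborhood size is non-decreasing in tolerance", {
  set.seed(8)
  mv <- random_model_vector(15)
  fit <- fit_npr(mv$x, mv$y)
  expect_true(all(diff(fit$grid$ave_n_star) >= -1e-12))
  expect_true(all(fit$grid$ave_n_star <= length(mv$x) - 1 + 1e-9))
})

test_that("all selection statistics are invariant to sample order", {
  set.seed(77)
  mv <- random_model_vector(18)
  perm <- sample(18)
  f1 <- fit_npr(mv$x, mv$y)
  f2 <- fit_npr(mv$x[perm], mv$y[perm])
  expect_equal(f1$tolerance, f2$tolerance)
  expect_equal(f1$xr2, f2$xr2)
  expect_equal(f1$ave_n_star, f2$ave_n_star)
  expect_equal(f1$loo$pred[perm], f2$loo$pred)
})

test_that("predicted curves interpolate and preserve monotone trends", {
  x <- c(0, 0.5, 1, 1.5, 2)
  y <- c(2.0, 1.4, 1.1, 1.0, 0.9)
  fit <- fit_npr(x, y, grid = tibble::tibble(fraction = 0.25, tolerance = 0.5))
  curve <- predict_curve(fit, at = c(0.25, 1.0, 1.75))
  expect_equal(curve$pred,
               c(1.718699208357, 1.186982347585, 0.949525874100),
               tolerance = 1e-10)

  # tiny tolerance: curve passes (numerically) through the observations
  tiny <- fit_npr(x, y, grid = tibble::tibble(fraction = 0.01, tolerance = 0.02),
                  min_nstar_frac = 0)
  at_obs <- predict_curve(tiny, at = x)
  expect_equal(at_obs$pred, y, tolerance = 1e-6)

  # smooth fit of noiseless monotone data stays monotone
  y_mono <- 3 - x
  fmono <- fit_npr(x, y_mono,
                   grid = tibble::tibble(fraction = 0.75, tolerance = 1.5))
  cmono <- predict_curve(fmono, at = seq(0, 2, by = 0.1))
  expect_true(all(diff(cmono$pred) <= 1e-12))
})

test_that("broom-style accessors expose the fit consistently", {
  set.seed(3)
  mv <- random_model_vector(20)
  fit <- fit_npr(mv$x, mv$y, response = "Hg")
  g <- glance(fit)
  expect_equal(g$xr2, fit$xr2)
  expect_equal(g$response, "Hg")
  td <- tidy(fit)
  expect_equal(sum(td$selected), 1L)
  expect_equal(td$tolerance[td$selected], fit$tolerance)
  au <- augment(fit)
  expect_equal(nrow(au), 20L)
  expect_equal(au$residual, mv$y - au$pred)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("degenerate weighted designs fall back to the local mean", {
  # all x identical except the target far away: weighted spread ~ 0
  x <- c(1, 1, 1, 5)
  y <- c(2, 3, 4, 10)
  est <- local_linear_estimate(x, y, target_x = 1, tolerance = 0.1,
                               exclude = 4L)
  expect_true(est$degenerate)
  expect_equal(est$estimate, mean(y[1:3]))
})
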