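test_that("the default design reproduces the study-like transect layout", {
  sim <- simulate_panel(sim_config(seed = 1))
  d <- dplyr::distinct(sim$panel, .data$sample_id, .data$distance_km)
  expect_equal(nrow(d), 36L)
  expect_equal(sum(d$distance_km < 1), 14L)
  expect_equal(sum(d$distance_km >= 1), 22L)
  expect_equal(sum(d$distance_km <= 0.5), 14L)   # ten scatter + four at 0.5
  expect_true(all(d$distance_km >= 0.1 & d$distance_km <= 32))
  reps <- dplyr::distinct(sim$panel, .data$sample_id, .data$replicate_group)
  expect_equal(sum(!is.na(reps$replicate_group)), 6L)
})

test_that("the same seed reproduces the panel bit-for-bit, different seeds differ", {
  a <- simulate_panel(sim_config(seed = 42))
  b <- simulate_panel(sim_config(seed = 42))
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth, b$truth)
  c <- simulate_panel(sim_config(seed = 43))
  expect_false(identical(a$panel$conc_ppm, c$panel$conc_ppm))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(simulate_panel(sim_config(seed = 5)))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("with all signal components off, concentrations equal background", {
  es <- default_element_specs()
  es$geogenic_beta <- 0
  es$plume_amplitude <- 0
  es$dust_amplitude <- 0
  es$noise_sd_log <- 1e-12
  sim <- simulate_panel(sim_config(seed = 3, element_specs = es))
  for (i in seq_len(nrow(es))) {
    vals <- sim$panel$conc_ppm[sim$panel$element == es$element[i]]
    expect_equal(vals, rep(es$background_ppm[i], 36), tolerance = 1e-9)
  }
})

test_that("the generative decomposition is honoured by the ground truth", {
  sim <- simulate_panel(sim_config(seed = 8))
  tr <- sim$truth[sim$truth$element == "Cr", ]
  spec <- default_element_specs()
  cr <- spec[spec$element == "Cr", ]
  rebuilt <- log10(cr$background_ppm) + tr$geogenic + tr$plume + tr$dust +
    tr$noise
  expect_equal(tr$log10_conc, rebuilt, tolerance = 1e-12)
  # plume term: amplitude/2 at d50, monotone declining in distance
  expect_equal(tr$plume[which.min(abs(tr$distance_km - cr$plume_d50_km))],
               cr$plume_amplitude / 2, tolerance = 0.05)
  expect_true(all(diff(tr$plume[order(tr$distance_km)]) <= 1e-12))
})

test_that("generator marginals are lognormal when amplitudes are zero", {
  es <- default_element_specs()[1, ]
  es$geogenic_beta <- 0; es$plume_amplitude <- 0; es$dust_amplitude <- 0
  es$noise_sd_log <- 0.15
  cfg <- sim_config(seed = 99, element_specs = es,
                    design = sim_design_dense(300))
  sim <- simulate_panel(cfg)
  logs <- log10(sim$panel$conc_ppm[sim$panel$element == "Hg"])
  expect_equal(mean(logs), log10(es$background_ppm), tolerance = 0.05)
  expect_equal(stats::sd(logs), 0.15, tolerance = 0.03)
  # calibration, not a hard gate: Shapiro on one fixed seed
  expect_gt(stats::shapiro.test(logs)$p.value, 0.001)
})

test_that("censoring scenarios hit their target fractions through the MDL quantile", {
  base <- sim_config(seed = 1)
  # use the pure-noise element so the lognormal quantile is exact
  es <- base$element_specs
  target_el <- "Mn"

  cfg0 <- make_censoring_scenario(base, target_el, 0)
  sim0 <- simulate_panel(cfg0)
  expect_equal(sum(sim0$panel$censored[sim0$panel$element == target_el]), 0L)

  cfg1 <- make_censoring_scenario(base, target_el, 1)
  sim1 <- simulate_panel(cfg1)
  expect_true(all(sim1$panel$censored[sim1$panel$element == target_el]))
  dl1 <- apply_detection_limits(sim1$panel, sim1$meta)
  expect_true(target_el %in% dl1$excluded$element)

  # target 0.30: excluded (>20% censored) in the median replicate
  cfg30 <- make_censoring_scenario(base, target_el, 0.30)
  excluded <- vapply(1:50, function(s) {
    cfg <- cfg30; cfg$seed <- 3000L + s
    sim <- simulate_panel(cfg)
    dl <- apply_detection_limits(sim$panel, sim$meta)
    target_el %in% dl$excluded$element
  }, logical(1))
  expect_gt(mean(excluded), 0.5)
})

test_that("scenario construction warns for patterned elements and validates inputs", {
  base <- sim_config(seed = 1)
  expect_warning(make_censoring_scenario(base, "Hg", 0.3), "signal components")
  expect_error(make_censoring_scenario(base, "Xx", 0.3), "unknown element")
  expect_error(make_censoring_scenario(base, "Mn", 1.5))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(design = tibble::tibble(distance_km = -1, n = 3L)))
  es <- default_element_specs()
  es$background_ppm[1] <- 0
  expect_error(sim_config(element_specs = es))
  expect_error(sim_config(design = tibble::tibble(distance_km = 1, n = 1L),
                          near_n = 0L))
})

test_that("recovery experiments summarise raw vs adjusted fits per element", {
  cfg <- sim_config(seed = 500)
  empty <- recovery_experiment(cfg, 0)
  expect_equal(nrow(empty), 0L)

  out <- recovery_experiment(cfg, 5, elements = c("Cr", "Ce", "Hg"))
  expect_equal(nrow(out), 3L)
  expect_equal(unique(out$n_replicates), 5L)
  # confounded plume element: adjustment helps consistently
  expect_gte(out$frac_adjusted_gt_raw[out$element == "Cr"], 0.8)
  # pure geogenic element: essentially no distance signal
  expect_lte(out$mean_raw_xr2[out$element == "Ce"], 0.15)
})
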