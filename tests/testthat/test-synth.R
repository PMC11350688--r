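test_that("gas-model configuration guards are enforced", {
  expect_error(gas_config(0.2, 5, angle = 3.5), "angle")
  expect_error(gas_config(0.2, 5, time_step = 0.01), "time_step")
  expect_error(gas_config(0.2, 5, arena_side = 0.05), "arena_side")
  expect_error(gas_config(0.1, 5, arena_side = 2), ">= 1 animal")
  cfg <- gas_config(0.2, 5)
  expect_equal(cfg$n_animals, 1L)
  expect_equal(cfg$realized_density, 0.2, tolerance = 1e-12)
  expect_lt(cfg$speed * cfg$time_step, cfg$radius / 2)
})

test_that("zero density yields zero encounters", {
  sim <- simulate_gas_model(gas_config(0, 5, arena_side = 2,
                                       duration_days = 10, seed = 1))
  expect_equal(sim$total_encounters, 0)
  expect_equal(sim$expected_rate, 0)
})

test_that("simulated encounter rate matches the closed-form expectation", {
  cfg <- gas_config(0.2, 5, n_detectors = 50, duration_days = 2000,
                    seed = 42)
  sim <- simulate_gas_model(cfg)
  # expectation D v r (2 + theta) / pi; ~914 expected encounters so the
  # Monte-Carlo SE is ~3.3% — allow 4 sigma
  expect_equal(sim$mean_daily_rate, sim$expected_rate, tolerance = 0.14)
  expect_equal(dim(sim$daily_counts), c(50L, 2000L))
  expect_equal(sum(sim$daily_counts), sim$total_encounters)
})

test_that("doubling speed doubles the encounter rate", {
  r1 <- simulate_gas_model(gas_config(0.3, 4, n_detectors = 60,
                                      duration_days = 1000, seed = 5))
  r2 <- simulate_gas_model(gas_config(0.3, 8, n_detectors = 60,
                                      duration_days = 1000, seed = 6))
  ratio <- r2$mean_daily_rate / r1$mean_daily_rate
  # ~660 and ~1320 expected encounters: ratio SE ~ 4.7%
  expect_equal(ratio, 2, tolerance = 0.2)
})

test_that("correlated turning preserves the encounter expectation", {
  sim <- simulate_gas_model(gas_config(0.3, 5, n_detectors = 40,
                                       duration_days = 1000,
                                       turn_model = "correlated",
                                       kappa = 8, seed = 9))
  expect_equal(sim$mean_daily_rate, sim$expected_rate, tolerance = 0.15)
})

test_that("simulations are deterministic under a fixed seed", {
  s1 <- simulate_gas_model(gas_config(0.2, 5, n_detectors = 3,
                                      duration_days = 50, seed = 77))
  s2 <- simulate_gas_model(gas_config(0.2, 5, n_detectors = 3,
                                      duration_days = 50, seed = 77))
  expect_identical(s1$daily_counts, s2$daily_counts)
  sv1 <- generate_detection_table(survey_config(seed = 3))
  sv2 <- generate_detection_table(survey_config(seed = 3))
  expect_identical(sv1$detections, sv2$detections)
  L1 <- generate_landscape(10, 10, seed = 4)
  L2 <- generate_landscape(10, 10, seed = 4)
  expect_identical(L1$layers, L2$layers)
  expect_identical(L1$presences, L2$presences)
})

test_that("survey generator totals stay within the Poisson bound", {
  cfg <- survey_config(seed = 55)
  sv <- generate_detection_table(cfg)
  for (sp in names(cfg$species_rates)) {
    expected <- sv$truth$expected_events[[sp]]
    realized <- sv$truth$n_events[[sp]] + 0  # after min-gap drops
    expect_lt(abs(realized - expected), 3 * sqrt(expected) + sv$truth$n_dropped)
  }
  # a zero-rate species never appears
  sv0 <- generate_detection_table(
    survey_config(species_rates = c(mishmi = 0.05, ghost = 0), seed = 8))
  expect_false("ghost" %in% sv0$detections$species)
})

test_that("independence filtering recovers generated events exactly", {
  sv <- generate_detection_table(survey_config(seed = 101))
  ev <- filter_independent(sv$detections, window_minutes = 30,
                           deployments = sv$deployments)
  expect_equal(nrow(ev), sum(sv$truth$n_events))
  per_sp <- table(ev$species)
  for (sp in names(sv$truth$n_events))
    expect_equal(unname(per_sp[sp]), sv$truth$n_events[[sp]],
                 ignore_attr = TRUE)
  # every record accounted for
  expect_equal(sum(ev$n_records), nrow(sv$detections))
})

test_that("generated activity times follow the configured mixture", {
  sv <- generate_detection_table(survey_config(seed = 17))
  ev <- filter_independent(sv$detections, 30,
                           deployments = sv$deployments)
  pk <- find_peaks(fit_circular_kde(time_to_radians(ev$event_start)))
  expect_equal(nrow(pk), 2)
  expect_true(all(hour_dist(sort(pk$peak_hour), c(8, 18)) <= 1.5))
})

test_that("flat Gibbs landscape gives uniform presences", {
  L <- generate_landscape(50, 50, n_layers = 2, true_lambdas = c(0, 0),
                          n_presences = 5000, seed = 23)
  counts <- tabulate(L$presences$row + (L$presences$col - 1) * 50,
                     nbins = 2500)
  gof <- suppressWarnings(chisq.test(counts, p = rep(1 / 2500, 2500)))
  expect_gt(gof$p.value, 0.001)
})

test_that("a dominant positive weight pulls presences up its layer", {
  L <- generate_landscape(30, 30, n_layers = 1, true_lambdas = 2,
                          n_presences = 300, seed = 31)
  f <- L$layers[[1]]
  pres_mean <- mean(f[cbind(L$presences$row, L$presences$col)])
  expect_gt(pres_mean, mean(f))
})
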