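test_that("circular KDE peaks at a single concentrated sample", {
  d <- fit_circular_kde(pi, bandwidth = 100)
  expect_equal(d$grid[which.max(d$density)], pi, tolerance = 0.02)
  expect_equal(d$density[1], d$density[length(d$density)])
  expect_true(all(d$density >= 0))
  expect_error(fit_circular_kde(numeric(0)), "at least one")
  expect_error(fit_circular_kde(7), "samples must")
})

test_that("density integrates to one and flattens for uniform samples", {
  set.seed(7)
  s <- runif(10000, 0, 2 * pi)
  d <- fit_circular_kde(s)
  integral <- sum(diff(d$grid) * (d$density[-1] +
                                    d$density[-length(d$density)]) / 2)
  expect_equal(integral, 1, tolerance = 1e-6)
  expect_lt(max(d$density) / min(d$density), 1.1)
})

test_that("KDE values match a direct kernel-sum at spot-check points", {
  set.seed(31)
  s <- rvonmises(80, hours_to_radians(9), 2.5)
  kappa <- 3
  d <- fit_circular_kde(s, bandwidth = kappa)
  pts <- seq(1, 513, by = 32)  # 16 grid points + the duplicated endpoint
  direct <- vapply(d$grid[pts], function(t)
    mean(oracle_dvm(t, mu = s, kappa = kappa)), numeric(1))
  # the fitted density renormalises the kernel sum by its trapezoidal
  # integral, which is 1 to well below this tolerance for smooth mixtures
  expect_equal(d$density[pts], direct, tolerance = 1e-6)
})

test_that("rotating all samples rotates the fitted density", {
  set.seed(12)
  s <- rvonmises(300, hours_to_radians(8), 3)
  delta <- hours_to_radians(5.5)
  d1 <- fit_circular_kde(s, bandwidth = 3)
  d2 <- fit_circular_kde((s + delta) %% (2 * pi), bandwidth = 3)
  m1 <- d1$grid[which.max(d1$density)]
  m2 <- d2$grid[which.max(d2$density)]
  shift <- (m2 - m1) %% (2 * pi)
  expect_equal(min(abs(shift - delta), abs(shift - delta - 2 * pi),
                   abs(shift - delta + 2 * pi)),
               0, tolerance = 0.05)
})

test_that("overlap coefficient: identity, disjointness, symmetry", {
  set.seed(44)
  s <- rvonmises(800, hours_to_radians(12), 3)
  d <- fit_circular_kde(s)
  expect_gte(overlap_coefficient(d, d), 0.99)
  a <- fit_circular_kde(rvonmises(800, hours_to_radians(2), 60))
  b <- fit_circular_kde(rvonmises(800, hours_to_radians(14), 60))
  expect_lte(overlap_coefficient(a, b), 0.05)
  expect_equal(overlap_coefficient(a, b), overlap_coefficient(b, a))
  expect_equal(overlap_coefficient(a, b, "sample"),
               overlap_coefficient(b, a, "sample"))
  expect_gte(overlap_coefficient(d, d, "sample"), 0.99)
})

test_that("fitted overlap tracks the quadrature truth for known mixtures", {
  mu1 <- hours_to_radians(8); mu2 <- hours_to_radians(13)
  k1 <- 3; k2 <- 2
  truth <- oracle_vm_overlap(mu1, k1, mu2, k2)
  set.seed(99)
  d1 <- fit_circular_kde(rvonmises(5000, mu1, k1))
  d2 <- fit_circular_kde(rvonmises(5000, mu2, k2))
  expect_lt(abs(overlap_coefficient(d1, d2) - truth), 0.02)
})

test_that("peak detection finds the bimodal morning/evening pattern", {
  set.seed(2024)
  s <- c(rvonmises(1000, hours_to_radians(8), 4),
         rvonmises(1000, hours_to_radians(18), 4))
  pk <- find_peaks(fit_circular_kde(s))
  expect_equal(nrow(pk), 2)
  expect_true(all(hour_dist(sort(pk$peak_hour), c(8, 18)) <= 1))
  # active intervals cover the peaks
  iv <- attr(pk, "active_intervals")
  expect_gt(nrow(iv), 0)

  uni <- find_peaks(fit_circular_kde(rvonmises(500, pi, 3)))
  expect_equal(nrow(uni), 1)

  flat <- fit_circular_kde(seq(0, 2 * pi, length.out = 101)[-101],
                           bandwidth = 0.5)
  expect_equal(nrow(find_peaks(flat)), 0)
})

test_that("elevation zones are half-open and lower-inclusive", {
  expect_equal(as.character(classify_zone(582)), "tropical_rainforest")
  expect_equal(as.character(classify_zone(2300)), "warm_temperate_mixed")
  expect_equal(as.character(classify_zone(4200)), "alpine_frost")
  expect_equal(as.character(classify_zone(c(1100, 2900, 3800, 4800))),
               c("subtropical_broadleaf", "cold_temperate_conifer",
                 "alpine_shrub_meadow", "ice_snow"))
  expect_error(classify_zone(-5), "elevation")
})

test_that("migration profile counts and season summary are conserved", {
  ev <- data.frame(
    event_start = as.POSIXct(c("2021-07-10 08:00", "2021-07-20 09:00",
                               "2021-01-05 10:00"), tz = "UTC"),
    elevation_m = c(4000, 4100, 2000))
  mp <- migration_profile(ev)
  expect_equal(sum(mp$counts), 3)
  expect_equal(mp$season$frac_above[mp$season$season == "rainy"], 1)
  expect_equal(mp$season$frac_above[mp$season$season == "dry"], 0)
  expect_equal(sum(mp$counts["Feb", ]), 0)
  expect_equal(rowSums(mp$counts)[["Jul"]], 2)
})

test_that("synthetic migratory surveys show the rainy-season uplift", {
  for (seed in c(1, 7, 13)) {
    sv <- generate_detection_table(survey_config(seed = seed))
    ev <- filter_independent(sv$detections, 30,
                             deployments = sv$deployments)
    mp <- migration_profile(ev)
    rainy <- mp$season$frac_above[mp$season$season == "rainy"]
    dry <- mp$season$frac_above[mp$season$season == "dry"]
    expect_gt(rainy, dry)
    expect_equal(sum(mp$counts), nrow(ev))
  }
})
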