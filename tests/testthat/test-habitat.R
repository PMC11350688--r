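test_that("a constant layer yields uniform suitability", {
  lay <- matrix(5, 4, 5)
  pres <- data.frame(row = c(1, 2, 3, 4, 1), col = c(1, 2, 3, 4, 5))
  fit <- fit_maxent(pres, lay, regularization = 0.01)
  expect_true(fit$converged)
  expect_equal(unname(fit$lambda), 0, tolerance = 1e-8)
  expect_equal(max(fit$p) - min(fit$p), 0, tolerance = 1e-12)
  expect_equal(sum(fit$p), 1, tolerance = 1e-9)
})

test_that("one-layer fit matches a brute-force search of the objective", {
  set.seed(2)
  lay <- matrix(rnorm(10), 2, 5)
  pres <- data.frame(row = c(1, 2, 1, 2, 1, 2), col = c(1, 1, 2, 3, 4, 5))
  reg <- 0.05
  fit <- fit_maxent(pres, lay, regularization = reg)
  # identical penalized objective, minimised by exhaustive grid search
  x <- as.numeric(scale(as.numeric(lay)))
  xp <- mean(x[pres$row + (pres$col - 1) * 2])
  grid <- seq(-5, 5, by = 5e-4)
  obj <- vapply(grid, function(l) {
    eta <- l * x
    m <- max(eta)
    -l * xp + m + log(sum(exp(eta - m))) + reg / 2 * l^2
  }, numeric(1))
  expect_lt(abs(unname(fit$lambda) - grid[which.min(obj)]), 1e-3)
  # stationarity: feature gap equals -reg * lambda
  expect_equal(unname(fit$feature_gap), -reg * unname(fit$lambda),
               tolerance = 1e-6)
  expect_true(all(diff(fit$trace) <= 1e-12))
})

test_that("presences from a known Gibbs landscape are recovered", {
  L <- generate_landscape(50, 50, n_layers = 3,
                          true_lambdas = c(1.2, -0.8, 0.5),
                          n_presences = 200, seed = 11)
  fit <- fit_maxent(L$presences, L$layers, regularization = 0.01)
  expect_true(fit$converged)
  expect_gte(cor(as.numeric(L$true_p), as.numeric(fit$p),
                 method = "spearman"), 0.9)
  # suitability reported on [0, 1] for both transforms
  expect_true(all(fit$suitability$index >= 0 & fit$suitability$index <= 1))
  raw <- fit_maxent(L$presences, L$layers, regularization = 0.01,
                    transform = "raw")
  expect_equal(max(raw$suitability$index), 1)
})

test_that("maxent input contracts are enforced", {
  lay <- matrix(rnorm(25), 5, 5)
  expect_error(fit_maxent(data.frame(row = 1:3, col = 1:3), lay),
               "at least 5")
  expect_error(fit_maxent(data.frame(row = c(1:5), col = c(1:4, 9)), lay),
               "extent")
  lay[2, 2] <- NA
  expect_error(fit_maxent(data.frame(row = rep(2, 5), col = rep(2, 5)), lay),
               "masked")
})

test_that("suitability classes partition the grid at the printed cuts", {
  expect_equal(as.character(classify_suitability(c(0.6, 0.7, 0.49, 0, 1))),
               c("potential", "high", "unsuitable", "unsuitable", "high"))
  set.seed(5)
  g <- suitability_grid(matrix(runif(200), 10, 20))
  cls <- classify_suitability(g)
  expect_equal(sum(table(cls)), 200)  # partition: classes cover all cells
  expect_equal(habitat_area(g, "unsuitable") + habitat_area(g, "potential") +
                 habitat_area(g, "high"), 200)
})

test_that("habitat area equals the counting oracle and is monotone", {
  set.seed(6)
  m <- matrix(runif(300), 15, 20)
  m[sample(300, 30)] <- NA
  g <- suitability_grid(m, cell_resolution = 1)
  for (thr in c(0, 0.3, 0.5, 0.7, 1)) {
    n <- 0
    for (i in 1:15) for (j in 1:20)
      if (!is.na(m[i, j]) && m[i, j] >= thr) n <- n + 1
    expect_equal(habitat_area(g, thr), n)
  }
  thresholds <- seq(0, 1, by = 0.1)
  areas <- vapply(thresholds, function(t) habitat_area(g, t), numeric(1))
  expect_true(all(diff(areas) <= 0))
  g2 <- suitability_grid(m, cell_resolution = 4)
  expect_equal(habitat_area(g2, 0.5), 4 * habitat_area(g, 0.5))
  expect_equal(habitat_area(suitability_grid(matrix(0.1, 3, 3)), 0.5), 0)
})

test_that("overlap ratios follow hand-counted constructions", {
  a <- matrix(0, 5, 8); b <- matrix(0, 5, 8)
  a[1:10] <- 0.9            # |A| = 10
  b[7:26] <- 0.9            # |B| = 20, |A intersect B| = 4
  ga <- suitability_grid(a); gb <- suitability_grid(b)
  ov <- overlap_ratio(ga, gb, threshold = 0.5)
  expect_equal(as.numeric(ov), c(0.4, 0.2))
  expect_equal(attr(ov, "overlap_km2"), 4)
  expect_equal(as.numeric(overlap_ratio(ga, ga)), c(1, 1))
  expect_equal(as.numeric(overlap_ratio(ga, gb, base = "union")),
               rep(4 / 26, 2))
  disj <- suitability_grid(matrix(c(rep(0.9, 20), rep(0, 20)), 5, 8))
  disj2 <- suitability_grid(matrix(c(rep(0, 20), rep(0.9, 20)), 5, 8))
  expect_equal(as.numeric(overlap_ratio(disj, disj2)), c(0, 0))
  expect_equal(as.numeric(overlap_ratio(ga, gb, report = TRUE)), c(0.4, 0.2))
})

test_that("ASCII grids round-trip through write and read", {
  set.seed(8)
  m <- matrix(round(runif(35), 4), 5, 7)
  m[c(3, 18)] <- NA
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m, f, cellsize = 1, xllcorner = 94.5, yllcorner = 29)
  m2 <- read_ascii_grid(f)
  expect_equal(unname(m2[, ]), unname(m), tolerance = 1e-12)
  expect_equal(attr(m2, "cellsize"), 1)
  expect_equal(attr(m2, "xllcorner"), 94.5)
  expect_true(all(is.na(m2[c(3, 18)])))
})
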