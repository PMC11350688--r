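# Daily activity rhythms on the 24-h circle: von Mises kernel density
# estimation, overlap coefficients between two rhythms, circular peak
# detection, elevation zones and seasonal migration profiles.

#' Convert clock times to circular coordinates
#'
#' Maps time of day onto the circle, 24 h = 2*pi radians.
#'
#' @param x POSIXct timestamps (`time_to_radians`) or clock hours
#'   (`hours_to_radians`).
#' @return radians in `[0, 2*pi)`.
#' @export
time_to_radians <- function(x) {
  lt <- as.POSIXlt(x)
  hours_to_radians(lt$hour + lt$min / 60 + lt$sec / 3600)
}

#' @rdname time_to_radians
#' @export
hours_to_radians <- function(x) (x %% 24) / 24 * 2 * pi

#' @rdname time_to_radians
#' @export
radians_to_hours <- function(x) (x %% (2 * pi)) / (2 * pi) * 24

# von Mises density, numerically safe for large kappa via scaled Bessel I0.
dvonmises <- function(theta, mu, kappa) {
  exp(kappa * (cos(theta - mu) - 1)) / (2 * pi * besselI(kappa, 0,
                                                        expon.scaled = TRUE))
}

#' Sample from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler; `kappa = 0` gives the circular
#' uniform.
#'
#' @param n sample size.
#' @param mu mean direction (radians).
#' @param kappa concentration, >= 0.
#' @return radians in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- (mu + sign(runif(1) - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

# ML concentration of a von Mises sample: solve A(kappa) = Rbar where
# A = I1/I0. Clamped to [0, 500] for numerical safety.
vm_ml_kappa <- function(theta) {
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  if (rbar >= 1 - 1e-10) return(500)
  if (rbar < 1e-10) return(0)
  afun <- function(k) besselI(k, 1, TRUE) / besselI(k, 0, TRUE) - rbar
  uniroot(afun, c(1e-8, 500), tol = 1e-10)$root
}

# Rule-of-thumb smoothing concentration for a von Mises kernel (Taylor
# 2008): nu = (3 n k^2 I2(2k) / (4 sqrt(pi) I0(k)^2))^(2/5), computed with
# exponentially scaled Bessels (I2(2k)/I0(k)^2 = I2s(2k)/I0s(k)^2 since the
# exp(2k) factors cancel).
vm_bandwidth <- function(theta) {
  n <- length(theta)
  kap <- min(vm_ml_kappa(theta), 200)
  if (kap < 1e-6) return(1)  # near-uniform sample: mild smoothing
  ratio <- besselI(2 * kap, 2, TRUE) / besselI(kap, 0, TRUE)^2
  (3 * n * kap^2 * ratio / (4 * sqrt(pi)))^(2 / 5)
}

#' Circular kernel density estimate of a daily activity rhythm
#'
#' Fits a von Mises kernel mixture to detection times on the 24-h circle,
#' evaluated on a regular grid (default 512 intervals; the grid carries
#' `n_grid + 1` points with the endpoint duplicating the origin, so the
#' density is stored periodically). The smoothing concentration defaults to
#' the von Mises plug-in rule times `adjust^(-2)` (larger `adjust` =
#' smoother, matching linear-KDE convention).
#'
#' @param samples detection times in radians on `[0, 2*pi)` (see
#'   [time_to_radians()]); at least one.
#' @param bandwidth kernel concentration parameter kappa (> 0); `NULL` for
#'   the plug-in rule.
#' @param adjust multiplier on the plug-in smoothing scale (default 1).
#' @param n_grid number of grid intervals (default 512).
#' @return object of class `activity_density`: `grid` (radians,
#'   `n_grid + 1` points, last = first + 2*pi), `hour` (clock hours),
#'   `density` (first value = last value), `bandwidth`, `n`, `samples`.
#' @export
fit_circular_kde <- function(samples, bandwidth = NULL, adjust = 1,
                             n_grid = 512) {
  if (length(samples) < 1L) stop("need at least one sample")
  if (any(samples < 0 | samples >= 2 * pi))
    stop("samples must lie in [0, 2*pi)")
  if (is.null(bandwidth)) bandwidth <- vm_bandwidth(samples) / adjust^2
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)
  dens <- eval_vm_mixture(grid, samples, bandwidth)
  # renormalise so the trapezoidal integral over the circle is exactly 1
  dens <- dens / trap_circ(grid, dens)
  structure(list(grid = grid, hour = radians_to_hours(grid[-(n_grid + 1)]),
                 density = dens, bandwidth = bandwidth,
                 n = length(samples), samples = samples),
            class = "activity_density")
}

# mixture of von Mises kernels centred on the samples, equal weights
eval_vm_mixture <- function(grid, samples, kappa) {
  i0 <- besselI(kappa, 0, expon.scaled = TRUE)
  out <- numeric(length(grid))
  # chunk over samples to bound the outer-product size
  chunk <- max(1L, floor(2e6 / length(grid)))
  for (start in seq(1L, length(samples), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(samples))
    out <- out + colSums(exp(kappa * (cos(outer(samples[idx], grid, "-")) - 1)))
  }
  out / (length(samples) * 2 * pi * i0)
}

# trapezoidal integral over one full circle (grid must close the circle)
trap_circ <- function(grid, dens) {
  sum(diff(grid) * (dens[-1] + dens[-length(dens)]) / 2)
}

#' @export
print.activity_density <- function(x, ...) {
  cat(sprintf("circular activity density: n = %d, kappa = %.3f, grid = %d\n",
              x$n, x$bandwidth, length(x$grid) - 1L))
  pk <- find_peaks(x)
  if (nrow(pk))
    cat("  peaks at", paste(sprintf("%05.2f h", pk$peak_hour), collapse = ", "),
        "\n")
  invisible(x)
}

#' Activity overlap coefficient
#'
#' The coefficient of overlap Delta = integral of min(f_A, f_B) over the
#' 24-h circle; 1 for identical rhythms, 0 for disjoint ones. The `"grid"`
#' variant integrates the pointwise minimum of the two fitted densities by
#' the trapezoidal rule on their (common) grid. The `"sample"` variant
#' evaluates both fitted densities at the stored sample points and averages
#' min(1, f_other/f_own) over each sample set — the estimator family that
#' weights the comparison by where the data actually lie.
#'
#' @param d_a,d_b `activity_density` objects on a common grid.
#' @param estimator_variant `"grid"` (default) or `"sample"`.
#' @return Delta in `[0, 1]`.
#' @export
overlap_coefficient <- function(d_a, d_b,
                                estimator_variant = c("grid", "sample")) {
  estimator_variant <- match.arg(estimator_variant)
  stopifnot(inherits(d_a, "activity_density"),
            inherits(d_b, "activity_density"))
  if (estimator_variant == "grid") {
    if (length(d_a$grid) != length(d_b$grid) ||
        max(abs(d_a$grid - d_b$grid)) > 1e-12)
      stop("densities must share a common grid")
    return(min(1, trap_circ(d_a$grid, pmin(d_a$density, d_b$density))))
  }
  eval_at <- function(d, t) {
    eval_vm_mixture(t, d$samples, d$bandwidth)
  }
  fa_a <- eval_at(d_a, d_a$samples); fb_a <- eval_at(d_b, d_a$samples)
  fa_b <- eval_at(d_a, d_b$samples); fb_b <- eval_at(d_b, d_b$samples)
  min(1, mean(c(pmin(1, fb_a / fa_a), pmin(1, fa_b / fb_b))))
}

#' Detect activity peaks on the circle
#'
#' Circularly-aware local maxima of a fitted activity density, filtered by
#' topographic prominence (height above the higher of the two key saddles,
#' walking each way around the circle). Also returns, as the
#' `"active_intervals"` attribute, the circular runs of grid hours where the
#' density exceeds its circular mean (1 / 2*pi after normalisation).
#'
#' @param density `activity_density` object.
#' @param prominence minimum prominence as a fraction of the maximum density
#'   (default 0.1).
#' @return data.frame with `peak_hour`, `height`, `prominence`, ordered by
#'   height; attribute `active_intervals` is a data.frame of
#'   `start_hour`/`end_hour` runs (circular, half-open on the grid).
#' @export
find_peaks <- function(density, prominence = 0.1) {
  stopifnot(inherits(density, "activity_density"))
  d <- density$density
  d <- d[-length(d)]  # drop duplicated endpoint
  n <- length(d)
  hrs <- density$hour
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  is_max <- d > d[prv] & d >= d[nxt]
  prom <- rep(NA_real_, n)
  for (i in which(is_max)) {
    side_min <- c(NA_real_, NA_real_)
    for (s in 1:2) {
      j <- i
      m <- d[i]
      step <- if (s == 1) 1L else -1L
      for (k in seq_len(n - 1L)) {
        j <- ((j - 1L + step) %% n) + 1L
        if (d[j] > d[i]) break
        if (d[j] < m) m <- d[j]
      }
      side_min[s] <- m
    }
    prom[i] <- d[i] - max(side_min)
  }
  thr <- prominence * max(d)
  keep <- which(is_max & prom >= thr & prom > 0)
  out <- data.frame(peak_hour = hrs[keep], height = d[keep],
                    prominence = prom[keep])
  out <- out[order(-out$height), , drop = FALSE]
  rownames(out) <- NULL
  above <- d > mean(d)
  attr(out, "active_intervals") <- circular_runs(above, hrs)
  out
}

# contiguous circular runs of TRUE, reported as [start_hour, end_hour]
circular_runs <- function(flag, hrs) {
  n <- length(flag)
  if (all(flag))
    return(data.frame(start_hour = 0, end_hour = 24))
  if (!any(flag))
    return(data.frame(start_hour = numeric(), end_hour = numeric()))
  starts <- which(flag & !flag[c(n, 1:(n - 1L))])
  ends <- which(flag & !flag[c(2:n, 1L)])
  # pair each start with the first end at or after it (circularly)
  ends_ord <- vapply(starts, function(s) {
    cand <- ends[ends >= s]
    if (length(cand)) cand[1] else ends[1]
  }, numeric(1))
  data.frame(start_hour = hrs[starts], end_hour = hrs[ends_ord])
}

ZONE_LABELS <- c("tropical_rainforest", "subtropical_broadleaf",
                 "warm_temperate_mixed", "cold_temperate_conifer",
                 "alpine_shrub_meadow", "alpine_frost", "ice_snow")
ZONE_EDGES <- c(0, 1100, 2300, 2900, 3800, 4200, 4800, Inf)

#' Elevation zone of the Eastern Himalayan vegetation belts
#'
#' Maps elevation (m ASL) to the seven vertical vegetation belts of the
#' study system: tropical rainforest (< 1100 m), subtropical broad-leaved
#' (1100-2300), warm-temperate mixed conifer/broad-leaved (2300-2900),
#' cold-temperate conifer (2900-3800), alpine shrub meadow (3800-4200),
#' alpine frost-weathering (4200-4800) and permanent ice/snow (>= 4800).
#' Intervals are half-open, lower-inclusive, so printed boundary elevations
#' classify deterministically.
#'
#' @param elevation_m elevations in metres, >= 0.
#' @return factor with the seven zone levels.
#' @export
classify_zone <- function(elevation_m) {
  if (any(elevation_m < 0)) stop("elevation must be >= 0")
  idx <- findInterval(elevation_m, ZONE_EDGES, left.open = FALSE)
  factor(ZONE_LABELS[idx], levels = ZONE_LABELS)
}

#' Month-by-elevation migration profile
#'
#' Cross-tabulates independent events by calendar month and elevation zone,
#' and summarises the seasonal altitudinal shift: the fraction of events
#' above `elevation_cut` in the rainy season (May-October) versus the dry
#' season (November-April).
#'
#' @param events data.frame with an `event_start` (POSIXct) or `date`
#'   column and `elevation_m`.
#' @param elevation_cut high-elevation cut in metres (default 3500, the
#'   rainy-season activity floor).
#' @param rainy_months months forming the rainy season (default 5:10).
#' @return object of class `migration_profile`: `counts` (12 x 7 month-by-
#'   zone matrix), `season` (data.frame season, n_events, n_above,
#'   frac_above), `elevation_cut`.
#' @export
migration_profile <- function(events, elevation_cut = 3500,
                              rainy_months = 5:10) {
  dt <- if (!is.null(events$date)) as.Date(events$date)
        else as.Date(events$event_start)
  if (is.null(events$elevation_m)) stop("events must carry elevation_m")
  month <- as.integer(format(dt, "%m"))
  zone <- classify_zone(events$elevation_m)
  counts <- table(factor(month, levels = 1:12), zone)
  dimnames(counts) <- list(month = month.abb, zone = ZONE_LABELS)
  season <- ifelse(month %in% rainy_months, "rainy", "dry")
  above <- events$elevation_m > elevation_cut
  seas <- do.call(rbind, lapply(c("rainy", "dry"), function(s) {
    sel <- season == s
    data.frame(season = s, n_events = sum(sel), n_above = sum(above & sel),
               frac_above = if (any(sel)) sum(above & sel) / sum(sel)
                            else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(counts = unclass(counts), season = seas,
                 elevation_cut = elevation_cut),
            class = "migration_profile")
}

#' @export
print.migration_profile <- function(x, ...) {
  cat("month x elevation-zone event counts (", sum(x$counts), "events )\n")
  print(x$counts[rowSums(x$counts) > 0, colSums(x$counts) > 0, drop = FALSE])
  cat(sprintf("fraction above %d m: rainy %.3f, dry %.3f\n",
              x$elevation_cut,
              x$season$frac_above[x$season$season == "rainy"],
              x$season$frac_above[x$season$season == "dry"]))
  invisible(x)
}
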