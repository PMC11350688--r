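# Independent oracles and tiny fixture builders used across the suite.

# build a detection data.frame from vectors (UTC timestamps)
make_detections <- function(station, time, species = "takin",
                            group_count = 1L, media_type = "photo") {
  data.frame(station_id = station,
             timestamp = as.POSIXct(time, tz = "UTC"),
             species = species,
             group_count = as.integer(group_count),
             media_type = media_type,
             stringsAsFactors = FALSE)
}

make_deployments <- function(station_id, elevation_m = 2000,
                             survey_area = "A",
                             start_date = as.Date("2021-01-01"),
                             end_date = as.Date("2021-12-31")) {
  data.frame(station_id = station_id, survey_area = survey_area,
             lon = 95, lat = 29.5, elevation_m = elevation_m,
             start_date = start_date, end_date = end_date,
             sector_radius_km = 0.01, sector_angle_rad = 0.872,
             stringsAsFactors = FALSE)
}

# Brute-force independent-event count: repeatedly take the earliest
# remaining record in a station x species series and discard everything
# within the window of it. O(n^2), independent of the package's single-pass
# grouping.
brute_force_event_count <- function(records, window_minutes) {
  w <- window_minutes * 60
  total <- 0L
  for (st in unique(records$station_id)) {
    for (sp in unique(records$species)) {
      tt <- sort(as.numeric(
        records$timestamp[records$station_id == st &
                            records$species == sp]))
      while (length(tt)) {
        total <- total + 1L
        tt <- tt[tt >= tt[1] + w]
      }
    }
  }
  total
}

# von Mises density written from scratch (unscaled Bessel; fine for the
# moderate concentrations used in tests)
oracle_dvm <- function(theta, mu, kappa) {
  exp(kappa * cos(theta - mu)) / (2 * pi * besselI(kappa, 0))
}

# quadrature of min(f1, f2) for two von Mises densities
oracle_vm_overlap <- function(mu1, k1, mu2, k2, n = 2e5) {
  t <- seq(0, 2 * pi, length.out = n + 1)
  f <- pmin(oracle_dvm(t, mu1, k1), oracle_dvm(t, mu2, k2))
  sum(diff(t) * (f[-1] + f[-length(f)]) / 2)
}

# circular distance in hours
hour_dist <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}
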