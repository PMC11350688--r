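# Synthetic-data generators: the ideal-gas movement simulator that
# validates the REM encounter-width, a camera-trap survey generator with
# bimodal activity and seasonal elevation structure, and a Gibbs-landscape
# generator for the suitability model.

#' Configuration for the ideal-gas encounter simulator
#'
#' Animals are points placed uniformly on a square torus (no edge loss, so
#' the closed-form encounter rate is exact) moving at constant speed; each
#' arena holds one stationary sector detector (radius `radius`, opening
#' angle `angle`) at its centre. `n_detectors` independent arenas are run.
#'
#' @param true_density target density in animals/km^2, >= 0.
#' @param speed travel speed in km/day, > 0.
#' @param radius detector radius in km (default 0.01).
#' @param angle detector opening angle in radians, in (0, pi\] (default
#'   0.872) — the range where the sector is convex and the mean profile
#'   width r(2+theta)/pi applies.
#' @param arena_side torus edge in km; default the smallest arena holding
#'   one animal at `true_density`. The arena must hold at least one whole
#'   animal and be wide enough that the detector never straddles the wrap.
#' @param duration_days days simulated per detector.
#' @param time_step step duration in days; the step length
#'   `speed * time_step` must stay below `radius / 2` (enforced). Default
#'   gives a step of 0.45 * radius.
#' @param turn_model `"straight"` (heading redrawn uniformly each day) or
#'   `"correlated"` (von Mises(`kappa`) turn each step).
#' @param kappa turning concentration for the correlated model.
#' @param n_detectors number of independent detector-arenas.
#' @param seed optional integer seed applied inside
#'   [simulate_gas_model()].
#' @return object of class `gas_config`.
#' @export
gas_config <- function(true_density, speed, radius = 0.01, angle = 0.872,
                       arena_side = NULL, duration_days = 1000,
                       time_step = NULL,
                       turn_model = c("straight", "correlated"),
                       kappa = 5, n_detectors = 1, seed = NULL) {
  turn_model <- match.arg(turn_model)
  if (true_density < 0) stop("true_density must be >= 0")
  if (speed <= 0) stop("speed must be > 0")
  if (radius <= 0) stop("radius must be > 0")
  if (angle <= 0 || angle > pi)
    stop("angle must lie in (0, pi]: the sector profile-width derivation ",
         "applies only to convex sectors")
  if (is.null(arena_side))
    arena_side <- if (true_density > 0) sqrt(1 / true_density) else 1
  if (arena_side <= 8 * radius)
    stop("arena_side too small relative to the detector")
  n_animals <- round(true_density * arena_side^2)
  if (true_density > 0 && n_animals < 1)
    stop("arena_side^2 * true_density must be >= 1 animal")
  if (is.null(time_step)) time_step <- 0.45 * radius / speed
  step_len <- speed * time_step
  if (step_len >= radius / 2)
    stop(sprintf(
      "time_step too coarse: step length %.4g km must be < radius/2 = %.4g",
      step_len, radius / 2))
  if (duration_days < 1) stop("duration_days must be >= 1")
  structure(list(true_density = true_density, speed = speed, radius = radius,
                 angle = angle, arena_side = arena_side,
                 n_animals = n_animals,
                 realized_density = n_animals / arena_side^2,
                 duration_days = as.integer(duration_days),
                 time_step = time_step,
                 steps_per_day = max(1L, as.integer(round(1 / time_step))),
                 turn_model = turn_model, kappa = kappa,
                 n_detectors = as.integer(n_detectors), seed = seed),
            class = "gas_config")
}

#' Expected daily encounter rate under the gas model
#'
#' `D * v * r * (2 + theta) / pi` — density times speed times the mean
#' profile width of the sector detector.
#'
#' @param config [gas_config()] (the realized, integer-animal density is
#'   used).
#' @return expected encounters per detector per day.
#' @export
expected_encounter_rate <- function(config) {
  stopifnot(inherits(config, "gas_config"))
  config$realized_density * config$speed * config$radius *
    (2 + config$angle) / pi
}

#' Run the ideal-gas encounter simulation
#'
#' Simulates point animals on independent torus arenas and logs an
#' encounter whenever an animal's step segment enters its arena's sector
#' detector from outside (exact segment-sector intersection, so no
#' detections are lost to discretisation; the step-length guard in
#' [gas_config()] bounds the per-step geometry regardless).
#'
#' @param config [gas_config()].
#' @return list: `daily_counts` (n_detectors x days integer matrix),
#'   `total_encounters`, `mean_daily_rate`, `expected_rate` (closed form at
#'   the realized density), `realized_density`, `config`.
#' @export
simulate_gas_model <- function(config) {
  stopifnot(inherits(config, "gas_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$n_animals == 0L) {
    counts <- matrix(0L, config$n_detectors, config$duration_days)
  } else {
    counts <- sim_gas_core(
      n_rep = config$n_detectors, n_animals = config$n_animals,
      side = config$arena_side, r = config$radius, theta = config$angle,
      azimuth = 0, v = config$speed,
      steps_per_day = config$steps_per_day, days = config$duration_days,
      turn_model = if (config$turn_model == "straight") 0L else 1L,
      kappa = config$kappa)
  }
  list(daily_counts = counts,
       total_encounters = sum(counts),
       mean_daily_rate = mean(counts),
       expected_rate = expected_encounter_rate(config),
       realized_density = config$realized_density,
       config = config)
}

#' Estimate density from a gas-model simulation via the REM
#'
#' Applies the encounter-width inversion to the simulated encounter stream:
#' treats every detector-day as a camera-day and every encounter as an
#' independent event.
#'
#' @param sim result of [simulate_gas_model()].
#' @return density estimate in animals/km^2.
#' @export
rem_from_simulation <- function(sim) {
  cfg <- sim$config
  params <- rem_params(speeds = cfg$speed, radius = cfg$radius,
                       angle = cfg$angle)
  rate <- mcv(sim$total_encounters, length(sim$daily_counts), decimals = NULL)
  rem_density(rate, cfg$speed, params)
}

#' Configuration for the synthetic camera-trap survey generator
#'
#' Emulates the monitored system: stations spread over an elevation
#' gradient, species detected as Poisson event streams, bimodal daily
#' activity (default peaks at 08:00 and 18:00), and seasonal altitudinal
#' migration (rainy-season May-October events at high elevation, dry-season
#' events low).
#'
#' @param n_stations number of camera stations (default 50).
#' @param species_rates named vector of independent events per station-day
#'   (default `c(mishmi = 0.03, bhutan = 0.05)`).
#' @param activity_means,activity_kappas,activity_weights von Mises mixture
#'   of daily activity, in clock hours / concentrations / weights summing
#'   to 1; defaults place peaks in the 07:00-09:00 and 16:00-20:00 windows.
#' @param rainy_elev_mean,rainy_elev_sd,dry_elev_mean,dry_elev_sd seasonal
#'   event-elevation distributions in m (defaults N(4000, 200) rainy,
#'   N(2000, 300) dry).
#' @param rainy_months rainy-season months (default May-October).
#' @param elev_range station elevation span in m (default 500-4500).
#' @param start_date,end_date survey window (defaults one year, 2021).
#' @param min_event_gap_min minimum spacing between true events at one
#'   station x species, minutes (default 60: twice the default independence
#'   window, so filtering recovers the truth exactly).
#' @param records_per_event photos per triggered event (default 3, the
#'   burst size; records within an event are seconds apart).
#' @param seed optional integer seed.
#' @return object of class `survey_config`.
#' @export
survey_config <- function(n_stations = 50,
                          species_rates = c(mishmi = 0.03, bhutan = 0.05),
                          activity_means = c(8, 18),
                          activity_kappas = c(4, 4),
                          activity_weights = c(0.5, 0.5),
                          rainy_elev_mean = 4000, rainy_elev_sd = 200,
                          dry_elev_mean = 2000, dry_elev_sd = 300,
                          rainy_months = 5:10,
                          elev_range = c(500, 4500),
                          start_date = as.Date("2021-01-01"),
                          end_date = as.Date("2021-12-31"),
                          min_event_gap_min = 60,
                          records_per_event = 3,
                          seed = NULL) {
  if (any(species_rates < 0)) stop("species rates must be >= 0")
  if (abs(sum(activity_weights) - 1) > 1e-8)
    stop("activity weights must sum to 1")
  if (length(activity_means) != length(activity_kappas) ||
      length(activity_means) != length(activity_weights))
    stop("activity mixture components must align")
  if (end_date < start_date) stop("end_date precedes start_date")
  structure(as.list(environment()), class = "survey_config")
}

#' Generate a synthetic camera-trap survey
#'
#' Draws independent events per station x species as a Poisson process over
#' the survey window, gives each event a time of day from the activity
#' mixture and an elevation-matched station from the seasonal migration
#' model, expands events into record bursts, and returns the tables in the
#' exact dialect [read_detections()] / [read_deployments()] consume, plus a
#' truth record holding every generating parameter and realized count.
#'
#' @param config [survey_config()].
#' @return list: `detections`, `deployments` (data.frames), `truth` (list:
#'   `config`, `n_events` named per species, `events` data.frame,
#'   `expected_events` named per species, `n_dropped` events removed by the
#'   minimum-gap guarantee).
#' @export
generate_detection_table <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_days <- as.numeric(cfg$end_date - cfg$start_date) + 1
  stations <- data.frame(
    station_id = sprintf("ST%03d", seq_len(cfg$n_stations)),
    survey_area = paste0("area_",
                         rep_len(LETTERS[1:4], cfg$n_stations)),
    lon = round(runif(cfg$n_stations, 94.5, 95.5), 5),
    lat = round(runif(cfg$n_stations, 29.0, 30.0), 5),
    elevation_m = round(seq(cfg$elev_range[1], cfg$elev_range[2],
                            length.out = cfg$n_stations)),
    start_date = cfg$start_date, end_date = cfg$end_date,
    sector_radius_km = 0.01, sector_angle_rad = 0.872,
    stringsAsFactors = FALSE)
  station_days <- cfg$n_stations * n_days
  expected <- cfg$species_rates * station_days

  all_events <- list()
  n_dropped <- 0L
  for (sp in names(cfg$species_rates)) {
    n_ev <- rpois(1, expected[[sp]])
    if (n_ev == 0L) next
    day_off <- sample.int(n_days, n_ev, replace = TRUE) - 1L
    date <- cfg$start_date + day_off
    month <- as.integer(format(date, "%m"))
    rainy <- month %in% cfg$rainy_months
    target_elev <- ifelse(rainy,
                          rnorm(n_ev, cfg$rainy_elev_mean, cfg$rainy_elev_sd),
                          rnorm(n_ev, cfg$dry_elev_mean, cfg$dry_elev_sd))
    st_idx <- vapply(target_elev, function(e)
      which.min(abs(stations$elevation_m - e)), integer(1))
    comp <- sample.int(length(cfg$activity_weights), n_ev, replace = TRUE,
                       prob = cfg$activity_weights)
    tod <- rvonmises(n_ev, hours_to_radians(cfg$activity_means[1]), 0)  # init
    for (k in seq_along(cfg$activity_weights)) {
      sel <- comp == k
      if (any(sel))
        tod[sel] <- rvonmises(sum(sel),
                              hours_to_radians(cfg$activity_means[k]),
                              cfg$activity_kappas[k])
    }
    secs <- round(radians_to_hours(tod) * 3600)
    ts <- as.POSIXct(date, tz = "UTC") + secs
    ev <- data.frame(species = sp,
                     station_id = stations$station_id[st_idx],
                     elevation_m = stations$elevation_m[st_idx],
                     timestamp = ts, date = date,
                     group_count = 1L + rpois(n_ev, 1.5),
                     stringsAsFactors = FALSE)
    # enforce the minimum between-event gap within station x species so the
    # independence filter recovers the truth exactly
    ev <- ev[order(ev$station_id, ev$timestamp), , drop = FALSE]
    keep <- rep(TRUE, nrow(ev))
    last_kept <- -Inf
    last_station <- ""
    for (i in seq_len(nrow(ev))) {
      ti <- as.numeric(ev$timestamp[i])
      if (ev$station_id[i] != last_station) {
        last_station <- ev$station_id[i]
        last_kept <- ti
      } else if (ti - last_kept < cfg$min_event_gap_min * 60) {
        keep[i] <- FALSE
        next
      } else last_kept <- ti
    }
    n_dropped <- n_dropped + sum(!keep)
    all_events[[sp]] <- ev[keep, , drop = FALSE]
  }
  events <- do.call(rbind, all_events)
  if (is.null(events))
    events <- data.frame(species = character(), station_id = character(),
                         elevation_m = numeric(),
                         timestamp = as.POSIXct(character()),
                         date = as.Date(character()),
                         group_count = integer(), stringsAsFactors = FALSE)
  rownames(events) <- NULL
  # expand each event into a burst of records seconds apart
  nrec <- cfg$records_per_event
  if (nrow(events)) {
    idx <- rep(seq_len(nrow(events)), each = nrec)
    detections <- data.frame(
      station_id = events$station_id[idx],
      timestamp = events$timestamp[idx] + rep(seq_len(nrec) - 1L,
                                              nrow(events)) * 10,
      species = events$species[idx],
      group_count = events$group_count[idx],
      media_type = rep(c(rep("photo", nrec - 1L), "video"), nrow(events)),
      stringsAsFactors = FALSE)
  } else {
    detections <- data.frame(station_id = character(),
                             timestamp = as.POSIXct(character()),
                             species = character(), group_count = integer(),
                             media_type = character(),
                             stringsAsFactors = FALSE)
  }
  n_events <- vapply(names(cfg$species_rates), function(sp)
    sum(events$species == sp), integer(1))
  list(detections = detections, deployments = stations,
       truth = list(config = cfg, n_events = n_events, events = events,
                    expected_events = expected,
                    station_days = station_days, n_dropped = n_dropped))
}

#' Write a synthetic survey to CSV
#'
#' @param survey result of [generate_detection_table()].
#' @param dir output directory (created if needed).
#' @return named paths of the two files, invisibly.
#' @export
write_survey_csv <- function(survey, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  det <- survey$detections
  det$timestamp <- format(det$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  p1 <- file.path(dir, "detections.csv")
  p2 <- file.path(dir, "deployments.csv")
  write.csv(det, p1, row.names = FALSE)
  write.csv(survey$deployments, p2, row.names = FALSE)
  invisible(c(detections = p1, deployments = p2))
}

#' Generate a synthetic Gibbs landscape
#'
#' Smooth Gaussian-field environmental layers (white noise convolved with a
#' Gaussian kernel, standardized), a true Gibbs suitability surface
#' `p(cell) proportional to exp(sum lambda_j f_j)`, and presence cells
#' drawn from it.
#'
#' @param rows,cols grid dimensions, `rows * cols >= 25`.
#' @param n_layers number of environmental layers.
#' @param true_lambdas numeric vector of length `n_layers`.
#' @param n_presences presence draws from the Gibbs distribution.
#' @param seed optional integer seed.
#' @param smooth Gaussian smoothing radius in cells (default 3; 0 for
#'   white-noise layers).
#' @return list: `layers` (list of matrices), `presences` (data.frame row,
#'   col), `true_p` (cell probabilities, matrix), `true_suitability`
#'   (matrix, `p / max(p)`), `true_lambdas`.
#' @export
generate_landscape <- function(rows, cols, n_layers = 2,
                               true_lambdas = rep(1, n_layers),
                               n_presences = 100, seed = NULL, smooth = 3) {
  if (rows * cols < 25) stop("grid must have at least 25 cells")
  if (length(true_lambdas) != n_layers)
    stop("true_lambdas must have one value per layer")
  if (!is.null(seed)) set.seed(seed)
  layers <- lapply(seq_len(n_layers), function(k) {
    m <- matrix(rnorm(rows * cols), rows, cols)
    if (smooth > 0) m <- gaussian_smooth(m, smooth)
    (m - mean(m)) / sd(m)
  })
  eta <- Reduce(`+`, Map(function(lam, f) lam * f, true_lambdas, layers))
  p <- exp(eta - max(eta))
  p <- p / sum(p)
  cells <- sample.int(rows * cols, n_presences, replace = TRUE,
                      prob = as.numeric(p))
  presences <- data.frame(row = ((cells - 1L) %% rows) + 1L,
                          col = ((cells - 1L) %/% rows) + 1L)
  list(layers = layers, presences = presences, true_p = p,
       true_suitability = p / max(p), true_lambdas = true_lambdas)
}

# separable Gaussian blur with reflecting edges
gaussian_smooth <- function(m, radius) {
  half <- ceiling(3 * radius)
  k <- exp(-(seq(-half, half))^2 / (2 * radius^2))
  k <- k / sum(k)
  blur1 <- function(v) {
    n <- length(v)
    idx <- outer(seq_len(n), seq(-half, half), `+`)
    idx[idx < 1] <- 1 - idx[idx < 1] + 1
    idx[idx > n] <- 2 * n - idx[idx > n]
    drop(matrix(v[idx], n) %*% k)
  }
  m <- apply(m, 2, blur1)
  t(apply(m, 1, blur1))
}
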