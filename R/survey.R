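# Survey data model: camera deployments, detection records, independence
# filtering into events ("Ips" = independent photographs), and survey-level
# accounting.

DETECTION_COLS <- c("station_id", "timestamp", "species", "group_count",
                    "media_type")
DEPLOYMENT_COLS <- c("station_id", "survey_area", "lon", "lat", "elevation_m",
                     "start_date", "end_date", "sector_radius_km",
                     "sector_angle_rad")

#' Read camera-trap detection records
#'
#' Reads a delimited table of triggered photo/video records. Required columns:
#' `station_id`, `timestamp` (ISO 8601, minute precision or better),
#' `species`, `group_count` (positive integer), `media_type` (photo|video).
#' Rows whose timestamp cannot be parsed or whose group count is invalid are
#' dropped and reported, with line numbers, in the `problems` attribute.
#'
#' @param path path to a CSV file with a header row.
#' @param tz timezone for timestamp parsing (default UTC).
#' @return a data.frame of detection records ordered as read, with a
#'   `problems` attribute (data.frame of line, message) describing rows that
#'   failed validation.
#' @export
read_detections <- function(path, tz = "UTC") {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(DETECTION_COLS, names(raw))
  if (length(missing) > 0L)
    stop("detection table is missing required column(s): ",
         paste(missing, collapse = ", "))
  ts <- parse_timestamps(raw$timestamp, tz)
  gc_num <- suppressWarnings(as.numeric(raw$group_count))
  bad_ts <- is.na(ts)
  bad_gc <- !bad_ts & (is.na(gc_num) | gc_num < 1 | gc_num != round(gc_num))
  problems <- data.frame(
    line = c(which(bad_ts), which(bad_gc)) + 1L,  # +1 for the header line
    message = c(rep("unparseable timestamp", sum(bad_ts)),
                rep("invalid group_count", sum(bad_gc))),
    stringsAsFactors = FALSE)
  problems <- problems[order(problems$line), , drop = FALSE]
  keep <- !bad_ts & !bad_gc
  out <- data.frame(
    station_id = as.character(raw$station_id)[keep],
    timestamp = ts[keep],
    species = as.character(raw$species)[keep],
    group_count = as.integer(gc_num[keep]),
    media_type = as.character(raw$media_type)[keep],
    stringsAsFactors = FALSE)
  attr(out, "problems") <- problems
  out
}

# row-safe multi-format timestamp parsing: failures become NA, never errors
parse_timestamps <- function(x, tz = "UTC") {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = tz))
  }
  out
}

#' Read camera deployment metadata
#'
#' Columns: `station_id`, `survey_area`, `lon`, `lat`, `elevation_m`,
#' `start_date`, `end_date`, `sector_radius_km`, `sector_angle_rad`.
#' Validates the deployment invariants: end >= start, elevation in
#' \[0, 9000\] m, sector radius > 0, sector angle in (0, 2*pi\].
#'
#' @param path path to a CSV file.
#' @return data.frame of deployments with Date start/end columns.
#' @export
read_deployments <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(DEPLOYMENT_COLS, names(raw))
  if (length(missing) > 0L)
    stop("deployment table is missing required column(s): ",
         paste(missing, collapse = ", "))
  out <- data.frame(
    station_id = as.character(raw$station_id),
    survey_area = as.character(raw$survey_area),
    lon = as.numeric(raw$lon), lat = as.numeric(raw$lat),
    elevation_m = as.numeric(raw$elevation_m),
    start_date = as.Date(raw$start_date), end_date = as.Date(raw$end_date),
    sector_radius_km = as.numeric(raw$sector_radius_km),
    sector_angle_rad = as.numeric(raw$sector_angle_rad),
    stringsAsFactors = FALSE)
  validate_deployments(out)
  out
}

validate_deployments <- function(dep) {
  if (anyDuplicated(dep$station_id))
    stop("duplicated station_id in deployments")
  if (any(dep$end_date < dep$start_date))
    stop("deployment end_date precedes start_date")
  if (any(dep$elevation_m < 0 | dep$elevation_m > 9000))
    stop("elevation outside [0, 9000] m")
  if (any(dep$sector_radius_km <= 0))
    stop("sector_radius_km must be > 0")
  if (any(dep$sector_angle_rad <= 0 | dep$sector_angle_rad > 2 * pi))
    stop("sector_angle_rad must lie in (0, 2*pi]")
  invisible(dep)
}

#' Collapse detection records into independent events
#'
#' Within each station x species series, consecutive records are merged into
#' one independent event ("Ip") whenever they fall within `window_minutes`
#' of the running event. The gap is measured either from the previous event's
#' start (`rule = "event_start"`, default: order-stable, a burst plus
#' stragglers within one window is always one event) or from the last record
#' absorbed so far (`rule = "last_record"`, the chaining convention).
#'
#' @param records data.frame as returned by [read_detections()].
#' @param window_minutes independence window in minutes (> 0); default 30,
#'   the conventional camera-trap independence interval.
#' @param rule gap semantics, `"event_start"` or `"last_record"`.
#' @param deployments optional deployment table; records outside their
#'   station's deployment interval (or at unknown stations) are excluded and
#'   counted in the `n_excluded` attribute. Event elevations are joined from
#'   it when present.
#' @param day_start,day_end clock hours delimiting "daytime" for the
#'   `is_daytime` flag (half-open `[day_start, day_end)`).
#' @return data.frame of events: `station_id`, `species`, `event_start`,
#'   `n_records`, `group_count` (maximum over the event's records),
#'   `is_daytime`, and `elevation_m` when deployments are given. Attributes:
#'   `n_excluded` (records outside deployment windows), `n_input`.
#' @export
filter_independent <- function(records, window_minutes = 30,
                               rule = c("event_start", "last_record"),
                               deployments = NULL,
                               day_start = 6, day_end = 18) {
  rule <- match.arg(rule)
  if (!is.numeric(window_minutes) || window_minutes <= 0)
    stop("window_minutes must be > 0")
  for (cn in c("station_id", "timestamp", "species", "group_count"))
    if (is.null(records[[cn]]))
      stop("records are missing required column: ", cn)
  n_input <- nrow(records)
  n_excluded <- 0L
  if (!is.null(deployments)) {
    idx <- match(records$station_id, deployments$station_id)
    rec_day <- as.Date(records$timestamp)
    ok <- !is.na(idx) &
      rec_day >= deployments$start_date[idx] &
      rec_day <= deployments$end_date[idx]
    n_excluded <- sum(!ok)
    records <- records[ok, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    out <- data.frame(station_id = character(), species = character(),
                      event_start = as.POSIXct(character()),
                      n_records = integer(), group_count = integer(),
                      is_daytime = logical(), stringsAsFactors = FALSE)
    attr(out, "n_excluded") <- n_excluded
    attr(out, "n_input") <- n_input
    return(out)
  }
  ord <- order(records$station_id, records$species, records$timestamp)
  rec <- records[ord, , drop = FALSE]
  key <- paste(rec$station_id, rec$species, sep = "\r")
  w <- window_minutes * 60
  n <- nrow(rec)
  event_id <- integer(n)
  cur <- 0L
  anchor <- -Inf  # reference time of the running event, per `rule`
  for (i in seq_len(n)) {
    new_series <- i == 1L || key[i] != key[i - 1L]
    ti <- as.numeric(rec$timestamp[i])
    if (new_series || ti - anchor >= w) {
      cur <- cur + 1L
      anchor <- ti
    } else if (rule == "last_record") {
      anchor <- ti
    }
    event_id[i] <- cur
  }
  first <- !duplicated(event_id)
  out <- data.frame(
    station_id = rec$station_id[first],
    species = rec$species[first],
    event_start = rec$timestamp[first],
    n_records = as.integer(tabulate(event_id)),
    group_count = as.integer(tapply(rec$group_count, event_id, max)),
    stringsAsFactors = FALSE)
  out$is_daytime <- classify_daytime(out$event_start, day_start, day_end)
  if (!is.null(deployments)) {
    out$elevation_m <-
      deployments$elevation_m[match(out$station_id, deployments$station_id)]
  }
  attr(out, "n_excluded") <- n_excluded
  attr(out, "n_input") <- n_input
  out
}

#' Day/night classification of a timestamp
#'
#' A record is "daytime" iff its clock time falls in the half-open window
#' `[day_start, day_end)`. The survey protocol uses daytime records for
#' visual identification; the boundary hours are a configurable convention
#' (default 06:00-18:00).
#'
#' @param timestamp POSIXct vector.
#' @param day_start,day_end clock hours, `day_start < day_end`.
#' @return logical vector.
#' @export
classify_daytime <- function(timestamp, day_start = 6, day_end = 18) {
  if (day_start >= day_end) stop("day_start must be < day_end")
  lt <- as.POSIXlt(timestamp)
  hr <- lt$hour + lt$min / 60 + lt$sec / 3600
  hr >= day_start & hr < day_end
}

#' Survey-effort and detection summary
#'
#' Per-survey-area accounting in the shape of a survey-effort table: number
#' of stations, elevation range, camera-days (sum over stations of
#' end - start + 1), photographs (detection records), and independent events
#' per species; plus a totals row whose entries are exact column sums.
#'
#' @param deployments deployment table.
#' @param records detection records (counted as photographs).
#' @param events independent events from [filter_independent()].
#' @return data.frame, one row per survey area plus a `"Total"` row; species
#'   event counts appear as `ips_<species>` columns.
#' @export
summarize_survey <- function(deployments, records, events) {
  area_of <- function(st)
    deployments$survey_area[match(st, deployments$station_id)]
  areas <- sort(unique(deployments$survey_area))
  species <- sort(unique(events$species))
  dep_area <- deployments$survey_area
  cam_days <- as.numeric(deployments$end_date - deployments$start_date) + 1
  rows <- lapply(areas, function(a) {
    sel <- dep_area == a
    rec_n <- if (nrow(records)) sum(area_of(records$station_id) == a,
                                    na.rm = TRUE) else 0L
    ips <- vapply(species, function(sp) {
      if (!nrow(events)) return(0L)
      sum(events$species == sp & area_of(events$station_id) == a,
          na.rm = TRUE)
    }, integer(1))
    base <- data.frame(survey_area = a,
                       n_stations = sum(sel),
                       elev_min = min(deployments$elevation_m[sel]),
                       elev_max = max(deployments$elevation_m[sel]),
                       camera_days = sum(cam_days[sel]),
                       n_photographs = rec_n,
                       stringsAsFactors = FALSE)
    for (sp in species) base[[paste0("ips_", sp)]] <- ips[[sp]]
    base
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(survey_area = character(), n_stations = integer(),
                      elev_min = numeric(), elev_max = numeric(),
                      camera_days = numeric(), n_photographs = integer(),
                      stringsAsFactors = FALSE)
  }
  num <- setdiff(names(out), c("survey_area", "elev_min", "elev_max"))
  total <- out[1, , drop = FALSE][NA, , drop = FALSE]
  total$survey_area <- "Total"
  if (nrow(out)) {
    for (cn in num) total[[cn]] <- sum(out[[cn]])
    total$elev_min <- min(out$elev_min)
    total$elev_max <- max(out$elev_max)
  } else {
    for (cn in num) total[[cn]] <- 0
    total$elev_min <- NA_real_; total$elev_max <- NA_real_
  }
  rbind(out, total)
}

#' Percentages at report precision
#'
#' Shares of a common denominator, as percentages rounded to 2 decimal
#' places — the precision used for group-composition and day/night
#' proportions in survey reports.
#'
#' @param numerators non-negative counts, each <= `denominator`.
#' @param denominator positive total.
#' @return named numeric vector of percentages (names kept from
#'   `numerators`).
#' @export
proportion_report <- function(numerators, denominator) {
  if (length(denominator) != 1L || denominator <= 0)
    stop("denominator must be a single positive number")
  if (any(numerators < 0) || any(numerators > denominator))
    stop("numerators must lie in [0, denominator]")
  round(100 * numerators / denominator, 2)
}

#' Group composition summary
#'
#' Composition of an instantaneously scanned group (e.g. one photographed
#' family herd): counts of adult males, adult females, juveniles and
#' sub-adults with their percentage shares at 2 decimal places.
#'
#' @param adult_male,adult_female,juvenile,subadult non-negative counts.
#' @return data.frame with class, count, pct; percentages are the arithmetic
#'   `round(100 * count / total, 2)` values.
#' @export
group_composition <- function(adult_male, adult_female, juvenile, subadult) {
  counts <- c(adult_male = adult_male, adult_female = adult_female,
              juvenile = juvenile, subadult = subadult)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("empty group")
  data.frame(class = names(counts), count = as.integer(counts),
             pct = proportion_report(unname(counts), total),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag station pairs eligible for cross-camera comparison
#'
#' The survey protocol compares images from paired cameras along the same
#' travel line only when the two stations are more than `min_distance_m`
#' apart; this returns the QC flag for every station pair (it never merges
#' records — that judgment stays manual).
#'
#' @param deployments deployment table with lon/lat in decimal degrees.
#' @param min_distance_m minimum separation in metres (default 500).
#' @return data.frame station_a, station_b, distance_m, comparable.
#' @export
paired_station_flags <- function(deployments, min_distance_m = 500) {
  n <- nrow(deployments)
  if (n < 2L)
    return(data.frame(station_a = character(), station_b = character(),
                      distance_m = numeric(), comparable = logical()))
  idx <- t(utils::combn(n, 2))
  lat1 <- deployments$lat[idx[, 1]] * pi / 180
  lat2 <- deployments$lat[idx[, 2]] * pi / 180
  dlat <- lat2 - lat1
  dlon <- (deployments$lon[idx[, 2]] - deployments$lon[idx[, 1]]) * pi / 180
  a <- sin(dlat / 2)^2 + cos(lat1) * cos(lat2) * sin(dlon / 2)^2
  d <- 2 * 6371000 * asin(pmin(1, sqrt(a)))
  data.frame(station_a = deployments$station_id[idx[, 1]],
             station_b = deployments$station_id[idx[, 2]],
             distance_m = d, comparable = d > min_distance_m,
             stringsAsFactors = FALSE)
}
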