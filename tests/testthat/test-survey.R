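test_that("read_detections parses well-formed files and reports bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("station_id,timestamp,species,group_count,media_type",
               "ST001,2021-06-01T08:00:00,takin,3,photo",
               "ST001,2021-06-01T08:40:00,takin,1,video",
               "ST002,2021-06-02T17:15:00,takin,2,photo"), f)
  det <- read_detections(f)
  expect_equal(nrow(det), 3)
  expect_s3_class(det$timestamp, "POSIXct")
  expect_equal(det$group_count, c(3L, 1L, 2L))
  expect_equal(nrow(attr(det, "problems")), 0)

  writeLines(c("station_id,timestamp,species,group_count,media_type",
               "ST001,2021-06-01T08:00:00,takin,3,photo",
               "ST001,not-a-time,takin,1,photo",
               "ST002,2021-06-02T17:15:00,takin,2,photo"), f)
  det <- read_detections(f)
  expect_equal(nrow(det), 2)
  prob <- attr(det, "problems")
  expect_equal(prob$line, 3L)
  expect_match(prob$message, "timestamp")

  writeLines(c("station_id,when,species,group_count,media_type",
               "ST001,2021-06-01T08:00:00,takin,3,photo"), f)
  expect_error(read_detections(f), "timestamp")
})

test_that("synthetic survey written to CSV reads back identically", {
  sv <- generate_detection_table(survey_config(n_stations = 10, seed = 21))
  dir <- withr::local_tempdir()
  paths <- write_survey_csv(sv, dir)
  det <- read_detections(paths[["detections"]])
  expect_equal(nrow(det), nrow(sv$detections))
  expect_equal(det$timestamp, sv$detections$timestamp)
  expect_equal(det$species, sv$detections$species)
  expect_equal(det$group_count, sv$detections$group_count)
  dep <- read_deployments(paths[["deployments"]])
  expect_equal(dep$station_id, sv$deployments$station_id)
  expect_equal(dep$elevation_m, sv$deployments$elevation_m)
})

test_that("deployment invariants are enforced on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  dep <- make_deployments("ST001")
  dep$end_date <- dep$start_date - 1
  write.csv(dep, f, row.names = FALSE)
  expect_error(read_deployments(f), "end_date")
  dep <- make_deployments("ST001")
  dep$sector_angle_rad <- 7
  write.csv(dep, f, row.names = FALSE)
  expect_error(read_deployments(f), "sector_angle")
})

test_that("filter_independent merges bursts and separates stations", {
  det <- make_detections(
    c("ST001", "ST001", "ST001"),
    c("2021-06-01 08:00:00", "2021-06-01 08:00:30", "2021-06-01 08:01:00"))
  ev <- filter_independent(det, window_minutes = 30)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_records, 3L)

  det2 <- make_detections(
    c("ST001", "ST002"),
    c("2021-06-01 08:00:00", "2021-06-01 08:00:00"))
  expect_equal(nrow(filter_independent(det2, 30)), 2)
})

test_that("independence filtering matches the brute-force oracle", {
  set.seed(404)
  for (rep in 1:5) {
    det <- make_detections(
      sample(sprintf("ST%03d", 1:4), 200, replace = TRUE),
      as.POSIXct("2021-06-01", tz = "UTC") +
        runif(200, 0, 5 * 86400),
      species = sample(c("mishmi", "bhutan"), 200, replace = TRUE))
    ev <- filter_independent(det, window_minutes = 30)
    expect_equal(nrow(ev), brute_force_event_count(det, 30))
    # partition: every record lands in exactly one event
    expect_equal(sum(ev$n_records), nrow(det))
    # idempotence: filtering the event starts returns the same events
    det2 <- make_detections(ev$station_id, ev$event_start,
                            species = ev$species)
    ev2 <- filter_independent(det2, window_minutes = 30)
    expect_equal(nrow(ev2), nrow(ev))
    expect_equal(sort(as.numeric(ev2$event_start)),
                 sort(as.numeric(ev$event_start)))
  }
})

test_that("gap rules differ only in chained sequences", {
  # records at 0, 20, 40 min: event-start rule splits at 40 (>= 30 from 0);
  # last-record rule chains them into one event
  det <- make_detections(
    rep("ST001", 3),
    as.POSIXct("2021-06-01 08:00:00", tz = "UTC") + c(0, 20, 40) * 60)
  expect_equal(nrow(filter_independent(det, 30, rule = "event_start")), 2)
  expect_equal(nrow(filter_independent(det, 30, rule = "last_record")), 1)
})

test_that("records outside deployments are excluded and counted", {
  dep <- make_deployments("ST001",
                          start_date = as.Date("2021-06-01"),
                          end_date = as.Date("2021-06-30"))
  det <- make_detections(
    c("ST001", "ST001", "ST999"),
    c("2021-06-15 10:00:00", "2021-07-15 10:00:00", "2021-06-15 10:00:00"))
  ev <- filter_independent(det, 30, deployments = dep)
  expect_equal(nrow(ev), 1)
  expect_equal(attr(ev, "n_excluded"), 2L)
  expect_equal(attr(ev, "n_input"), 3L)
  expect_equal(ev$elevation_m, 2000)
})

test_that("daytime classification uses a half-open clock window", {
  ts <- as.POSIXct(c("2021-06-01 12:00:00", "2021-06-01 05:59:00",
                     "2021-06-01 06:00:00", "2021-06-01 18:00:00"),
                   tz = "UTC")
  expect_equal(classify_daytime(ts), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(classify_daytime(ts, 18, 6), "day_start")
})

test_that("summarize_survey gives exact per-area sums and totals", {
  dep <- make_deployments(sprintf("ST%03d", 1:4),
                          elevation_m = c(1000, 2000, 3000, 4000),
                          survey_area = c("A", "A", "B", "B"),
                          start_date = as.Date("2021-01-01"),
                          end_date = as.Date("2021-01-10"))
  det <- make_detections(c("ST001", "ST001", "ST003"),
                         c("2021-01-02 08:00:00", "2021-01-02 12:00:00",
                           "2021-01-03 09:00:00"))
  ev <- filter_independent(det, 30, deployments = dep)
  s <- summarize_survey(dep, det, ev)
  expect_equal(nrow(s), 3)
  tot <- s[s$survey_area == "Total", ]
  expect_equal(tot$n_stations, 4)
  expect_equal(tot$camera_days, 40)  # 4 stations x (10 - 1 + 1) days
  expect_equal(tot$n_photographs, 3)
  expect_equal(tot$ips_takin, sum(s$ips_takin[s$survey_area != "Total"]))
  expect_equal(s$camera_days[s$survey_area == "A"], 20)

  s0 <- summarize_survey(dep, det[0, ], ev[0, ])
  tot0 <- s0[s0$survey_area == "Total", ]
  expect_equal(tot0$n_photographs, 0)
})

test_that("proportions and group composition round to 2 dp", {
  expect_equal(proportion_report(540, 1210), 44.63)
  expect_equal(proportion_report(c(1123, 2242), 3365), c(33.37, 66.63))
  gc <- group_composition(adult_male = 1, adult_female = 26,
                          juvenile = 9, subadult = 11)
  expect_equal(gc$pct, c(2.13, 55.32, 19.15, 23.40))
  expect_lt(abs(sum(gc$pct) - 100), 0.05)
  expect_error(proportion_report(5, 0), "denominator")
  expect_error(proportion_report(11, 10), "numerators")
})

test_that("paired-station comparability is a distance flag, not a merge", {
  dep <- make_deployments(c("A", "B", "C"))
  dep$lon <- c(95, 95, 95.1)   # B ~ at A; C ~ 9.7 km east
  dep$lat <- c(29.5, 29.5001, 29.5)
  fl <- paired_station_flags(dep, min_distance_m = 500)
  expect_equal(nrow(fl), 3)
  expect_false(fl$comparable[fl$station_a == "A" & fl$station_b == "B"])
  expect_true(fl$comparable[fl$station_a == "A" & fl$station_b == "C"])
})
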