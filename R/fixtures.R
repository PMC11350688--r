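# Packaged fixture tables: the published survey-effort accounting (12
# survey areas, 2013-2022) and the density-estimation inputs for the two
# takin subspecies. Stored as plain CSV under extdata and loaded verbatim;
# the per-speed densities and SEs in the density table are carried as
# fixture data because they are not derivable from the printed inputs (see
# the methods vignette).

#' Packaged survey-effort and density fixture tables
#'
#' Returns the transcribed survey-effort table (per-area stations,
#' elevation range, camera-days, photographs, independent events per
#' subspecies; empty cells stored as 0) and the density table (independent
#' events, camera-days, encounter rate, per-speed densities, mean +/- SE,
#' distribution and optimal-habitat areas in km^2 for *B. taxicolor*
#' (Mishmi) and *B. whitei* (Bhutan)).
#'
#' @return list with data.frames `survey_effort` and `density`.
#' @export
fixture_tables <- function() {
  eff <- read.csv(system.file("extdata", "survey_effort_table.csv",
                              package = "budorcas"),
                  stringsAsFactors = FALSE, check.names = FALSE)
  den <- read.csv(system.file("extdata", "density_table.csv",
                              package = "budorcas"),
                  stringsAsFactors = FALSE, check.names = FALSE)
  list(survey_effort = eff, density = den)
}

#' Column totals of a survey-effort table
#'
#' Exact column sums of the additive columns, as the published totals row
#' reports them.
#'
#' @param effort survey-effort data.frame as in
#'   `fixture_tables()$survey_effort`.
#' @return one-row data.frame: n_stations, elev_min_m, elev_max_m (range,
#'   not sums), camera_days, n_photographs, and each `ips_` column.
#' @export
survey_effort_totals <- function(effort) {
  ips_cols <- grep("^ips_", names(effort), value = TRUE)
  out <- data.frame(n_stations = sum(effort$n_stations),
                    elev_min_m = min(effort$elev_min_m),
                    elev_max_m = max(effort$elev_max_m),
                    camera_days = sum(effort$camera_days),
                    n_photographs = sum(effort$n_photographs))
  for (cn in ips_cols) out[[cn]] <- sum(effort[[cn]])
  out
}
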