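# CSV readers/writers for the four field-data dialects.
# All files are UTF-8 with a header row, ISO 8601 timestamps and period
# decimals. Writers use fixed numeric formats so that write -> read ->
# write round-trips are byte-identical.

read_checked_csv <- function(path, columns) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols))
    stop_input("%s: missing column(s) %s", path,
               paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop_input("%s: no records (header only)", path)
  df[columns]
}

#' Read an observation-times CSV
#'
#' Columns `site`, `role`, `timestamp`; `role` must be one of `prey`,
#' `predator`, `potential`.
#'
#' @param path CSV path.
#' @return Data frame `site`, `role`, `timestamp`.
#' @export
read_observations <- function(path) {
  df <- read_checked_csv(path, c("site", "role", "timestamp"))
  bad <- which(!df$role %in% c("prey", "predator", "potential"))
  if (length(bad))
    stop_input("%s: invalid role '%s' at data row %d (column 'role')",
               path, df$role[bad[1]], bad[1])
  time_to_hours(df$timestamp)  # validates timestamps
  df
}

#' Read a body-temperature CSV
#'
#' Columns `individual_id`, `temp_c`, `hour`.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_tb <- function(path) {
  df <- read_checked_csv(path, c("individual_id", "temp_c", "hour"))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$temp_c))))
  if (length(bad))
    stop_input("%s: non-numeric temp_c at data row %d (column 'temp_c')",
               path, bad[1])
  df$temp_c <- as.numeric(df$temp_c)
  df
}

#' Read an operative-temperature logger CSV
#'
#' Columns `logger_id`, `microenv`, `timestamp`, `temp_c`.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_to <- function(path) {
  df <- read_checked_csv(path, c("logger_id", "microenv", "timestamp",
                                 "temp_c"))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$temp_c))))
  if (length(bad))
    stop_input("%s: non-numeric temp_c at data row %d (column 'temp_c')",
               path, bad[1])
  df$temp_c <- as.numeric(df$temp_c)
  time_to_hours(df$timestamp)
  df
}

#' Read a viper survey CSV
#'
#' Columns `population`, `sex`, `svl_mm`, `injured`.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_vipers <- function(path) {
  df <- read_checked_csv(path, c("population", "sex", "svl_mm", "injured"))
  bad <- which(!df$sex %in% c("male", "female", "unknown"))
  if (length(bad))
    stop_input("%s: invalid sex '%s' at data row %d (column 'sex')",
               path, df$sex[bad[1]], bad[1])
  svl <- suppressWarnings(as.numeric(df$svl_mm))
  bad <- which(!is.finite(svl) | svl <= 0)
  if (length(bad))
    stop_input("%s: svl_mm must be a positive number at data row %d", path,
               bad[1])
  df$svl_mm <- svl
  df$injured <- as.logical(df$injured)
  df
}

fmt_num <- function(x, fmt) ifelse(is.na(x), "NA", sprintf(fmt, x))

write_stable_csv <- function(df, path) {
  con <- file(path, open = "wb")  # binary mode: LF endings on every OS
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con, sep = "\n")
  rows <- do.call(paste, c(lapply(df, as.character), sep = ","))
  if (length(rows)) writeLines(rows, con, sep = "\n")
  invisible(path)
}

#' Write observation, body-temperature or logger tables in the standard dialects
#'
#' Fixed numeric formats (`temp_c` to 3 decimals, `hour` to 4, `svl_mm` to
#' 1) make round-trips byte-identical.
#'
#' @param df Table to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(df, path) {
  write_stable_csv(df[c("site", "role", "timestamp")], path)
}

#' @rdname write_observations
#' @export
write_tb <- function(df, path) {
  out <- data.frame(individual_id = df$individual_id,
                    temp_c = fmt_num(df$temp_c, "%.3f"),
                    hour = fmt_num(df$hour, "%.4f"))
  write_stable_csv(out, path)
}

#' @rdname write_observations
#' @export
write_to <- function(df, path) {
  out <- data.frame(logger_id = df$logger_id, microenv = df$microenv,
                    timestamp = df$timestamp,
                    temp_c = fmt_num(df$temp_c, "%.3f"))
  write_stable_csv(out, path)
}

#' @rdname write_observations
#' @export
write_vipers <- function(df, path) {
  out <- data.frame(population = df$population, sex = df$sex,
                    svl_mm = fmt_num(df$svl_mm, "%.1f"),
                    injured = as.logical(df$injured))
  write_stable_csv(out, path)
}

# Angle (radians) -> "HH:MM:SS" clock string, rounded to whole seconds.
angle_to_clock <- function(theta, date = NULL) {
  secs <- round((theta %% (2 * pi)) * 24 * 3600 / (2 * pi)) %% 86400
  hh <- secs %/% 3600
  mm <- (secs %% 3600) %/% 60
  ss <- secs %% 60
  clock <- sprintf("%02d:%02d:%02d", hh, mm, ss)
  if (is.null(date)) clock else paste0(date, "T", clock)
}

#' Write a full synthetic scenario to CSV files
#'
#' Generates per-site observation times plus pooled body-temperature and
#' operative-temperature tables, and writes `observations.csv`, `tb.csv`
#' and `to.csv` into `dir`. Site `i` uses scenario seed
#' `config$seed + 1000 * (i - 1)` so sites are independent but jointly
#' reproducible.
#'
#' @param config A [scenario_config()].
#' @param dir Output directory (created if needed).
#' @param sites Site labels (default `c("siteA", "siteB")`).
#' @param obs_date Date stamped onto observation times.
#' @return Invisible list of the three file paths.
#' @export
simulate_scenario <- function(config, dir, sites = c("siteA", "siteB"),
                              obs_date = "2017-07-20") {
  if (!inherits(config, "scenario_config"))
    stop_input("expected a scenario_config object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- do.call(rbind, lapply(seq_along(sites), function(i) {
    cfg <- config
    cfg$seed <- as.integer((config$seed + 1000 * (i - 1)) %% 2147483647)
    prey <- generate_observation_times(cfg, "prey")
    pred <- generate_observation_times(cfg, "predator")
    data.frame(
      site = sites[i],
      role = c(rep("prey", prey$n), rep("predator", pred$n)),
      timestamp = angle_to_clock(c(prey$angles, pred$angles), obs_date)
    )
  }))
  tb <- generate_tb_samples(config)
  tb_df <- data.frame(
    individual_id = sprintf("ind%03d", seq_along(tb)),
    temp_c = tb,
    hour = rep(seq(8, 17), length.out = length(tb))
  )
  to_df <- generate_to_series(config)
  paths <- list(
    observations = file.path(dir, "observations.csv"),
    tb = file.path(dir, "tb.csv"),
    to = file.path(dir, "to.csv")
  )
  write_observations(obs, paths$observations)
  write_tb(tb_df, paths$tb)
  write_to(to_df, paths$to)
  invisible(paths)
}
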