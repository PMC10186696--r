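# Thermal "potential" activity: preference density -> activity probability,
# operative temperature aggregation, and probability-weighted time resampling.

#' Activity probability from a fitted thermal preference
#'
#' Evaluates the fitted preference density on a temperature grid and rescales
#' it to peak at exactly 1: the value at temperature T is read as the
#' probability that an animal free to choose would be active at T.
#'
#' @param fit A [fit_pearson()] thermal-preference fit.
#' @param temp_grid Temperatures (degrees C) at which to evaluate;
#'   default `seq(0, 50, by = 0.1)`.
#' @return List of class `activity_prob_curve`: `temps`, `prob` (in
#'   `[0, 1]`, max exactly 1), `t_max` (temperature of the peak).
#' @export
activity_probability <- function(fit, temp_grid = seq(0, 50, by = 0.1)) {
  if (!inherits(fit, "pearson_fit")) stop_input("expected a pearson_fit object")
  if (!is.numeric(temp_grid) || length(temp_grid) < 2L ||
      any(!is.finite(temp_grid)))
    stop_input("temp_grid must be a finite numeric grid")
  d <- fit$density(temp_grid)
  mx <- max(d)
  if (mx <= 0)
    stop_estimation("fitted density is zero on the whole temperature grid; grid does not intersect the support [%.3g, %.3g]",
                    fit$support[1], fit$support[2])
  structure(
    list(temps = temp_grid, prob = d / mx, t_max = temp_grid[which.max(d)]),
    class = "activity_prob_curve"
  )
}

#' Aggregate operative-temperature logger records to 5-minute diel bins
#'
#' Pools raw logger records across loggers, days and (optionally a subset
#' of) micro-environments, and averages the temperature within each of the
#' 288 half-open 5-minute time-of-day bins.
#'
#' @param records Data frame with columns `logger_id`, `microenv`,
#'   `timestamp` (ISO 8601 or `POSIXct`), `temp_c`.
#' @param microenvs Micro-environments to include (default: all present).
#' @return Data frame of class `to_series` with 288 rows: `bin` (0-based
#'   index), `start_hour`, `mid_hour`, `mean_to` (`NA` where no records
#'   fall), `n_records`; micro-environments kept are in
#'   `attr(, "microenvs")`.
#' @export
aggregate_to <- function(records, microenvs = NULL) {
  need <- c("logger_id", "microenv", "timestamp", "temp_c")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_input("records must be a data frame with columns %s",
               paste(need, collapse = ", "))
  if (nrow(records) == 0L) stop_input("no operative-temperature records")
  if (is.null(microenvs)) microenvs <- unique(records$microenv)
  keep <- records$microenv %in% microenvs
  if (!any(keep))
    stop_input("no records left after restricting to micro-environments: %s",
               paste(microenvs, collapse = ", "))
  records <- records[keep, , drop = FALSE]
  if (!is.numeric(records$temp_c) || any(!is.finite(records$temp_c)))
    stop_input("temp_c must be finite numeric")
  hours <- time_to_hours(records$timestamp)
  bin <- pmin(287L, as.integer(floor(hours * 12)))  # 5-min bins, half-open
  mean_to <- rep(NA_real_, 288L)
  n_rec <- integer(288L)
  sums <- tapply(records$temp_c, bin, sum)
  cnts <- tapply(records$temp_c, bin, length)
  idx <- as.integer(names(sums)) + 1L
  mean_to[idx] <- as.numeric(sums) / as.numeric(cnts)
  n_rec[idx] <- as.integer(cnts)
  out <- data.frame(
    bin = 0:287,
    start_hour = (0:287) / 12,
    mid_hour = (0:287) / 12 + 1 / 24,
    mean_to = mean_to,
    n_records = n_rec
  )
  attr(out, "microenvs") <- microenvs
  class(out) <- c("to_series", "data.frame")
  out
}

#' Thermally potential activity times
#'
#' Resamples times of day with replacement, weighting each 5-minute bin by
#' the activity probability at the bin's mean operative temperature: the
#' resulting circular sample represents when the animal *could* be active
#' based on thermal suitability alone.
#'
#' @param series A [aggregate_to()] result (288 diel bins).
#' @param curve An [activity_probability()] curve.
#' @param n_out Number of times to draw.
#' @param seed Optional integer seed.
#' @param jitter If `TRUE`, add a uniform within-bin offset instead of
#'   returning exact bin midpoints (default `FALSE`).
#' @return A [circular_sample()] with role `"potential"`. Bins with no
#'   records, or whose mean temperature falls outside the probability
#'   curve's grid, get weight zero.
#' @export
potential_activity <- function(series, curve, n_out, seed = NULL,
                               jitter = FALSE) {
  if (!inherits(series, "to_series")) stop_input("expected a to_series object")
  if (!inherits(curve, "activity_prob_curve"))
    stop_input("expected an activity_prob_curve object")
  if (!is.numeric(n_out) || length(n_out) != 1L || n_out < 1)
    stop_input("n_out must be a positive count")
  w <- rep(0, nrow(series))
  ok <- !is.na(series$mean_to)
  w[ok] <- stats::approx(curve$temps, curve$prob, xout = series$mean_to[ok],
                         rule = 1)$y
  w[is.na(w)] <- 0  # mean T_o outside the curve's temperature grid
  if (sum(w) <= 0)
    stop_estimation("all activity-probability weights are zero: operative temperatures never intersect the thermal preference")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(series), size = n_out, replace = TRUE, prob = w)
  hours <- series$mid_hour[idx]
  if (jitter) hours <- series$start_hour[idx] + stats::runif(n_out, 0, 1 / 12)
  circular_sample(time_to_angle(hours %% 24), role = "potential",
                  site = "potential")
}
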