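# Seeded synthetic field data with the statistical structure the analysis
# assumes: bimodal prey activity (early-morning and late-afternoon basking
# peaks), unimodal midday predator activity, a right-skewed body-temperature
# preference on the 20-40 degree gradient, and smooth sinusoid-plus-noise
# diel operative-temperature curves whose amplitude orders as
# exposed soil > shade > rock > burrow.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults emulate the field study conditions: 19 prey and 49 predator
#' observation times per site (half of the 38 snake and 98 raptor
#' observations split over two sites), prey activity peaks at 07:00 and
#' 18:30 with the morning peak carrying more weight, a broad predator peak
#' at 13:00, a gamma-shaped thermal preference with mode 28 degrees C
#' clamped to the 20-40 degree gradient, and one logger in each of four
#' micro-environments recording a sinusoidal thermal day (peak 14:00) at
#' 5-minute cadence.
#'
#' @param seed Integer scenario seed; every generated output is a
#'   deterministic function of it. Sub-streams are split per output, so
#'   e.g. adding loggers does not perturb observation times.
#' @param n_prey_obs,n_predator_obs Observation counts (per site).
#' @param prey_peaks Data frame `mean_hour`, `kappa`, `weight` (weights sum
#'   to 1) for the prey von Mises mixture.
#' @param predator_peak List `mean_hour`, `kappa` for the predator peak.
#' @param tb_params List `shape`, `scale`, `shift`, `support` for the
#'   gamma-shaped body-temperature preference, plus `n` draws.
#' @param to_curves Data frame `microenv`, `t_min`, `t_max`, `peak_hour`,
#'   `noise_sd` per micro-environment.
#' @param n_loggers_per_microenv Loggers per micro-environment.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_prey_obs = 19L,
                            n_predator_obs = 49L,
                            prey_peaks = data.frame(
                              mean_hour = c(7, 18.5),
                              kappa = c(8, 6),
                              weight = c(0.6, 0.4)),
                            predator_peak = list(mean_hour = 13, kappa = 3),
                            tb_params = list(shape = 9, scale = 1, shift = 20,
                                             support = c(20, 40), n = 100L),
                            to_curves = data.frame(
                              microenv = c("soil_exposed", "shade", "rock",
                                           "burrow"),
                              t_min = c(12, 13, 14, 16),
                              t_max = c(45, 32, 28, 24),
                              peak_hour = c(14, 14, 14, 14),
                              noise_sd = c(0.5, 0.5, 0.5, 0.5)),
                            n_loggers_per_microenv = 1L) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_input("seed must be a single integer")
  if (n_prey_obs < 1 || n_predator_obs < 1 || n_loggers_per_microenv < 1 ||
      tb_params$n < 1)
    stop_input("all counts must be >= 1")
  if (abs(sum(prey_peaks$weight) - 1) > 1e-8)
    stop_input("prey mixture weights must sum to 1")
  if (any(prey_peaks$kappa <= 0) || predator_peak$kappa <= 0)
    stop_input("concentrations must be > 0")
  if (any(prey_peaks$mean_hour < 0 | prey_peaks$mean_hour >= 24) ||
      predator_peak$mean_hour < 0 || predator_peak$mean_hour >= 24)
    stop_input("mean hours must lie in [0, 24)")
  if (any(to_curves$t_min >= to_curves$t_max))
    stop_input("each micro-environment needs daily min < max temperature")
  if (!all(is.finite(unlist(tb_params[c("shape", "scale", "shift")]))))
    stop_input("tb_params must be finite")
  if (tb_params$support[1] < 0 || tb_params$support[2] > 50)
    stop_input("tb support must lie within the plausible 0-50 degree range")
  structure(
    list(seed = as.integer(seed), n_prey_obs = as.integer(n_prey_obs),
         n_predator_obs = as.integer(n_predator_obs),
         prey_peaks = prey_peaks, predator_peak = predator_peak,
         tb_params = tb_params, to_curves = to_curves,
         n_loggers_per_microenv = as.integer(n_loggers_per_microenv)),
    class = "scenario_config"
  )
}

# Deterministic per-output sub-seed, kept below 2^31.
substream_seed <- function(seed, stream) {
  offs <- c(prey = 101L, predator = 211L, tb = 307L, to = 401L,
            vipers = 503L)
  if (!stream %in% names(offs)) stop_input("unknown RNG stream '%s'", stream)
  (abs(as.double(seed)) * 1009 + offs[[stream]]) %% 2147483647
}

#' Generate observation times for one role
#'
#' Prey times come from the configured von Mises mixture (bimodal activity);
#' predator times from a single von Mises peak at midday.
#'
#' @param config A [scenario_config()].
#' @param role `"prey"` or `"predator"`.
#' @return A [circular_sample()].
#' @export
generate_observation_times <- function(config, role = c("prey", "predator")) {
  if (!inherits(config, "scenario_config"))
    stop_input("expected a scenario_config object")
  if (!is.character(role) || !role[1] %in% c("prey", "predator"))
    stop_input("role must be 'prey' or 'predator' (got '%s')",
               as.character(role)[1])
  role <- role[1]
  set.seed(substream_seed(config$seed, role))
  if (role == "prey") {
    n <- config$n_prey_obs
    pk <- config$prey_peaks
    comp <- sample.int(nrow(pk), n, replace = TRUE, prob = pk$weight)
    ang <- numeric(n)
    for (j in seq_len(nrow(pk))) {
      sel <- comp == j
      if (any(sel))
        ang[sel] <- rvonmises(sum(sel), time_to_angle(pk$mean_hour[j]),
                              pk$kappa[j])
    }
  } else {
    n <- config$n_predator_obs
    ang <- rvonmises(n, time_to_angle(config$predator_peak$mean_hour),
                     config$predator_peak$kappa)
  }
  circular_sample(ang, role = role, site = "synthetic")
}

#' Generate gradient-selected body temperatures
#'
#' Draws from the configured shifted-gamma preference distribution;
#' draws falling outside the gradient support are redrawn (rejection), so
#' the sample stays smooth with no boundary atoms. A zero-variance
#' configuration (`scale = 0`) returns the mode for every draw.
#'
#' @param config A [scenario_config()].
#' @param n Number of draws (default `config$tb_params$n`).
#' @return Numeric vector of body temperatures (degrees C).
#' @export
generate_tb_samples <- function(config, n = NULL) {
  if (!inherits(config, "scenario_config"))
    stop_input("expected a scenario_config object")
  p <- config$tb_params
  if (is.null(n)) n <- p$n
  set.seed(substream_seed(config$seed, "tb"))
  if (p$scale == 0)  # degenerate: all mass at the mode
    return(rep(p$shift + (p$shape - 1) * p$scale, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- p$shift + stats::rgamma(n, shape = p$shape, scale = p$scale)
    draw <- draw[draw >= p$support[1] & draw <= p$support[2]]
    out <- c(out, draw)
  }
  out[seq_len(n)]
}

#' Generate operative-temperature logger records
#'
#' One record per logger per 5-minute interval over `n_days` days: a
#' sinusoidal diel curve (minimum 12 h before the peak hour) specific to
#' each micro-environment, plus Gaussian noise.
#'
#' @param config A [scenario_config()].
#' @param n_days Number of full days (default 1).
#' @param start_date Date of the first record (ISO string).
#' @return Data frame `logger_id`, `microenv`, `timestamp` (ISO 8601),
#'   `temp_c`.
#' @export
generate_to_series <- function(config, n_days = 1L,
                               start_date = "2017-07-15") {
  if (!inherits(config, "scenario_config"))
    stop_input("expected a scenario_config object")
  if (n_days < 1) stop_input("n_days must be >= 1")
  set.seed(substream_seed(config$seed, "to"))
  tc <- config$to_curves
  per_day <- 288L
  hours <- rep(seq(0, 24 - 1 / 12, by = 1 / 12), n_days)
  day <- rep(seq_len(n_days) - 1L, each = per_day)
  base <- as.POSIXct(paste0(start_date, " 00:00:00"), tz = "UTC")
  stamp <- format(base + (day * 24 + hours) * 3600, "%Y-%m-%dT%H:%M:%S")
  out <- vector("list", nrow(tc) * config$n_loggers_per_microenv)
  k <- 0L
  for (i in seq_len(nrow(tc))) {
    mid <- (tc$t_min[i] + tc$t_max[i]) / 2
    amp <- (tc$t_max[i] - tc$t_min[i]) / 2
    mu <- mid + amp * cos(2 * pi * (hours - tc$peak_hour[i]) / 24)
    for (l in seq_len(config$n_loggers_per_microenv)) {
      k <- k + 1L
      noise <- if (tc$noise_sd[i] > 0)
        stats::rnorm(length(mu), 0, tc$noise_sd[i]) else 0
      out[[k]] <- data.frame(
        logger_id = sprintf("%s_%02d", tc$microenv[i], l),
        microenv = tc$microenv[i],
        timestamp = stamp,
        temp_c = mu + noise
      )
    }
  }
  do.call(rbind, out)
}

#' Generate a synthetic injury-survey table
#'
#' Viper records with the qualitative structure of the field survey: females
#' larger than males, and injury probability increasing with body length and
#' higher in females. Intended for documentation examples and descriptive
#' summaries, not for model-based inference.
#'
#' @param config A [scenario_config()].
#' @param n Number of individuals (default 319).
#' @param n_populations Number of populations the records spread over
#'   (default 14).
#' @return Data frame `population`, `sex`, `svl_mm`, `injured`.
#' @export
generate_viper_records <- function(config, n = 319L, n_populations = 14L) {
  if (!inherits(config, "scenario_config"))
    stop_input("expected a scenario_config object")
  set.seed(substream_seed(config$seed, "vipers"))
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.39, 0.61))
  svl <- ifelse(sex == "male", stats::rnorm(n, 244, 42), stats::rnorm(n, 301, 44))
  svl <- pmax(svl, 120)
  lin <- -6 + 0.015 * svl + 0.6 * (sex == "female")
  injured <- stats::runif(n) < stats::plogis(lin)
  data.frame(
    population = sprintf("pop%02d", sample.int(n_populations, n, replace = TRUE)),
    sex = sex,
    svl_mm = round(svl, 1),
    injured = injured
  )
}
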