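# Shared fixtures: seeded von Mises samples and a high-resolution quadrature
# oracle for the overlap of two closed-form von Mises densities.

vm_sample <- function(n, mu, kappa, seed, role = "prey", site = "site") {
  set.seed(seed)
  circular_sample(rvonmises(n, mu, kappa), role = role, site = site)
}

# Independent oracle: overlap of two analytic von Mises densities by
# trapezoidal quadrature at `npts` points (1e5 by default).
oracle_delta_vm <- function(mu1, k1, mu2, k2, npts = 1e5) {
  g <- 2 * pi * (0:(npts - 1)) / npts
  (2 * pi / npts) * sum(pmin(dvonmises(g, mu1, k1), dvonmises(g, mu2, k2)))
}

# Closed-form von Mises curve on the package's standard grid.
vm_curve <- function(mu, kappa, m = 512) {
  g <- 2 * pi * (0:(m - 1)) / m
  density_curve(dvonmises(g, mu, kappa))
}

# Small noise-free operative-temperature table: one logger, sinusoidal day.
sinusoid_to_records <- function(t_min = 14, t_max = 34, peak_hour = 14,
                                date = "2017-07-15") {
  hours <- seq(0, 24 - 1 / 12, by = 1 / 12)
  mid <- (t_min + t_max) / 2
  amp <- (t_max - t_min) / 2
  base <- as.POSIXct(paste0(date, " 00:00:00"), tz = "UTC")
  data.frame(
    logger_id = "lg1", microenv = "soil_exposed",
    timestamp = format(base + hours * 3600, "%Y-%m-%dT%H:%M:%S"),
    temp_c = mid + amp * cos(2 * pi * (hours - peak_hour) / 24)
  )
}

# A to_series with a prescribed mean temperature in every 5-min bin.
flat_to_series <- function(temps) {
  stopifnot(length(temps) %in% c(1L, 288L))
  out <- data.frame(bin = 0:287, start_hour = (0:287) / 12,
                    mid_hour = (0:287) / 12 + 1 / 24,
                    mean_to = rep(temps, length.out = 288L),
                    n_records = 1L)
  class(out) <- c("to_series", "data.frame")
  out
}
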