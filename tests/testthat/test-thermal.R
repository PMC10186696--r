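test_that("noise-free logger records are recovered exactly per 5-min bin", {
  recs <- sinusoid_to_records(t_min = 14, t_max = 34, peak_hour = 14)
  series <- aggregate_to(recs)
  expect_identical(nrow(series), 288L)
  expect_true(all(series$n_records == 1L))
  expect_equal(series$mean_to, recs$temp_c, tolerance = 1e-9)
})

test_that("bin means pool loggers and days arithmetically", {
  recs <- rbind(sinusoid_to_records(), sinusoid_to_records())
  recs$temp_c <- rep(c(20, 30), each = 288)
  recs$logger_id <- rep(c("a", "b"), each = 288)
  series <- aggregate_to(recs)
  expect_true(all(series$mean_to == 25))
  expect_true(all(series$n_records == 2L))

  # two days, hand-computed toy: bin 0 sees 10 and 20, bin 1 sees 12 and 26
  toy <- data.frame(
    logger_id = "lg", microenv = "shade",
    timestamp = c("2017-07-01T00:01:00", "2017-07-02T00:03:00",
                  "2017-07-01T00:06:00", "2017-07-02T00:08:00"),
    temp_c = c(10, 20, 12, 26))
  s2 <- aggregate_to(toy)
  expect_identical(s2$mean_to[1], 15)
  expect_identical(s2$mean_to[2], 19)
  expect_identical(s2$n_records[1:2], c(2L, 2L))
  expect_true(all(is.na(s2$mean_to[3:288])))
  expect_true(all(s2$n_records[3:288] == 0L))
})

test_that("micro-environment subsetting and empty input are validated", {
  recs <- sinusoid_to_records()
  expect_error(aggregate_to(recs[0, ]), class = "dielshift_input_error")
  expect_error(aggregate_to(recs, microenvs = "burrow"),
               class = "dielshift_input_error")
  sub <- aggregate_to(recs, microenvs = "soil_exposed")
  expect_identical(attr(sub, "microenvs"), "soil_exposed")
})

test_that("potential activity respects the thermal window's support", {
  set.seed(81)
  fit <- fit_pearson(20 + rgamma(5000, shape = 9))
  curve <- activity_probability(fit, seq(0, 50, by = 0.1))
  # thermally suitable only 06:00-08:00 (bins 72..96): mode temperature
  # there, far-off-support temperature elsewhere
  temps <- rep(5, 288)
  temps[73:96] <- curve$t_max
  series <- flat_to_series(temps)
  pot <- potential_activity(series, curve, n_out = 400, seed = 3)
  hours <- pot$angles * 24 / (2 * pi)
  expect_identical(pot$role, "potential")
  expect_true(all(hours >= 6 & hours < 8 + 5 / 60))
})

test_that("potential activity is deterministic per seed and errors with no weight", {
  set.seed(82)
  fit <- fit_pearson(20 + rgamma(5000, shape = 9))
  curve <- activity_probability(fit, seq(20, 40, by = 0.1))
  series <- flat_to_series(28)
  p1 <- potential_activity(series, curve, 100, seed = 11)
  p2 <- potential_activity(series, curve, 100, seed = 11)
  expect_identical(p1, p2)
  cold <- flat_to_series(5)  # outside the curve's temperature grid
  expect_error(potential_activity(cold, curve, 100, seed = 1),
               class = "dielshift_estimation_error")
})

test_that("empirical bin frequencies converge to the normalized weights", {
  set.seed(83)
  fit <- fit_pearson(20 + rgamma(5000, shape = 9))
  curve <- activity_probability(fit, seq(0, 50, by = 0.1))
  # a realistic thermal day: suitability peaks morning and evening, so the
  # weight mass concentrates on a subset of bins
  hours <- (0:287) / 12 + 1 / 24
  temps <- 31 + 14 * cos(2 * pi * (hours - 14) / 24)
  series <- flat_to_series(temps)
  w <- approx(curve$temps, curve$prob, xout = temps, rule = 1)$y
  w[is.na(w)] <- 0
  w <- w / sum(w)
  pot <- potential_activity(series, curve, n_out = 1e5, seed = 12)
  freq <- tabulate(round(pot$angles * 288 / (2 * pi) + 0.5), nbins = 288)
  tv <- 0.5 * sum(abs(freq / 1e5 - w))
  expect_lt(tv, 0.02)
})

test_that("a hot midday carves the potential activity into two peaks", {
  set.seed(84)
  fit <- fit_pearson(20 + rgamma(5000, shape = 9))
  curve <- activity_probability(fit, seq(0, 50, by = 0.1))
  hours <- (0:287) / 12 + 1 / 24
  midday_hot <- 31 + 14 * cos(2 * pi * (hours - 14) / 24)  # 17 C at night, 45 C peak
  series <- flat_to_series(midday_hot)
  pot <- potential_activity(series, curve, n_out = 3000, seed = 5)
  d <- kde_circular(pot)
  expect_identical(dielshift:::count_modes(d), 2L)

  # an activity generator shifted 1 h away from the thermal optimum overlaps
  # the potential distribution less than one centred on it
  dens_pot <- d
  peak_hours <- sort((d$grid[order(d$values, decreasing = TRUE)][1:40] *
                        24 / (2 * pi)))
  morning <- peak_hours[peak_hours < 12][1]
  evening <- rev(peak_hours[peak_hours > 12])[1]
  mk_obs <- function(shift_morning, shift_evening, seed) {
    set.seed(seed)
    circular_sample(c(
      rvonmises(600, time_to_angle((morning + shift_morning) %% 24), 8),
      rvonmises(400, time_to_angle((evening + shift_evening) %% 24), 8)))
  }
  unshifted <- overlap_from_samples(pot, mk_obs(0, 0, 101))
  shifted <- overlap_from_samples(pot, mk_obs(-1, 1, 101))
  expect_lt(shifted, unshifted)
})
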