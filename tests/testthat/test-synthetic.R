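test_that("scenario configs validate their invariants", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(n_prey_obs = 0), class = "dielshift_input_error")
  bad_w <- data.frame(mean_hour = c(7, 19), kappa = c(8, 6),
                      weight = c(0.7, 0.4))
  expect_error(scenario_config(prey_peaks = bad_w),
               class = "dielshift_input_error")
  bad_k <- data.frame(mean_hour = c(7, 19), kappa = c(-1, 6),
                      weight = c(0.6, 0.4))
  expect_error(scenario_config(prey_peaks = bad_k),
               class = "dielshift_input_error")
  expect_error(scenario_config(predator_peak = list(mean_hour = 25, kappa = 3)),
               class = "dielshift_input_error")
  bad_to <- data.frame(microenv = "burrow", t_min = 20, t_max = 18,
                       peak_hour = 14, noise_sd = 0.5)
  expect_error(scenario_config(to_curves = bad_to),
               class = "dielshift_input_error")
})

test_that("all generator outputs are bit-identical for a fixed config", {
  cfg <- scenario_config(seed = 99)
  expect_identical(generate_observation_times(cfg, "prey"),
                   generate_observation_times(cfg, "prey"))
  expect_identical(generate_observation_times(cfg, "predator"),
                   generate_observation_times(cfg, "predator"))
  expect_identical(generate_tb_samples(cfg), generate_tb_samples(cfg))
  expect_identical(generate_to_series(cfg), generate_to_series(cfg))
  expect_error(generate_observation_times(cfg, "raptor"),
               class = "dielshift_input_error")
})

test_that("observation-time streams are split: loggers do not perturb times", {
  cfg1 <- scenario_config(seed = 5, n_loggers_per_microenv = 1)
  cfg2 <- scenario_config(seed = 5, n_loggers_per_microenv = 3)
  t1 <- generate_observation_times(cfg1, "prey")
  generate_to_series(cfg2)  # interleave logger generation
  t2 <- generate_observation_times(cfg2, "prey")
  expect_identical(t1$angles, t2$angles)
})

test_that("prey times show the configured bimodal structure at large n", {
  cfg <- scenario_config(
    seed = 1, n_prey_obs = 1e5,
    prey_peaks = data.frame(mean_hour = c(7, 19), kappa = c(8, 6),
                            weight = c(0.6, 0.4)))
  s <- generate_observation_times(cfg, "prey")
  d <- kde_circular(s)
  expect_identical(dielshift:::count_modes(d), 2L)
  grid_hours <- d$grid * 24 / (2 * pi)
  morning <- grid_hours[which.max(d$values)]
  eve_idx <- which(grid_hours > 12)
  evening <- grid_hours[eve_idx][which.max(d$values[eve_idx])]
  expect_lt(abs(morning - 7), 1)
  expect_lt(abs(evening - 19), 1)
})

test_that("a near-degenerate single peak pins all times to its mean hour", {
  cfg <- scenario_config(
    seed = 2, n_prey_obs = 100,
    prey_peaks = data.frame(mean_hour = 12, kappa = 1e6, weight = 1))
  s <- generate_observation_times(cfg, "prey")
  hrs <- s$angles * 24 / (2 * pi)
  expect_true(all(abs(hrs - 12) < 10 / 60))
})

test_that("body temperatures hit the analytic mean and respect the gradient", {
  cfg <- scenario_config(seed = 3)
  x <- generate_tb_samples(cfg, n = 10000)
  expect_lt(abs(mean(x) - 29), 0.2)  # shifted gamma(9, 1): mean 20 + 9
  expect_true(all(x >= 20 & x <= 40))
  cfg0 <- scenario_config(seed = 3,
                          tb_params = list(shape = 9, scale = 0, shift = 20,
                                           support = c(20, 40), n = 10))
  expect_true(all(generate_tb_samples(cfg0) == 20))
})

test_that("logger series have 288 records per logger-day and exact noise-free curves", {
  cfg <- scenario_config(
    seed = 4,
    to_curves = data.frame(microenv = "shade", t_min = 13, t_max = 32,
                           peak_hour = 14, noise_sd = 0))
  recs <- generate_to_series(cfg, n_days = 1)
  expect_identical(nrow(recs), 288L)
  hours <- seq(0, 24 - 1 / 12, by = 1 / 12)
  expect_equal(recs$temp_c,
               22.5 + 9.5 * cos(2 * pi * (hours - 14) / 24), tolerance = 1e-12)
  recs2 <- generate_to_series(cfg, n_days = 3)
  expect_identical(nrow(recs2), 3L * 288L)
})

test_that("burrows always damp the thermal day relative to exposed soil", {
  for (seed in 1:20) {
    recs <- generate_to_series(scenario_config(seed = seed))
    amp_burrow <- diff(range(aggregate_to(recs, "burrow")$mean_to))
    amp_sun <- diff(range(aggregate_to(recs, "soil_exposed")$mean_to))
    expect_lt(amp_burrow, amp_sun)
  }
})

test_that("synthetic viper surveys show larger females and length-linked injuries", {
  cfg <- scenario_config(seed = 6)
  recs <- generate_viper_records(cfg)
  expect_identical(nrow(recs), 319L)
  expect_lte(length(unique(recs$population)), 14L)
  expect_gt(median(recs$svl_mm[recs$sex == "female"]),
            median(recs$svl_mm[recs$sex == "male"]))
  expect_gt(mean(recs$svl_mm[recs$injured]), mean(recs$svl_mm[!recs$injured]))
})
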