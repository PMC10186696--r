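# End-to-end analysis: activity densities -> potential activity ->
# pairwise overlaps per site -> comparison test.

#' Analysis configuration
#'
#' @param seed Master seed; all bootstrap and resampling randomness derives
#'   from it.
#' @param sites Sites to analyse (default: all sites present in the data).
#' @param estimator Overlap estimator variant (see [overlap_from_samples()]).
#' @param grid_size Angular grid size (`>= 64`).
#' @param bandwidth_adjust Kernel bandwidth multiplier.
#' @param switch_threshold `"auto"` estimator switch point.
#' @param n_boot Bootstrap replicates per overlap (`>= 1`).
#' @param microenvs Micro-environment subset for operative temperatures
#'   (default: all).
#' @param n_out Potential-activity sample size; `NULL` (default) uses the
#'   number of observed prey records at the same site.
#' @param temp_grid Temperature grid for the activity-probability curve.
#' @param out_dir If non-`NULL`, results are written there
#'   (`results.json`, `densities.csv`, `replicates.csv`).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1L, sites = NULL,
                            estimator = c("auto", "grid", "at_points"),
                            grid_size = 512L, bandwidth_adjust = 1,
                            switch_threshold = 75L, n_boot = 1000L,
                            microenvs = NULL, n_out = NULL,
                            temp_grid = seq(0, 50, by = 0.1),
                            out_dir = NULL) {
  estimator <- match.arg(estimator)
  if (!is.numeric(n_boot) || n_boot < 1) stop_input("n_boot must be >= 1")
  if (!is.numeric(grid_size) || grid_size < 64)
    stop_input("grid_size must be >= 64")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_input("seed must be a single integer")
  structure(
    list(seed = as.integer(seed), sites = sites, estimator = estimator,
         grid_size = as.integer(grid_size),
         bandwidth_adjust = bandwidth_adjust,
         switch_threshold = as.integer(switch_threshold),
         n_boot = as.integer(n_boot), microenvs = microenvs, n_out = n_out,
         temp_grid = temp_grid, out_dir = out_dir),
    class = "analysis_config"
  )
}

pair_seed <- function(seed, site_idx, pair_idx) {
  (abs(as.double(seed)) * 2003 + 97 * site_idx + pair_idx) %% 2147483647
}

#' Run the full activity-shift analysis
#'
#' For every site: estimates the predator and observed-prey activity
#' densities, builds the thermally potential prey activity (thermal
#' preference fit, operative-temperature aggregation, weighted resampling),
#' computes \eqn{\Delta} with bootstrap confidence intervals for the three
#' pairs (observed vs potential prey, predator vs observed prey, predator
#' vs potential prey), and compares the predator-observed against the
#' predator-potential overlap with a rank-sum test on bootstrap replicates.
#'
#' @param config An [analysis_config()].
#' @param obs Observations: path to CSV or data frame
#'   (`site`, `role`, `timestamp`).
#' @param tb Body temperatures: path or data frame
#'   (`individual_id`, `temp_c`, `hour`).
#' @param to Operative temperatures: path or data frame
#'   (`logger_id`, `microenv`, `timestamp`, `temp_c`).
#' @return List of class `dielshift_results`: `config`, `tb_fit` summary,
#'   and per-site entries with density curves, the potential sample, the
#'   three `overlap_result`s and the comparison test.
#' @export
run_pipeline <- function(config, obs, tb, to) {
  if (!inherits(config, "analysis_config"))
    stop_input("expected an analysis_config object")
  obs <- if (is.character(obs)) read_observations(obs) else obs
  tb <- if (is.character(tb)) read_tb(tb) else tb
  to <- if (is.character(to)) read_to(to) else to

  sites <- config$sites
  if (is.null(sites)) sites <- sort(unique(obs$site))
  if (length(sites) == 0L) stop_input("no sites found in the observations")

  tb_fit <- fit_pearson(tb$temp_c)
  prob_curve <- activity_probability(tb_fit, config$temp_grid)
  series <- aggregate_to(to, config$microenvs)

  site_results <- lapply(seq_along(sites), function(i) {
    s <- sites[i]
    rows <- obs[obs$site == s, , drop = FALSE]
    for (need_role in c("prey", "predator"))
      if (!any(rows$role == need_role))
        stop_input("site '%s' has no %s observations", s, need_role)
    prey <- circular_sample(time_to_angle(rows$timestamp[rows$role == "prey"]),
                            "prey", s)
    pred <- circular_sample(
      time_to_angle(rows$timestamp[rows$role == "predator"]), "predator", s)
    n_out <- if (is.null(config$n_out)) prey$n else config$n_out
    pot <- potential_activity(series, prob_curve, n_out,
                              seed = pair_seed(config$seed, i, 0))
    pot$site <- s

    boot_pair <- function(a, b, k)
      bootstrap_delta(a, b, n_boot = config$n_boot,
                      seed = pair_seed(config$seed, i, k),
                      estimator = config$estimator,
                      bandwidth_adjust = config$bandwidth_adjust,
                      grid_size = config$grid_size,
                      switch_threshold = config$switch_threshold)
    obs_pot <- boot_pair(prey, pot, 1)
    pred_obs <- boot_pair(pred, prey, 2)
    pred_pot <- boot_pair(pred, pot, 3)
    comp <- compare_overlaps(pred_obs, pred_pot)

    list(site = s,
         n_prey = prey$n, n_predator = pred$n, n_potential = pot$n,
         densities = list(
           predator = kde_circular(pred, config$bandwidth_adjust,
                                   config$grid_size),
           observed = kde_circular(prey, config$bandwidth_adjust,
                                   config$grid_size),
           potential = kde_circular(pot, config$bandwidth_adjust,
                                    config$grid_size)),
         potential_sample = pot,
         overlaps = list(observed_vs_potential = obs_pot,
                         predator_vs_observed = pred_obs,
                         predator_vs_potential = pred_pot),
         comparison = comp)
  })
  names(site_results) <- sites

  res <- structure(
    list(config = config,
         tb_fit = list(family = tb_fit$family,
                       moments = as.list(tb_fit$fitted_moments),
                       t_max = prob_curve$t_max),
         sites = site_results),
    class = "dielshift_results"
  )
  if (!is.null(config$out_dir)) write_results(res, config$out_dir)
  res
}

#' @export
print.dielshift_results <- function(x, ...) {
  cat(sprintf("<dielshift_results> %d site(s); thermal preference type %s (peak %.1f C)\n",
              length(x$sites), x$tb_fit$family, x$tb_fit$t_max))
  for (s in x$sites) {
    cat(sprintf("  %s (prey n=%d, predator n=%d):\n", s$site, s$n_prey,
                s$n_predator))
    for (nm in names(s$overlaps)) {
      o <- s$overlaps[[nm]]
      cat(sprintf("    %-22s Delta = %.3f [%.3f, %.3f]\n", nm, o$delta,
                  o$ci_low, o$ci_high))
    }
    cat(sprintf("    rank-sum W = %.0f, p = %.3g\n", s$comparison$statistic,
                s$comparison$p_value))
  }
  invisible(x)
}

#' Write a results bundle to disk
#'
#' Emits `results.json` (config, seed, per-site overlap estimates, CIs and
#' comparison tests), `densities.csv` (site, series, angle, density) and
#' `replicates.csv` (site, pair, replicate, delta). Outputs are a pure
#' function of config + seed, so reruns are byte-identical.
#'
#' @param res A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisible vector of file paths.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$config
  json <- list(
    config = list(seed = cfg$seed, estimator = cfg$estimator,
                  grid_size = cfg$grid_size,
                  bandwidth_adjust = cfg$bandwidth_adjust,
                  switch_threshold = cfg$switch_threshold,
                  n_boot = cfg$n_boot,
                  microenvs = if (is.null(cfg$microenvs)) "all"
                              else cfg$microenvs,
                  n_out = if (is.null(cfg$n_out)) "n_prey" else cfg$n_out),
    thermal_preference = res$tb_fit,
    sites = lapply(res$sites, function(s) {
      list(n_prey = s$n_prey, n_predator = s$n_predator,
           overlaps = lapply(s$overlaps, function(o)
             list(delta = o$delta, ci_low = o$ci_low, ci_high = o$ci_high,
                  n_boot = o$n_boot, estimator = o$estimator)),
           comparison = s$comparison)
    })
  )
  f_json <- file.path(dir, "results.json")
  jsonlite::write_json(json, f_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  dens <- do.call(rbind, lapply(res$sites, function(s)
    do.call(rbind, lapply(names(s$densities), function(nm)
      data.frame(site = s$site, series = nm,
                 angle = fmt_num(s$densities[[nm]]$grid, "%.8f"),
                 density = fmt_num(s$densities[[nm]]$values, "%.8f"))))))
  f_dens <- file.path(dir, "densities.csv")
  write_stable_csv(dens, f_dens)

  reps <- do.call(rbind, lapply(res$sites, function(s)
    do.call(rbind, lapply(names(s$overlaps), function(nm)
      data.frame(site = s$site, pair = nm,
                 replicate = seq_len(s$overlaps[[nm]]$n_boot),
                 delta = fmt_num(s$overlaps[[nm]]$replicates, "%.8f"))))))
  f_reps <- file.path(dir, "replicates.csv")
  write_stable_csv(reps, f_reps)
  invisible(c(f_json, f_dens, f_reps))
}
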