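# dielshift

Quantifying shifts in the daily activity of ectothermic prey under
predation pressure.

Reptiles in cold mountain environments must bask to reach their preferred
body temperature, and basking in the open is exactly when visually hunting
raptors can find them. One behavioural escape route is temporal: shift
activity into thermally suboptimal parts of the day that predators use
less. `dielshift` provides the statistical machinery to detect such a
shift from three kinds of field data:

* **observation times** of prey and predators (time of day, treated as a
  circular random variable),
* **gradient-selected body temperatures** `T_b` — the thermal preference of
  the animal measured in a laboratory gradient, and
* **operative temperatures** `T_o` — logger series from biomimetic models
  placed in different micro-environments, describing what body temperature
  a non-thermoregulating animal would reach over the day.

## Methods at a glance

* **Circular activity densities.** Time of day is mapped to angles
  (`hours * 2π/24`) and activity is estimated either by a von Mises kernel
  density estimate with the Taylor plug-in concentration
  `κ_h = (3 n κ̂² I₂(2κ̂) / (4 √π I₀(κ̂)²))^{2/5}`, or by maximum-likelihood
  nonnegative trigonometric sums
  `f(θ) = |Σ_k c_k e^{ikθ}|² / (2π Σ_k |c_k|²)` with AIC order selection.
* **Coefficient of overlapping.** For two activity densities,
  `Δ = ∫ min(f₁, f₂)` (0 = disjoint, 1 = identical), estimated from samples
  by the grid (Dhat1) or density-ratio (Dhat4) kernel estimator, with a
  smoothed bootstrap giving bias-corrected percentile confidence intervals,
  and a rank-sum test comparing two overlaps via their bootstrap
  replicates.
* **Thermally potential activity.** The `T_b` sample is summarized by a
  Pearson-system distribution matched to its mean, variance, skewness and
  kurtosis; the fitted density rescaled to a 0–1 "activity probability";
  each 5-minute interval of the day is weighted by the probability at its
  mean `T_o`; and times are resampled with those weights. The resulting
  "potential" activity distribution is what the animal *could* do on
  thermal grounds alone — the gap between it and the observed distribution
  is the behavioural shift.
* **Synthetic data.** A seeded generator produces observation times
  (bimodal prey, midday predator), body temperatures and multi-microhabitat
  logger series with the structure the analysis assumes, so every step is
  testable without field data.

## Worked example

```r
library(dielshift)

dir <- tempfile()
paths <- simulate_scenario(scenario_config(seed = 1), dir)
res <- run_pipeline(analysis_config(seed = 1, n_boot = 1000),
                    paths$observations, paths$tb, paths$to)
res
#> <dielshift_results> 2 site(s); thermal preference type III (peak 28.2 C)
#>   siteA (prey n=19, predator n=49):
#>     observed_vs_potential  Delta = 0.551 [0.377, 0.727]
#>     predator_vs_observed   Delta = 0.434 [0.318, 0.585]
#>     predator_vs_potential  Delta = 0.721 [0.562, 0.863]
#>     rank-sum W = 5354, p = 0
#>   siteB (prey n=19, predator n=49):
#>     observed_vs_potential  Delta = 0.639 [0.466, 0.815]
#>     predator_vs_observed   Delta = 0.463 [0.341, 0.607]
#>     predator_vs_potential  Delta = 0.659 [0.502, 0.829]
#>     rank-sum W = 34207, p = 6.44e-285
```

Reading the output: the gamma-shaped thermal preference simulated for the
gradient data is recognized as a Pearson type III density peaking near
28 °C. At each site the observed prey activity overlaps the thermally
potential activity only moderately (`Δ ≈ 0.55–0.64`), and
the predator's midday activity overlaps the *potential* prey activity
substantially more than the *observed* one — the rank-sum test on the
bootstrap replicates of the two overlaps is decisive. That is the
signature of a predator-avoidance shift: the prey is active earlier and
later than the thermal environment alone would predict.

Individual steps are exported too: `kde_circular()`, `fit_trig_sum()`,
`overlap_delta()`, `overlap_from_samples()`, `bootstrap_delta()`,
`compare_overlaps()`, `fit_pearson()`, `activity_probability()`,
`aggregate_to()`, `potential_activity()`, and the survey summaries
`prevalence()`, `per_population_summary()`, `sex_size_comparison()`.

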