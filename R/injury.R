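# Descriptive summaries of the predation-injury survey.

# Half-up rounding (round() in R rounds half to even, which would report
# 12.45 -> 12.4; survey percentages are conventionally rounded half up).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_viper_records <- function(records) {
  need <- c("population", "sex", "svl_mm", "injured")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_input("records must be a data frame with columns %s",
               paste(need, collapse = ", "))
  if (nrow(records) == 0L) stop_input("no viper records")
  invisible(records)
}

#' Injury prevalence
#'
#' @param records Viper survey data frame (`population`, `sex`, `svl_mm`,
#'   `injured`).
#' @return List `n_total`, `n_injured`, `percent` (half-up rounded to one
#'   decimal).
#' @examples
#' recs <- data.frame(population = "p", sex = "female", svl_mm = 300,
#'                    injured = rep(c(TRUE, FALSE), c(40, 279)))
#' prevalence(recs)$percent  # 12.5
#' @export
prevalence <- function(records) {
  check_viper_records(records)
  n <- nrow(records)
  ninj <- sum(as.logical(records$injured))
  list(n_total = n, n_injured = ninj,
       percent = round_half_up(100 * ninj / n, 1))
}

#' Per-population survey effort summary
#'
#' @param records Viper survey data frame.
#' @return List `n_populations`, `mean_count`, `se_count` (`NA` for a single
#'   population), `counts`.
#' @export
per_population_summary <- function(records) {
  check_viper_records(records)
  counts <- as.integer(table(records$population))
  k <- length(counts)
  list(n_populations = k,
       mean_count = mean(counts),
       se_count = if (k > 1) stats::sd(counts) / sqrt(k) else NA_real_,
       counts = counts)
}

#' Sex difference in body size
#'
#' Two-sided Wilcoxon rank-sum test of snout-vent length by sex; the
#' statistic is oriented with females as the first group.
#'
#' @param records Viper survey data frame with both sexes present
#'   (`>= 2` records each).
#' @return List `statistic` (W), `p_value`, `median_female`, `median_male`,
#'   `n_female`, `n_male`.
#' @export
sex_size_comparison <- function(records) {
  check_viper_records(records)
  f <- records$svl_mm[records$sex == "female"]
  m <- records$svl_mm[records$sex == "male"]
  if (length(f) < 2L || length(m) < 2L)
    stop_input("need at least 2 records per sex (female: %d, male: %d)",
               length(f), length(m))
  wt <- suppressWarnings(
    stats::wilcox.test(f, m, alternative = "two.sided", exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_female = stats::median(f), median_male = stats::median(m),
       n_female = length(f), n_male = length(m))
}
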