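# The Pearson fit is checked two ways: fitted_moments (closed-form moments
# implied by the solved parameters) against the sample moments, and the
# density itself against independent numerical quadrature of its moments.

quad_moments <- function(fit) {
  lo <- max(fit$support[1], fit$fitted_moments[["mean"]] -
              60 * sqrt(fit$fitted_moments[["variance"]]))
  hi <- min(fit$support[2], fit$fitted_moments[["mean"]] +
              60 * sqrt(fit$fitted_moments[["variance"]]))
  mom <- function(p) stats::integrate(function(x) x^p * fit$density(x), lo, hi,
                                      rel.tol = 1e-11,
                                      subdivisions = 500L)$value
  r <- vapply(0:4, mom, numeric(1))
  raw <- r[2:5] / r[1]
  mu2 <- raw[2] - raw[1]^2
  mu3 <- raw[3] - 3 * raw[1] * raw[2] + 2 * raw[1]^3
  mu4 <- raw[4] - 4 * raw[1] * raw[3] + 6 * raw[1]^2 * raw[2] - 3 * raw[1]^4
  c(mean = raw[1], variance = mu2, skewness = mu3 / mu2^1.5,
    kurtosis = mu4 / mu2^2)
}

test_that("interior Pearson families match all four sample moments exactly", {
  draws <- list(
    beta_I      = function() 3 + 10 * rbeta(4000, 2, 5),
    beta_left   = function() 3 + 10 * rbeta(4000, 5, 1.5),
    invgamma_VI = function() 1 / rgamma(8000, 9),
    fisher_VI   = function() rf(8000, 10, 30))
  seeds <- c(61, 62, 63, 64)
  for (i in seq_along(draws)) {
    set.seed(seeds[i])
    x <- draws[[i]]()
    fit <- fit_pearson(x)
    expect_true(fit$family %in% c("I", "IV", "VI"), info = names(draws)[i])
    sm <- fit$sample_moments
    expect_equal(fit$fitted_moments[["mean"]], sm[["mean"]],
                 tolerance = 1e-8, info = names(draws)[i])
    expect_equal(fit$fitted_moments[["variance"]], sm[["variance"]],
                 tolerance = 1e-8, info = names(draws)[i])
    expect_equal(fit$fitted_moments[["skewness"]], sm[["skewness"]],
                 tolerance = 1e-8, info = names(draws)[i])
    expect_equal(fit$fitted_moments[["kurtosis"]], sm[["kurtosis"]],
                 tolerance = 1e-8, info = names(draws)[i])
    qm <- quad_moments(fit)
    expect_equal(unname(qm), unname(sm), tolerance = 1e-6,
                 info = paste("quadrature", names(draws)[i]))
  }
})

test_that("a skewed heavy-tailed sample lands in type IV and still moment-matches", {
  set.seed(65)
  x <- sinh((rnorm(20000) + 0.9) / 1.6)  # skewed, unbounded both sides
  fit <- fit_pearson(x)
  expect_identical(fit$family, "IV")
  expect_equal(unname(fit$fitted_moments), unname(fit$sample_moments),
               tolerance = 1e-7)
  # density integrates to 1 on its infinite support
  z <- stats::integrate(fit$density, -Inf, Inf, rel.tol = 1e-9)$value
  expect_equal(z, 1, tolerance = 1e-6)
})

test_that("large gamma samples are recognized as type III with the shape recovered", {
  set.seed(1)
  x <- 20 + rgamma(1e5, shape = 4)
  fit <- fit_pearson(x)
  expect_identical(fit$family, "III")
  expect_lt(abs(fit$parameters$shape - 4) / 4, 0.05)
  # matched moments: mean, variance, skewness
  expect_equal(unname(fit$fitted_moments[1:3]), unname(fit$sample_moments[1:3]),
               tolerance = 1e-10)
})

test_that("negative skew mirrors type III correctly", {
  set.seed(66)
  x <- 40 - rgamma(5e4, shape = 6)
  fit <- fit_pearson(x)
  expect_identical(fit$family, "III")
  expect_lt(fit$fitted_moments[["skewness"]], 0)
  qm <- quad_moments(fit)
  expect_equal(unname(qm[1:3]), unname(fit$sample_moments[1:3]),
               tolerance = 1e-6)
})

test_that("a large normal draw collapses to the normal limit with exact mean and sd", {
  set.seed(67)
  x <- rnorm(5e4, 30, 3)
  fit <- fit_pearson(x)
  expect_identical(fit$family, "normal")
  expect_equal(fit$parameters$mean, mean(x), tolerance = 1e-12)
  expect_equal(fit$parameters$sd^2, mean((x - mean(x))^2), tolerance = 1e-12)
})

test_that("symmetric heavy tails collapse to the scaled-t (type VII) limit", {
  set.seed(68)
  x <- rt(3e4, df = 8)
  fit <- fit_pearson(x)
  expect_identical(fit$family, "VII")
  expect_equal(fit$fitted_moments[["kurtosis"]], fit$sample_moments[["kurtosis"]],
               tolerance = 1e-10)
})

test_that("sample skewness and kurtosis agree with an independent implementation", {
  skip_if_not_installed("fitdistrplus")
  set.seed(69)
  x <- rgamma(2000, 3)
  mu <- dielshift:::central_moments(x, 4)
  # descdist's method-of-moments estimators use the same n-denominator
  dd <- fitdistrplus::descdist(x, graph = FALSE)
  expect_equal(mu[3] / mu[2]^1.5, dd$skewness, tolerance = 0.02)
  expect_equal(mu[4] / mu[2]^2, dd$kurtosis, tolerance = 0.02)
})

test_that("degenerate and unrealizable inputs raise estimation errors", {
  expect_error(fit_pearson(rep(28, 50)), class = "dielshift_estimation_error")
  expect_error(fit_pearson(c(1, 2, 3)), class = "dielshift_estimation_error")
  expect_error(fit_pearson(rep(c(0, 1), 20)),  # two-point: beta2 = beta1 + 1
               class = "dielshift_estimation_error")
  expect_error(fit_pearson(c(1, NA, 3, 4)), class = "dielshift_input_error")
})

test_that("activity probability peaks at exactly 1 and vanishes off-support", {
  set.seed(70)
  fit <- fit_pearson(20 + rgamma(5000, shape = 9))
  curve <- activity_probability(fit, seq(0, 50, by = 0.05))
  expect_identical(max(curve$prob), 1)
  expect_true(all(curve$prob >= 0))
  expect_lt(abs(curve$t_max - 28), 1)           # gamma(9) mode at 28
  expect_identical(fit$density(5), 0)           # far below the support
  expect_error(activity_probability(fit, seq(0, 10, by = 0.5)),
               class = "dielshift_estimation_error")
})

test_that("a symmetric fit yields a probability curve symmetric about the mean", {
  set.seed(71)
  fit <- fit_pearson(rnorm(5e4, 30, 2.5))
  expect_identical(fit$family, "normal")
  m <- fit$parameters$mean
  d <- seq(0.1, 8, by = 0.3)
  expect_equal(fit$density(m + d), fit$density(m - d), tolerance = 1e-9)
})
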