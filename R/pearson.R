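# Pearson distribution system fitted by matching the first four moments,
# used to summarize gradient-selected body temperatures (thermal preference).
#
# Classification follows the classical (beta1, beta2) moment-ratio plane,
# where beta1 is squared skewness and beta2 is (non-excess) kurtosis:
# interior families are type I (bounded, beta), type IV (unbounded, skewed
# heavy tails) and type VI (half-bounded, beta-prime); the normal, type III
# (gamma), type V (inverse gamma) and type VII (scaled t) live on boundary
# curves of measure zero. Finite samples never land exactly on a boundary,
# so the classifier collapses to a boundary family whenever the sample
# moment point is within `boundary_z` asymptotic standard errors (delta
# method) of it: a large gamma sample is then recognized as type III and a
# large normal sample as the normal limit, while the moments a boundary
# family can match are matched exactly and the remaining one is implied.

# Central moments with denominator n, orders 1..max_order.
central_moments <- function(x, max_order = 8L) {
  xc <- x - mean(x)
  vapply(seq_len(max_order), function(k) mean(xc^k), numeric(1))
}

# Delta-method asymptotic SEs for skewness gamma1, kurtosis beta2 and the
# type-III criterion D = 2*beta2 - 3*beta1 - 6, from empirical central
# moments up to order 8. Returns SEs scaled by 1/sqrt(n).
moment_ratio_se <- function(mu, n) {
  g <- function(j, k) {  # n * Cov(m_j, m_k); mu_0 = 1, mu_1 = 0
    mom <- function(i) if (i == 0) 1 else if (i == 1) 0 else mu[i]
    mom(j + k) - mom(j) * mom(k) + j * k * mu[2] * mom(j - 1) * mom(k - 1) -
      j * mom(j - 1) * mom(k + 1) - k * mom(k - 1) * mom(j + 1)
  }
  S <- matrix(0, 3, 3)
  ord <- c(2, 3, 4)
  for (a in 1:3) for (b in 1:3) S[a, b] <- g(ord[a], ord[b])
  mu2 <- mu[2]; mu3 <- mu[3]; mu4 <- mu[4]
  grad_g1 <- c(-1.5 * mu3 / mu2^2.5, 1 / mu2^1.5, 0)
  grad_b2 <- c(-2 * mu4 / mu2^3, 0, 1 / mu2^2)
  grad_b1 <- c(-3 * mu3^2 / mu2^4, 2 * mu3 / mu2^3, 0)
  grad_D <- 2 * grad_b2 - 3 * grad_b1
  se <- function(grad) sqrt(max(0, drop(t(grad) %*% S %*% grad)) / n)
  list(se_g1 = se(grad_g1), se_b2 = se(grad_b2), se_D = se(grad_D))
}

#' Fit a Pearson-system distribution by moment matching
#'
#' Selects a Pearson family from the sample's squared skewness and kurtosis
#' and solves the family's parameters so that the matched sample moments are
#' reproduced exactly. Interior families (I, IV, VI) match all four moments;
#' boundary families are chosen when the moment point lies within
#' `boundary_z` asymptotic standard errors of the boundary and match the
#' moments they can (normal: mean/variance; III: mean/variance/skewness;
#' VII: mean/variance/kurtosis), the remaining moment being implied by the
#' family.
#'
#' @param tb Numeric sample (here: selected body temperatures, degrees C),
#'   `n >= 4`, nonzero variance.
#' @param boundary_z Boundary-collapse width in standard errors (default 2);
#'   set to 0 to force the exact interior classification.
#' @return An object of class `pearson_fit` with fields `family` (one of
#'   `"normal"`, `"I"`, `"III"`, `"IV"`, `"V"`, `"VI"`, `"VII"`),
#'   `parameters`, `fitted_moments` (mean, variance, skewness, kurtosis
#'   implied by the fit), `sample_moments`, `support`, and `density`
#'   (vectorized function of temperature).
#' @examples
#' set.seed(1)
#' fit <- fit_pearson(20 + rgamma(5000, shape = 9))
#' fit$family
#' @export
fit_pearson <- function(tb, boundary_z = 2) {
  if (!is.numeric(tb) || any(!is.finite(tb)))
    stop_input("tb must be a finite numeric vector")
  n <- length(tb)
  if (n < 4L) stop_estimation("need at least 4 observations to match four moments")
  mu <- central_moments(tb, 8L)
  m <- mean(tb)
  mu2 <- mu[2]; mu3 <- mu[3]; mu4 <- mu[4]
  if (mu2 <= 0 || mu2 < 1e-12 * max(1, m^2))
    stop_estimation("degenerate (zero-variance) sample")
  g1 <- mu3 / mu2^1.5
  b1 <- g1^2
  b2 <- mu4 / mu2^2
  if (b2 <= b1 + 1 + 1e-12)
    stop_estimation(
      "moment point (beta1 = %.4g, beta2 = %.4g) is outside the realizable region beta2 > beta1 + 1",
      b1, b2)
  se <- moment_ratio_se(mu, n)
  sdv <- sqrt(mu2)
  Dcrit <- 2 * b2 - 3 * b1 - 6

  symmetric <- abs(g1) <= boundary_z * se$se_g1
  fit <-
    if (symmetric && abs(b2 - 3) <= boundary_z * se$se_b2) {
      pearson_normal(m, sdv)
    } else if (symmetric && b2 > 3) {
      pearson_vii(m, sdv, b2)
    } else if (symmetric) {
      pearson_i(m, sdv, 0, b2)
    } else if (abs(Dcrit) <= boundary_z * se$se_D) {
      pearson_iii(m, sdv, g1)
    } else {
      kappa <- b1 * (b2 + 3)^2 / (4 * (4 * b2 - 3 * b1) * Dcrit)
      if (kappa < 0) {
        pearson_i(m, sdv, g1, b2)
      } else if (kappa < 1 - 1e-6) {
        pearson_iv(m, sdv, g1, b2)
      } else if (kappa <= 1 + 1e-6) {
        pearson_v(m, sdv, g1, b2)
      } else {
        pearson_vi(m, sdv, g1, b2)
      }
    }
  fit$sample_moments <- c(mean = m, variance = mu2, skewness = g1, kurtosis = b2)
  fit$n <- n
  class(fit) <- "pearson_fit"
  fit
}

#' @export
print.pearson_fit <- function(x, ...) {
  cat(sprintf(
    "<pearson_fit> type %s; mean %.3f, var %.3f, skew %.3f, kurt %.3f; support [%.3g, %.3g]\n",
    x$family, x$fitted_moments["mean"], x$fitted_moments["variance"],
    x$fitted_moments["skewness"], x$fitted_moments["kurtosis"],
    x$support[1], x$support[2]))
  invisible(x)
}

#' Evaluate a fitted Pearson density
#'
#' @param fit A [fit_pearson()] result.
#' @param x Evaluation points.
#' @return Density values (0 outside the support).
#' @export
pearson_density <- function(fit, x) {
  if (!inherits(fit, "pearson_fit")) stop_input("expected a pearson_fit object")
  fit$density(x)
}

raw_to_central4 <- function(r1, r2, r3, r4) {
  mu2 <- r2 - r1^2
  mu3 <- r3 - 3 * r1 * r2 + 2 * r1^3
  mu4 <- r4 - 4 * r1 * r3 + 6 * r1^2 * r2 - 3 * r1^4
  c(mu2, mu3, mu4)
}

fitted_from_linear <- function(lambda, delta, rw) {
  # moments of X = lambda + delta * W from raw moments rw[1..4] of W
  r1 <- rw[1]; ctr <- raw_to_central4(rw[1], rw[2], rw[3], rw[4])
  mu2 <- delta^2 * ctr[1]
  mu3 <- delta^3 * ctr[2]
  mu4 <- delta^4 * ctr[3]
  c(mean = lambda + delta * r1, variance = mu2,
    skewness = mu3 / mu2^1.5, kurtosis = mu4 / mu2^2)
}

pearson_normal <- function(m, sdv) {
  list(family = "normal",
       parameters = list(mean = m, sd = sdv),
       fitted_moments = c(mean = m, variance = sdv^2, skewness = 0, kurtosis = 3),
       support = c(-Inf, Inf),
       density = function(x) stats::dnorm(x, m, sdv))
}

pearson_vii <- function(m, sdv, b2) {
  df <- 4 + 6 / (b2 - 3)
  s <- sdv * sqrt((df - 2) / df)
  list(family = "VII",
       parameters = list(location = m, scale = s, df = df),
       fitted_moments = c(mean = m, variance = sdv^2, skewness = 0, kurtosis = b2),
       support = c(-Inf, Inf),
       density = function(x) stats::dt((x - m) / s, df) / s)
}

pearson_iii <- function(m, sdv, g1) {
  # gamma with shape 4/g1^2; matches mean, variance, skewness exactly;
  # kurtosis implied = 3 + 1.5 * g1^2
  ag <- abs(g1)
  shape <- 4 / g1^2
  scale <- sdv * ag / 2
  sgn <- if (g1 >= 0) 1 else -1
  loc <- m - sgn * shape * scale
  dens <- function(x) {
    y <- sgn * (x - loc)
    out <- numeric(length(x))
    ok <- y > 0
    out[ok] <- stats::dgamma(y[ok], shape = shape, scale = scale)
    out
  }
  supp <- if (sgn > 0) c(loc, Inf) else c(-Inf, loc)
  list(family = "III",
       parameters = list(shape = shape, scale = sgn * scale, location = loc),
       fitted_moments = c(mean = m, variance = sdv^2, skewness = g1,
                          kurtosis = 3 + 1.5 * g1^2),
       support = supp,
       density = dens)
}

pearson_i <- function(m, sdv, g1, b2) {
  b1 <- g1^2
  denom <- 6 + 3 * b1 - 2 * b2
  if (denom <= 0) stop_estimation("type I solve failed (r denominator <= 0)")
  r <- 6 * (b2 - b1 - 1) / denom
  tt <- if (b1 == 0) 0 else
    (r + 2) * sqrt(b1) / sqrt(b1 * (r + 2)^2 + 16 * (r + 1))
  alpha <- (r / 2) * (1 - tt)   # smaller shape -> positive skew
  beta <- r - alpha
  if (g1 < 0) { tmp <- alpha; alpha <- beta; beta <- tmp }
  if (alpha <= 0 || beta <= 0)
    stop_estimation("type I solve produced nonpositive beta shapes")
  varB <- alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1))
  delta <- sdv / sqrt(varB)
  lambda <- m - delta * alpha / (alpha + beta)
  rw <- cumprod((alpha + 0:3) / (alpha + beta + 0:3))  # raw moments of Beta
  dens <- function(x) {
    w <- (x - lambda) / delta
    out <- numeric(length(x))
    ok <- w > 0 & w < 1
    out[ok] <- stats::dbeta(w[ok], alpha, beta) / delta
    out
  }
  list(family = "I",
       parameters = list(shape1 = alpha, shape2 = beta,
                         location = lambda, scale = delta),
       fitted_moments = fitted_from_linear(lambda, delta, rw),
       support = c(lambda, lambda + delta),
       density = dens)
}

# Quadratic-denominator coefficients of the Pearson ODE
#   f'/f = -(x + b1c) / (b0c + b1c x + b2c x^2)   (x centered at the mean);
# valid for the IV/V/VI region where the common denominator c is positive.
pearson_ode_coefs <- function(sdv, g1, b2) {
  b1 <- g1^2
  c0 <- 10 * b2 - 12 * b1 - 18
  if (c0 <= 0) stop_estimation("Pearson ODE denominator nonpositive in IV/V/VI region")
  list(b0c = sdv^2 * (4 * b2 - 3 * b1) / c0,
       b1c = sdv * g1 * (b2 + 3) / c0,
       b2c = (2 * b2 - 3 * b1 - 6) / c0)
}

pearson_iv <- function(m, sdv, g1, b2) {
  co <- pearson_ode_coefs(sdv, g1, b2)
  mm <- 1 / (2 * co$b2c)
  lc <- -co$b1c / (2 * co$b2c)                 # mode offset from mean
  A2 <- co$b0c / co$b2c - co$b1c^2 / (4 * co$b2c^2)
  if (!is.finite(A2) || A2 <= 0) stop_estimation("type IV solve failed (A^2 <= 0)")
  A <- sqrt(A2)
  nu <- (lc + co$b1c) / (co$b2c * A)
  # normalization and moments via x = (m + lc) + A tan(phi);
  # tan^p cos^(2m-2) = sin^p cos^(2m-2-p) keeps the integrand bounded
  # (or endpoint-integrable) for p <= 4 since m > 2.5 in the IV region
  base_int <- function(p) {
    stats::integrate(function(phi)
      sin(phi)^p * cos(phi)^(2 * mm - 2 - p) * exp(-nu * phi),
      -pi / 2, pi / 2, rel.tol = 1e-11, subdivisions = 500L)$value
  }
  i0 <- base_int(0)
  Z <- A * i0
  tp <- vapply(1:4, function(p) base_int(p) / i0, numeric(1))  # E tan^p
  L <- m + lc
  raw <- vapply(1:4, function(p)
    sum(choose(p, 0:p) * L^(p - (0:p)) * A^(0:p) * c(1, tp)[1 + (0:p)]),
    numeric(1))
  ctr <- raw_to_central4(raw[1], raw[2], raw[3], raw[4])
  dens <- function(x) {
    z <- (x - m - lc) / A
    exp(-mm * log1p(z^2) - nu * atan(z)) / Z
  }
  list(family = "IV",
       parameters = list(m = mm, nu = nu, location = m + lc, scale = A),
       fitted_moments = c(mean = raw[1], variance = ctr[1],
                          skewness = ctr[2] / ctr[1]^1.5,
                          kurtosis = ctr[3] / ctr[1]^2),
       support = c(-Inf, Inf),
       density = dens)
}

pearson_v <- function(m, sdv, g1, b2) {
  co <- pearson_ode_coefs(sdv, g1, b2)
  a <- -co$b1c / (2 * co$b2c)                  # double root (centered)
  shape <- 1 / co$b2c - 1
  rate <- -(a + co$b1c) / co$b2c
  sgn <- if (g1 >= 0) 1 else -1
  if (sgn < 0) { a <- -a; rate <- -rate }      # mirror for left skew
  if (shape <= 4 || rate <= 0)
    stop_estimation("type V solve failed (shape %.3g, rate %.3g)", shape, rate)
  loc <- if (sgn > 0) m + a else m - a
  # inverse-gamma moments: E Y^k = rate^k / prod(shape-1 ... shape-k)
  raw_y <- vapply(1:4, function(k) rate^k / prod(shape - seq_len(k)), numeric(1))
  dens <- function(x) {
    y <- sgn * (x - loc)
    out <- numeric(length(x))
    ok <- y > 0
    out[ok] <- stats::dgamma(1 / y[ok], shape = shape, rate = rate) / y[ok]^2
    out
  }
  fm <- fitted_from_linear(loc, sgn, raw_y)
  list(family = "V",
       parameters = list(shape = shape, rate = rate, location = loc, sign = sgn),
       fitted_moments = fm,
       support = if (sgn > 0) c(loc, Inf) else c(-Inf, loc),
       density = dens)
}

pearson_vi <- function(m, sdv, g1, b2) {
  sgn <- if (g1 >= 0) 1 else -1
  co <- pearson_ode_coefs(sdv, sgn * g1, b2)   # solve for the right-skew mirror
  disc <- co$b1c^2 - 4 * co$b0c * co$b2c
  if (disc <= 0) stop_estimation("type VI solve failed (complex roots)")
  a1 <- (-co$b1c - sqrt(disc)) / (2 * co$b2c)
  a2 <- (-co$b1c + sqrt(disc)) / (2 * co$b2c)
  if (a1 > a2) { tmp <- a1; a1 <- a2; a2 <- tmp }
  if (a2 >= 0) stop_estimation("type VI solve failed (roots not both negative)")
  m1 <- (a1 + co$b1c) / (co$b2c * (a2 - a1))
  m2 <- -(a2 + co$b1c) / (co$b2c * (a2 - a1))
  alpha <- m2 + 1
  beta <- -m1 - m2 - 1
  if (alpha <= 0 || beta <= 4)
    stop_estimation("type VI solve failed (beta-prime shapes %.3g, %.3g)",
                    alpha, beta)
  delta <- a2 - a1                              # > 0
  raw_w <- cumprod((alpha + 0:3) / (beta - 1 - 0:3))  # beta-prime raw moments
  dens <- function(x) {
    w <- (sgn * (x - m) - a2) / delta
    out <- numeric(length(x))
    ok <- w > 0
    out[ok] <- exp((alpha - 1) * log(w[ok]) - (alpha + beta) * log1p(w[ok]) -
                     lbeta(alpha, beta)) / delta
    out
  }
  # X = m + sgn * (a2 + delta * W), W ~ beta-prime(alpha, beta)
  fm <- fitted_from_linear(m + sgn * a2, sgn * delta, raw_w)
  supp <- if (sgn > 0) c(m + a2, Inf) else c(-Inf, m - a2)
  list(family = "VI",
       parameters = list(shape1 = alpha, shape2 = beta, location = supp[1],
                         scale = delta, sign = sgn),
       fitted_moments = fm,
       support = supp,
       density = dens)
}
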