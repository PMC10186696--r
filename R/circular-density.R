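# Circular (time-of-day) samples and periodic density estimation.

#' Convert clock time to an angle on the diel circle
#'
#' Maps time of day to radians, `hours * 2 * pi / 24`. Accepts numeric hours
#' in `[0, 24)`, `"HH:MM"` / `"HH:MM:SS"` clock strings, ISO 8601 timestamps
#' (`"2017-07-15T06:30:00"`, the date part is discarded) or `POSIXct`.
#'
#' @param x Times (numeric hours, character, or `POSIXct`).
#' @return Angles in radians, `[0, 2*pi)`.
#' @examples
#' time_to_angle(c(0, 12, 6.5))
#' time_to_angle("06:30")
#' @export
time_to_angle <- function(x) {
  hours <- time_to_hours(x)
  (hours %% 24) * 2 * pi / 24
}

# Internal: coerce any supported time representation to fractional hours.
time_to_hours <- function(x) {
  if (inherits(x, "POSIXt")) {
    lt <- as.POSIXlt(x)
    return(lt$hour + lt$min / 60 + lt$sec / 3600)
  }
  if (is.numeric(x)) {
    if (any(!is.finite(x)) || any(x < 0) || any(x >= 24))
      stop_input("numeric times must be finite hours in [0, 24)")
    return(x)
  }
  if (is.character(x)) {
    clock <- sub("^.*[T ]", "", x)  # strip a date part if present
    parts <- strsplit(clock, ":", fixed = TRUE)
    bad <- which(!vapply(parts, function(p)
      length(p) %in% 2:3 && !anyNA(suppressWarnings(as.numeric(p))), logical(1)))
    if (length(bad))
      stop_input("unparseable time at position %d: '%s'", bad[1], x[bad[1]])
    hours <- vapply(parts, function(p) {
      p <- as.numeric(p)
      p[1] + p[2] / 60 + if (length(p) == 3) p[3] / 3600 else 0
    }, numeric(1))
    if (any(hours < 0) || any(hours >= 24))
      stop_input("clock times must fall in [00:00, 24:00)")
    return(hours)
  }
  stop_input("unsupported time representation of class '%s'", class(x)[1])
}

#' Construct a circular sample of activity times
#'
#' @param angles Angles in radians, `[0, 2*pi)` (values are wrapped).
#' @param role One of `"prey"`, `"predator"`, `"potential"`.
#' @param site Site label.
#' @return An object of class `circular_sample`.
#' @seealso [time_to_angle()] to convert clock times.
#' @export
circular_sample <- function(angles, role = "prey", site = "site") {
  if (!is.numeric(angles) || length(angles) < 1L || any(!is.finite(angles)))
    stop_input("angles must be a nonempty numeric vector of finite radians")
  if (!is.character(role) || length(role) != 1L ||
      !role %in% c("prey", "predator", "potential"))
    stop_input("role must be one of 'prey', 'predator', 'potential' (got '%s')",
               as.character(role)[1])
  structure(
    list(angles = as.numeric(angles) %% (2 * pi), role = role,
         site = site, n = length(angles)),
    class = "circular_sample"
  )
}

#' @export
print.circular_sample <- function(x, ...) {
  cat(sprintf("<circular_sample> %s @ %s, n = %d\n", x$role, x$site, x$n))
  invisible(x)
}

#' Construct a periodic density curve on a regular angular grid
#'
#' The grid holds `m` equally spaced angles in `[0, 2*pi)`; on such a grid
#' the periodic trapezoidal rule is the spacing times the sum of values, and
#' curves are normalized to integrate to 1 over the circle.
#'
#' @param values Nonnegative density values at `2*pi*(0:(m-1))/m`.
#' @param estimator Label recording how the curve was obtained.
#' @param bandwidth Smoothing parameter used, if any.
#' @param normalize Rescale so the circular integral is 1 (default `TRUE`).
#' @return An object of class `density_curve` with fields `grid`, `values`,
#'   `meta`.
#' @export
density_curve <- function(values, estimator = "manual", bandwidth = NA_real_,
                          normalize = TRUE) {
  m <- length(values)
  if (m < 8L || any(!is.finite(values)) || any(values < 0))
    stop_input("values must be >= 8 finite nonnegative densities")
  h <- 2 * pi / m
  if (normalize) {
    tot <- h * sum(values)
    if (tot <= 0) stop_estimation("density curve has zero total mass")
    values <- values / tot
  }
  structure(
    list(grid = h * (seq_len(m) - 1), values = as.numeric(values),
         meta = list(estimator = estimator, bandwidth = bandwidth)),
    class = "density_curve"
  )
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf("<density_curve> %s on %d grid points (integral %.6f)\n",
              x$meta$estimator, length(x$grid), curve_integral(x)))
  invisible(x)
}

# Circular trapezoidal integral of a curve (or of arbitrary values on its grid).
curve_integral <- function(curve, values = curve$values) {
  (2 * pi / length(curve$grid)) * sum(values)
}

#' Evaluate a density curve at arbitrary angles
#'
#' Periodic linear interpolation between grid points.
#'
#' @param curve A [density_curve()].
#' @param theta Angles (radians, wrapped to `[0, 2*pi)`).
#' @return Density values at `theta`.
#' @export
eval_density_curve <- function(curve, theta) {
  m <- length(curve$grid)
  h <- 2 * pi / m
  pos <- (theta %% (2 * pi)) / h
  i0 <- floor(pos)
  frac <- pos - i0
  i0 <- as.integer(i0 %% m)
  i1 <- (i0 + 1L) %% m
  (1 - frac) * curve$values[i0 + 1L] + frac * curve$values[i1 + 1L]
}

#' von Mises kernel density estimate on the circle
#'
#' Smooths the sample with von Mises kernels whose concentration comes from
#' the Taylor (2008) plug-in rule (see [bw_vonmises_plugin]); larger
#' `bandwidth_adjust` means a smoother estimate (the kernel concentration is
#' divided by it).
#'
#' @param sample A [circular_sample()] with `n >= 2`.
#' @param bandwidth_adjust Positive bandwidth multiplier (default 1).
#' @param grid_size Number of grid points (default 512).
#' @return A [density_curve()].
#' @export
kde_circular <- function(sample, bandwidth_adjust = 1, grid_size = 512L) {
  check_sample(sample, min_n = 2L)
  if (!is.numeric(bandwidth_adjust) || bandwidth_adjust <= 0)
    stop_input("bandwidth_adjust must be positive")
  if (grid_size < 64L) stop_input("grid_size must be >= 64")
  kap <- bw_vonmises_plugin(sample$angles) / bandwidth_adjust
  grid <- 2 * pi * (seq_len(grid_size) - 1) / grid_size
  vals <- kde_values(grid, sample$angles, kap)
  density_curve(vals, estimator = "vonmises_kde", bandwidth = kap)
}

# Mean of von Mises kernels over data points, evaluated at `at`.
# Scaled-Bessel form keeps huge kernel concentrations finite.
kde_values <- function(at, angles, kappa) {
  i0s <- if (kappa > 1e5) 1 / sqrt(2 * pi * kappa)  # besselI degrades here
         else besselI(kappa, 0, expon.scaled = TRUE)
  mat <- exp(kappa * (cos(outer(at, angles, "-")) - 1))
  rowMeans(mat) / (2 * pi * i0s)
}

#' Nonnegative trigonometric-sum density fit
#'
#' Fits the nonnegative trigonometric sum family of Fernandez-Duran (2004),
#' \eqn{f(\theta) = |\sum_{k=0}^{K} c_k e^{ik\theta}|^2 / (2\pi\sum|c_k|^2)},
#' by maximum likelihood, choosing the order `K` in `0..max_order` by AIC
#' (2K free parameters; K = 0 is the circular uniform). The family is
#' nonnegative and normalized by construction.
#'
#' @param sample A [circular_sample()] with `n >= 2 * max_order + 2`.
#' @param max_order Largest harmonic order tried (default 4).
#' @param grid_size Number of grid points for the returned curve.
#' @param n_starts Random restarts per order in addition to the
#'   moment-based start (default 2).
#' @return A [density_curve()] whose `meta` records the selected order and
#'   fitted coefficients.
#' @export
fit_trig_sum <- function(sample, max_order = 4L, grid_size = 512L,
                         n_starts = 2L) {
  check_sample(sample, min_n = 2L * max_order + 2L)
  x <- sample$angles
  n <- length(x)
  best <- list(aic = Inf, k = 0L, par = NULL, loglik = NULL)
  for (k in 0:max_order) {
    fit <- tryCatch(nnts_ml(x, k, n_starts = n_starts),
                    error = function(e) NULL)
    if (is.null(fit)) next
    aic <- 2 * (2 * k) - 2 * fit$loglik
    if (aic < best$aic)
      best <- list(aic = aic, k = k, par = fit$par, loglik = fit$loglik)
  }
  if (!is.finite(best$aic))
    stop_estimation("trigonometric-sum fit failed at every order up to %d",
                    max_order)
  grid <- 2 * pi * (seq_len(grid_size) - 1) / grid_size
  vals <- nnts_density(grid, best$par)
  crv <- density_curve(vals, estimator = "trig_sum", bandwidth = best$k)
  crv$meta$order <- best$k
  crv$meta$coef <- best$par
  crv$meta$aic <- best$aic
  crv
}

# NNTS density from a real parameter vector p = (Re c_0, Im c_0, ...).
# Normalization is built in, so any p (not all zero) is a valid density.
nnts_density <- function(theta, p) {
  cre <- p[seq(1, length(p), by = 2)]
  cim <- p[seq(2, length(p), by = 2)]
  ks <- seq_along(cre) - 1
  re <- cos(outer(theta, ks)) %*% cre - sin(outer(theta, ks)) %*% cim
  im <- sin(outer(theta, ks)) %*% cre + cos(outer(theta, ks)) %*% cim
  as.numeric(re^2 + im^2) / (2 * pi * sum(cre^2 + cim^2))
}

nnts_ml <- function(x, k, n_starts = 2L) {
  if (k == 0L)
    return(list(par = c(1, 0), loglik = -length(x) * log(2 * pi)))
  n <- length(x)
  E <- exp(1i * outer(x, 0:k))             # n x (k+1) Fourier basis at data
  negll <- function(p) {
    cc <- complex(real = p[seq(1, 2 * k + 2, 2)],
                  imaginary = p[seq(2, 2 * k + 2, 2)])
    g2 <- Mod(E %*% cc)^2
    S <- sum(Mod(cc)^2)
    if (S <= 0 || any(g2 <= 0)) return(.Machine$double.xmax / 2)
    -(sum(log(g2)) - n * log(2 * pi * S))
  }
  negll_grad <- function(p) {
    cc <- complex(real = p[seq(1, 2 * k + 2, 2)],
                  imaginary = p[seq(2, 2 * k + 2, 2)])
    g <- drop(E %*% cc)
    g2 <- Mod(g)^2
    S <- sum(Mod(cc)^2)
    if (S <= 0 || any(g2 <= 0)) return(rep(0, length(p)))
    z <- colSums((Conj(g) / g2) * E)  # sum_j conj(g_j) E_jk / |g_j|^2
    gre <- 2 * Re(z) - 2 * n * Re(cc) / S
    gim <- -2 * Im(z) - 2 * n * Im(cc) / S
    out <- numeric(2 * k + 2)
    out[seq(1, 2 * k + 2, 2)] <- -gre
    out[seq(2, 2 * k + 2, 2)] <- -gim
    out
  }
  # moment-informed start: c_0 real, higher coefficients from empirical
  # trigonometric moments (halved so the squared modulus stays tame)
  starts <- list()
  tm <- vapply(1:k, function(j)
    c(mean(cos(j * x)), mean(sin(j * x))), numeric(2))
  p0 <- c(1, 0, as.numeric(tm) / 2)
  starts[[1]] <- p0
  for (s in seq_len(n_starts)) {
    # deterministic restarts from a local LCG so the caller's RNG stream
    # is never touched
    starts[[s + 1]] <- c(1, 0, 0.6 * lcg_unif(2 * k, seed = 97 * k + s) - 0.3)
  }
  best <- NULL
  for (p in starts) {
    opt <- tryCatch(
      stats::optim(p, negll, negll_grad, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop_estimation("NNTS optimization failed at order %d", k)
  list(par = best$par, loglik = -best$value)
}

# Count local maxima of a periodic curve (wrap-around aware). A maximum
# only counts if it rises above both neighbouring local minima by at least
# `prominence` times the global maximum, so epsilon-sized wiggles that
# maximum-likelihood trigonometric fits can leave in a trough are ignored
# when a prominence is requested.
count_modes <- function(curve, prominence = 0, tol = 1e-10) {
  v <- curve$values
  m <- length(v)
  up <- v - v[c(m, 1:(m - 1))]
  is_max <- up > tol & (v[c(2:m, 1)] - v) < -tol
  is_min <- up < -tol & (v[c(2:m, 1)] - v) > tol
  maxima <- which(is_max)
  if (prominence <= 0 || length(maxima) < 2L) return(length(maxima))
  minima <- which(is_min)
  thresh <- prominence * max(v)
  count <- 0L
  for (i in maxima) {
    lower <- minima[minima < i]
    left <- if (length(lower)) max(lower) else max(minima)   # wrap
    higher <- minima[minima > i]
    right <- if (length(higher)) min(higher) else min(minima)
    if (v[i] - max(v[left], v[right]) >= thresh) count <- count + 1L
  }
  count
}

# Minimal linear congruential generator (Numerical Recipes constants),
# for deterministic optimizer restarts independent of R's RNG.
lcg_unif <- function(n, seed) {
  state <- as.double(seed %% 2^32)
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (1664525 * state + 1013904223) %% 2^32
    out[i] <- state / 2^32
  }
  out
}

check_sample <- function(sample, min_n = 1L) {
  if (!inherits(sample, "circular_sample"))
    stop_input("expected a circular_sample object")
  if (sample$n < min_n)
    stop_estimation("need at least %d observations, got %d", min_n, sample$n)
  invisible(sample)
}
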