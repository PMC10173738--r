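#' Fidelity statistics of a centering trajectory
#'
#' Computes the reliability `delta = |mean(x)|` (mean longitudinal
#' displacement of the nucleus from the cell center; the absolute value
#' implements the convention that cells are oriented so the time-averaged
#' displacement falls in the first quadrant), the robustness
#' `sigma_x = sd(x)`, and `sigma_y = sd(y)`, over the post-burn-in segment.
#' Standard errors come from a moving-block bootstrap with block size equal to
#' the autocorrelation time of the series.
#'
#' @param traj A `centering_trajectory` (from [simulate_centering()] or
#'   [gen_spb_trajectory()]), or any data frame with `time`, `x` and
#'   optionally `y` columns.
#' @param burn_in Seconds discarded from the start; defaults to the
#'   trajectory's config burn-in, else 0.
#' @param n_boot Bootstrap replicates for the standard errors (0 skips them).
#' @return An object of class `centering_summary`: `delta`, `sigma_x`,
#'   `sigma_y`, `se_delta`, `se_sigma_x`, `autocorr_time` (seconds),
#'   `n_samples`.
#' @export
summarize_centering <- function(traj, burn_in = NULL, n_boot = 200) {
  stopifnot(is.data.frame(traj), all(c("time", "x") %in% names(traj)))
  if (is.null(burn_in)) {
    cfg <- attr(traj, "config")
    burn_in <- if (!is.null(cfg)) cfg$burn_in else 0
  }
  keep <- traj$time >= burn_in
  if (!any(keep)) stop("trajectory shorter than burn-in")
  x <- traj$x[keep]
  y <- if ("y" %in% names(traj)) traj$y[keep] else rep(0, length(x))
  dt <- if (length(traj$time) > 1) diff(traj$time[1:2]) else 1

  delta <- abs(mean(x))
  sigma_x <- if (length(x) > 1) sd(x) else 0
  sigma_y <- if (length(y) > 1) sd(y) else 0
  act <- autocorrelation_time(x, dt = dt)
  block <- max(1L, min(as.integer(round(act / dt)), length(x)))

  se_delta <- se_sigma_x <- NA_real_
  if (n_boot > 0) {
    se_delta <- moving_block_bootstrap_se(x, function(z) abs(mean(z)),
                                          block = block, n_boot = n_boot)
    se_sigma_x <- moving_block_bootstrap_se(x, sd, block = block,
                                            n_boot = n_boot)
  }
  structure(list(delta = delta, sigma_x = sigma_x, sigma_y = sigma_y,
                 se_delta = se_delta, se_sigma_x = se_sigma_x,
                 autocorr_time = act, n_samples = length(x)),
            class = "centering_summary")
}

#' @export
print.centering_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "centering summary (%d samples)\n",
    "  delta   = %.4f um (SE %.4f)\n",
    "  sigma_x = %.4f um (SE %.4f)\n",
    "  sigma_y = %.4f um\n",
    "  autocorrelation time = %.1f s\n"),
    x$n_samples, x$delta, x$se_delta, x$sigma_x, x$se_sigma_x,
    x$sigma_y, x$autocorr_time))
  invisible(x)
}

#' Autocorrelation time of a series
#'
#' First lag at which the empirical autocorrelation drops below `1/e`,
#' converted to seconds through the sampling interval; at least one sample.
#' A constant series is fully correlated and returns the record length.
#'
#' @param series Numeric vector (length >= 10).
#' @param dt Sampling interval in seconds.
#' @return Autocorrelation time in seconds.
#' @export
autocorrelation_time <- function(series, dt = 1) {
  n <- length(series)
  stopifnot(n >= 10)
  if (sd(series) == 0) return(n * dt)
  r <- as.numeric(acf(series, lag.max = n - 1, plot = FALSE,
                      demean = TRUE)$acf)[-1]
  hit <- which(r < exp(-1))
  lag <- if (length(hit)) hit[1] else n
  max(1L, lag) * dt
}

#' Moving-block bootstrap standard error
#'
#' Resamples overlapping blocks of `block` consecutive samples with
#' replacement, concatenates them to the original length, recomputes the
#' statistic, and returns the standard deviation across replicates. With a
#' block size equal to the autocorrelation time this gives honest standard
#' errors for autocorrelated trajectories.
#'
#' @param series Numeric vector.
#' @param statistic Function of a numeric vector returning a scalar.
#' @param block Block size in samples (`1 <= block <= length(series)`).
#' @param n_boot Number of bootstrap replicates (>= 100 recommended).
#' @return Standard error (scalar).
#' @export
moving_block_bootstrap_se <- function(series, statistic, block,
                                      n_boot = 200) {
  n <- length(series)
  stopifnot(block >= 1)
  if (block > n) stop("block size exceeds series length")
  nblocks <- ceiling(n / block)
  starts_max <- n - block + 1L
  reps <- vapply(seq_len(n_boot), function(b) {
    s <- sample.int(starts_max, nblocks, replace = TRUE)
    idx <- rep(s, each = block) + rep.int(seq_len(block) - 1L, nblocks)
    statistic(series[idx[seq_len(n)]])
  }, numeric(1))
  sd(reps)
}

#' Failure coefficient of nucleus localization
#'
#' Approximates the stationary position distribution as a Gaussian with mean
#' `delta` and standard deviation `sigma_x` and returns the probability mass
#' beyond the failure threshold `xf`:
#' `Phi = A(>xf)/A` (upper tail, the default, matching the orientation
#' convention `delta >= 0`), or the two-sided mass beyond `|x| = xf`.
#'
#' @param delta Mean displacement, micrometers (>= 0 by convention).
#' @param sigma_x Standard deviation, micrometers (>= 0).
#' @param xf Failure threshold, micrometers.
#' @param two_sided Also count the opposite tail?
#' @return Probability in `[0, 1]`; at `sigma_x = 0` an indicator of
#'   `delta > xf`.
#' @export
failure_coefficient <- function(delta, sigma_x, xf, two_sided = FALSE) {
  stopifnot(all(sigma_x >= 0, na.rm = TRUE))
  upper <- ifelse(sigma_x == 0, as.numeric(delta > xf),
                  pnorm(xf, mean = delta, sd = sigma_x, lower.tail = FALSE))
  if (!two_sided) return(upper)
  lower <- ifelse(sigma_x == 0, as.numeric(delta < -xf),
                  pnorm(-xf, mean = delta, sd = sigma_x))
  upper + lower
}

#' Failure threshold from reference septum offsets
#'
#' The threshold `xf` beyond which septum localization counts as a failure is
#' defined as the `(1 - quantile)` quantile of the absolute reference offsets
#' — by default the extreme-5% events of the wild-type population.
#'
#' @param offsets Septum offsets from the cell center, micrometers (sign
#'   ignored).
#' @param quantile Extreme fraction (default 0.05).
#' @return Threshold in micrometers.
#' @export
failure_threshold <- function(offsets, quantile = 0.05) {
  stopifnot(length(offsets) > 0, quantile > 0, quantile < 1)
  unname(stats::quantile(abs(offsets), probs = 1 - quantile))
}

#' Fraction of failed septum localizations
#'
#' Fraction of cells whose absolute septum offset exceeds `xf`, with a
#' case-resampling bootstrap standard error.
#'
#' @param offsets Septum offsets, micrometers.
#' @param xf Failure threshold, micrometers.
#' @param n_boot Bootstrap replicas (default 100).
#' @return List with `sf` (fraction) and `se`.
#' @export
septum_failure_fraction <- function(offsets, xf, n_boot = 100) {
  stopifnot(length(offsets) > 0)
  fail <- abs(offsets) > xf
  sf <- mean(fail)
  reps <- vapply(seq_len(n_boot), function(b)
    mean(fail[sample.int(length(fail), replace = TRUE)]), numeric(1))
  list(sf = sf, se = sd(reps))
}

#' Z scores of mutant features against the wild type
#'
#' Per shared numeric feature: `(mean(mutant) - mean(wt)) / sd(wt)`. Features
#' with zero wild-type standard deviation are flagged ill-defined (score
#' `NA`).
#'
#' @param mutant,wt Data frames of per-cell features with shared column names.
#' @return Data frame with columns `feature`, `z`, `ill_defined`.
#' @export
z_score_features <- function(mutant, wt) {
  shared <- intersect(names(mutant), names(wt))
  shared <- shared[vapply(shared, function(f)
    is.numeric(mutant[[f]]) && is.numeric(wt[[f]]), logical(1))]
  if (length(shared) == 0) stop("no shared numeric features")
  res <- lapply(shared, function(f) {
    s <- sd(wt[[f]])
    if (!is.finite(s) || s == 0)
      data.frame(feature = f, z = NA_real_, ill_defined = TRUE)
    else
      data.frame(feature = f, z = (mean(mutant[[f]]) - mean(wt[[f]])) / s,
                 ill_defined = FALSE)
  })
  do.call(rbind, res)
}

#' Convolve centroid positions with the axis projection of a sphere
#'
#' The spindle pole body sits on the nuclear envelope, so its longitudinal
#' position is the nucleus centroid position plus the axis projection of a
#' point on a sphere of radius `radius`. By Archimedes' hat-box theorem that
#' projection is uniform on `[-radius, radius]`, so the SPB density is the
#' empirical centroid distribution convolved with that uniform density:
#' `h(g) = (F(g + radius) - F(g - radius)) / (2 radius)` with `F` the
#' empirical CDF.
#'
#' @param centroid_x Centroid position samples, micrometers.
#' @param radius Sphere (nucleus) radius, micrometers (> 0).
#' @param n_grid Number of grid points for the returned density.
#' @return List with `grid`, `density`, and `cdf` (a function; the convolved
#'   distribution function, exact).
#' @export
sphere_projection_convolve <- function(centroid_x, radius, n_grid = 512) {
  stopifnot(radius > 0, length(centroid_x) > 0)
  Fhat <- ecdf(centroid_x)
  grid <- seq(min(centroid_x) - radius, max(centroid_x) + radius,
              length.out = n_grid)
  dens <- (Fhat(grid + radius) - Fhat(grid - radius)) / (2 * radius)
  cdf <- function(q) {
    vapply(q, function(g)
      mean(pmin(pmax((g - centroid_x + radius) / (2 * radius), 0), 1)),
      numeric(1))
  }
  list(grid = grid, density = dens, cdf = cdf)
}

#' Windowed stationarity check
#'
#' Splits the series into `n_windows` equal windows, computes per-window means
#' and variances, regresses each against the window index, and bootstrap
#' intervals for the slopes (pair resampling). The series is flagged
#' non-stationary when either interval excludes zero.
#'
#' @param series Numeric vector.
#' @param n_windows Number of windows (>= 3).
#' @param n_boot Bootstrap replicates for the slope intervals.
#' @param level Interval coverage.
#' @return List with `window_means`, `window_vars`, `slope_mean`, `ci_mean`,
#'   `slope_var`, `ci_var`, `stationary` (logical).
#' @export
stationarity_check <- function(series, n_windows = 6, n_boot = 500,
                               level = 0.95) {
  stopifnot(n_windows >= 3, length(series) >= 2 * n_windows)
  idx <- cut(seq_along(series), n_windows, labels = FALSE)
  wmean <- tapply(series, idx, mean)
  wvar <- tapply(series, idx, var)
  w <- seq_len(n_windows)
  slope <- function(yv, ii) coef(lm(yv[ii] ~ w[ii]))[2]
  boot_ci <- function(yv) {
    reps <- vapply(seq_len(n_boot), function(b) {
      ii <- sample.int(n_windows, replace = TRUE)
      if (length(unique(w[ii])) < 2) return(NA_real_)
      slope(yv, ii)
    }, numeric(1))
    stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                    na.rm = TRUE)
  }
  ci_m <- boot_ci(as.numeric(wmean))
  ci_v <- boot_ci(as.numeric(wvar))
  list(window_means = as.numeric(wmean), window_vars = as.numeric(wvar),
       slope_mean = unname(slope(as.numeric(wmean), w)),
       ci_mean = unname(ci_m),
       slope_var = unname(slope(as.numeric(wvar), w)),
       ci_var = unname(ci_v),
       stationary = (ci_m[1] <= 0 && ci_m[2] >= 0) &&
         (ci_v[1] <= 0 && ci_v[2] >= 0))
}
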