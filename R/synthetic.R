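#' Synthetic catastrophe-time datasets
#'
#' Draws gamma-distributed catastrophe times observed through a min/max
#' truncation window (rejection sampling until `n` events are accepted),
#' emulating the windowed observation of catastrophe events in imaging data.
#' The default calibration is the Mal3 condition: `shape = 3.6`,
#' `scale = 35` s, window `(10, 400)` s.
#'
#' @param shape,scale Gamma parameters (step parameter and timescale in s).
#' @param window Observation window in seconds, inside `(0, Inf)`.
#' @param n Number of accepted events.
#' @param seed Integer seed.
#' @return A [catastrophe_dataset()].
#' @export
gen_catastrophe_times <- function(shape = 3.6, scale = 35,
                                  window = c(10, 400), n = 200, seed = 1) {
  stopifnot(n >= 1, length(window) == 2L, window[1] >= 0,
            window[1] < window[2])
  acc <- pgamma(window[2], shape, scale = scale) -
    pgamma(window[1], shape, scale = scale)
  if (acc < 1e-3)
    stop("window acceptance probability below 1e-3; widen the window")
  times <- with_seed_(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- rgamma(ceiling((n - length(out)) / acc * 1.2) + 16,
                     shape = shape, scale = scale)
      out <- c(out, draw[draw >= window[1] & draw <= window[2]])
    }
    out[seq_len(n)]
  })
  catastrophe_dataset(times, window = window)
}

#' Synthetic stationary SPB trajectory
#'
#' First-order autoregressive surrogate for a stationary centering
#' trajectory: longitudinal position with stationary mean `mean_offset`,
#' stationary standard deviation `sd`, and autocorrelation time `ac_time`
#' (`x`), plus an independent zero-mean transverse component (`y`). This is
#' the simplest stationary autocorrelated process and exists so that the
#' statistics layer can be validated independently of the mechanistic
#' simulator.
#'
#' @param mean_offset Stationary mean of `x`, micrometers.
#' @param sd Stationary standard deviation, micrometers (>= 0).
#' @param ac_time Autocorrelation time in seconds (>= dt).
#' @param dt Sampling interval, seconds.
#' @param duration Record length, seconds.
#' @param seed Integer seed.
#' @return A `centering_trajectory` data frame (`time`, `x`, `y`).
#' @export
gen_spb_trajectory <- function(mean_offset = 0.3, sd = 0.3, ac_time = 60,
                               dt = 1, duration = 7200, seed = 1) {
  stopifnot(sd >= 0, ac_time >= dt, dt > 0, duration > dt)
  nt <- floor(duration / dt) + 1
  phi <- exp(-dt / ac_time)
  sd_inn <- sd * sqrt(1 - phi^2)
  sim_ar1 <- function(mu) {
    x <- numeric(nt)
    x[1] <- rnorm(1, 0, sd)
    if (nt > 1) {
      inn <- rnorm(nt - 1, 0, sd_inn)
      x[-1] <- as.numeric(stats::filter(inn, phi, method = "recursive",
                                        init = x[1]))
    }
    mu + x
  }
  traj <- with_seed_(seed, data.frame(
    time = seq(0, by = dt, length.out = nt),
    x = sim_ar1(mean_offset),
    y = sim_ar1(0)))
  class(traj) <- c("centering_trajectory", "data.frame")
  traj
}

#' Synthetic septum offsets
#'
#' Septum position error as the absolute value of a Gaussian whose variance
#' combines the SPB positional spread with an independent placement noise:
#' `|N(delta, sqrt(sigma^2 + placement_noise^2))|`.
#'
#' @param delta Mean SPB displacement, micrometers.
#' @param sigma SPB positional standard deviation, micrometers (>= 0).
#' @param placement_noise Septum placement noise, micrometers (>= 0).
#' @param n Number of cells.
#' @param seed Integer seed.
#' @return Numeric vector of unsigned offsets, micrometers.
#' @export
gen_septum_offsets <- function(delta = 0.1, sigma = 0.3,
                               placement_noise = 0.3, n = 200, seed = 1) {
  stopifnot(sigma >= 0, placement_noise >= 0, n >= 1)
  s <- sqrt(sigma^2 + placement_noise^2)
  with_seed_(seed, abs(rnorm(n, mean = delta, sd = s)))
}

#' Synthetic cell-length population
#'
#' Truncated-normal sample of division-onset cell lengths, used to drive
#' per-replicate geometry when emulating natural cell-length variation
#' (wild-type-like default: mean 14 um).
#'
#' @param mean Mean cell length, micrometers.
#' @param sd Standard deviation, micrometers (>= 0).
#' @param bounds Length-2 truncation bounds, micrometers.
#' @param n Number of cells.
#' @param seed Integer seed.
#' @return Numeric vector of cell lengths (`2L`), micrometers.
#' @export
gen_cell_lengths <- function(mean = 14, sd = 1, bounds = c(10, 18), n = 100,
                             seed = 1) {
  stopifnot(length(bounds) == 2L, bounds[1] > 0, bounds[1] < bounds[2],
            sd >= 0, n >= 1)
  if (sd == 0) return(rep(mean, n))
  lo <- pnorm(bounds[1], mean, sd)
  hi <- pnorm(bounds[2], mean, sd)
  with_seed_(seed, qnorm(lo + runif(n) * (hi - lo), mean, sd))
}
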