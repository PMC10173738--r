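#' Gamma model of microtubule catastrophe times
#'
#' Catastrophe times of growing microtubules are modeled as gamma distributed,
#' with a step parameter `N` (interpreted as the effective number of hidden
#' molecular steps preceding catastrophe) and a timescale `T` in seconds. At
#' `N = 1` the model reduces to the memoryless exponential catastrophe of
#' classical dynamic-instability descriptions. `tau0` is the mean catastrophe
#' time in the stalled limit (growth velocity under load going to zero); it
#' anchors the force-dependent shortening of catastrophe times, see
#' [rescale_catastrophe_time()].
#'
#' @param step_parameter Dimensionless shape `N` (> 0, non-integer allowed).
#' @param timescale Timescale `T` in seconds (> 0).
#' @param tau0 Stall-limit mean catastrophe time in seconds; must lie below the
#'   unloaded mean `N * T` so that load shortens rather than lengthens
#'   catastrophe.
#' @return An object of class `catastrophe_model`.
#' @examples
#' m <- catastrophe_model(3.6, 35)
#' catastrophe_density(35, m)
#' @export
catastrophe_model <- function(step_parameter = 3.6, timescale = 35, tau0 = 25) {
  stopifnot(is.numeric(step_parameter), length(step_parameter) == 1L,
            is.finite(step_parameter), step_parameter > 0,
            is.numeric(timescale), length(timescale) == 1L,
            is.finite(timescale), timescale > 0,
            is.numeric(tau0), length(tau0) == 1L, is.finite(tau0), tau0 >= 0)
  if (tau0 >= step_parameter * timescale)
    stop("tau0 must be smaller than the unloaded mean catastrophe time N * T")
  structure(list(step_parameter = step_parameter, timescale = timescale,
                 tau0 = tau0),
            class = "catastrophe_model")
}

#' @export
print.catastrophe_model <- function(x, ...) {
  cat(sprintf("gamma catastrophe model: N = %g, T = %g s (mean %g s), tau0 = %g s\n",
              x$step_parameter, x$timescale,
              x$step_parameter * x$timescale, x$tau0))
  invisible(x)
}

#' Catastrophe-time probability density
#'
#' Gamma density `t^(N-1) exp(-t/T) / (T^N Gamma(N))` of the catastrophe time.
#'
#' @param t Times in seconds (finite, >= 0).
#' @param model A [catastrophe_model()].
#' @param log Return the log density?
#' @return Density values, per second.
#' @export
catastrophe_density <- function(t, model, log = FALSE) {
  stopifnot(inherits(model, "catastrophe_model"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("catastrophe times must be finite and non-negative")
  dgamma(t, shape = model$step_parameter, scale = model$timescale, log = log)
}

#' Window-truncated catastrophe-time density
#'
#' Gamma catastrophe density renormalized to an observation window
#' `[lower, upper]` and zero outside it. This is the distribution against which
#' experimentally observable catastrophe events should be compared, since
#' imaging only captures events inside a finite length/time window.
#'
#' @inheritParams catastrophe_density
#' @param lower,upper Window bounds in seconds, `0 <= lower < upper`.
#' @export
catastrophe_density_truncated <- function(t, model, lower = 0, upper = Inf) {
  stopifnot(inherits(model, "catastrophe_model"),
            length(lower) == 1L, length(upper) == 1L,
            lower >= 0, lower < upper)
  mass <- pgamma(upper, model$step_parameter, scale = model$timescale) -
    pgamma(lower, model$step_parameter, scale = model$timescale)
  if (!is.finite(mass) || mass <= 1e-12)
    stop("degenerate support: the window [", lower, ", ", upper,
         "] carries no probability mass under the model")
  out <- catastrophe_density(t, model) / mass
  out[t < lower | t > upper] <- 0
  out
}

#' Truncated catastrophe-time CDF
#'
#' @inheritParams catastrophe_density_truncated
#' @param q Quantiles in seconds.
#' @keywords internal
#' @export
catastrophe_cdf_truncated <- function(q, model, lower = 0, upper = Inf) {
  stopifnot(inherits(model, "catastrophe_model"), lower >= 0, lower < upper)
  pl <- pgamma(lower, model$step_parameter, scale = model$timescale)
  pu <- pgamma(upper, model$step_parameter, scale = model$timescale)
  if (pu - pl <= 1e-12) stop("degenerate support")
  p <- (pgamma(pmin(pmax(q, lower), upper),
               model$step_parameter, scale = model$timescale) - pl) / (pu - pl)
  p[q < lower] <- 0
  p[q > upper] <- 1
  p
}

#' Mean remaining catastrophe time at a given age (inverse hazard)
#'
#' Returns `S(age) / p(age)`, the survival function over the density of the
#' catastrophe-time distribution. This is the per-age timescale entering the
#' per-step catastrophe probability `1 - exp(-dt / inverse_hazard(age))`. For
#' the exponential limit (`N = 1`) it is constant and equal to `T`
#' (memorylessness); for `N > 1` it diverges at age zero because the gamma
#' hazard vanishes at the origin (`Inf` is returned, which yields a zero
#' catastrophe probability).
#'
#' Computed in log space so that large ages never produce a 0/0.
#'
#' @param age Age of the current growth excursion, seconds (>= 0).
#' @param model A [catastrophe_model()].
#' @return Timescale in seconds, strictly positive (possibly `Inf`).
#' @export
inverse_hazard <- function(age, model) {
  stopifnot(inherits(model, "catastrophe_model"))
  if (any(!is.finite(age)) || any(age < 0))
    stop("age must be finite and non-negative")
  log_s <- pgamma(age, model$step_parameter, scale = model$timescale,
                  lower.tail = FALSE, log.p = TRUE)
  log_p <- dgamma(age, shape = model$step_parameter, scale = model$timescale,
                  log = TRUE)
  exp(log_s - log_p)
}

#' Per-step catastrophe probability
#'
#' Probability `1 - exp(-load_factor * dt / inverse_hazard(age))` that a
#' microtubule of the given age undergoes catastrophe within the next `dt`
#' seconds. `load_factor = 1` is free growth; during wall contact the clock
#' runs faster (`load_factor > 1`) because pushing shortens catastrophe times.
#'
#' @param age Age of the growth excursion, seconds.
#' @param dt Time step, seconds (> 0).
#' @param model A [catastrophe_model()].
#' @param load_factor Dimensionless acceleration of the catastrophe clock
#'   (>= 1).
#' @return Probability in `[0, 1]`, non-decreasing in `dt` and `load_factor`.
#' @export
catastrophe_probability <- function(age, dt, model, load_factor = 1) {
  stopifnot(all(dt > 0), all(load_factor >= 1))
  p <- 1 - exp(-load_factor * dt / inverse_hazard(age, model))
  pmin(pmax(p, 0), 1)
}

#' Force-dependent shortening of a catastrophe time
#'
#' Under contact with the cell tip the growth velocity drops from `V+` to
#' `V+f`, and the catastrophe time shortens according to
#' `tau(V+f) = tau0 + (tau(V+) - tau0) * V+f / V+`. Values drawn below `tau0`
#' (possible in the distribution tail) are clamped to `tau0` with a warning.
#'
#' @param tau_free Catastrophe time under free growth, seconds.
#' @param model A [catastrophe_model()] supplying `tau0`.
#' @param v_ratio Velocity ratio `V+f / V+` in `(0, 1]`.
#' @return Rescaled catastrophe time, between `tau0` and `tau_free`.
#' @export
rescale_catastrophe_time <- function(tau_free, model, v_ratio) {
  stopifnot(inherits(model, "catastrophe_model"),
            all(v_ratio > 0), all(v_ratio <= 1))
  if (any(tau_free <= model$tau0)) {
    warning("catastrophe time(s) at or below tau0 clamped to tau0")
    tau_free <- pmax(tau_free, model$tau0)
  }
  model$tau0 + (tau_free - model$tau0) * v_ratio
}

# Quiet variant used inside integrators where small drawn values are routine.
rescale_quiet_ <- function(tau_free, tau0, v_ratio) {
  tau0 + (pmax(tau_free, tau0) - tau0) * v_ratio
}

#' One microtubule state
#'
#' Container for a single filament: anchor angle `psi` (fixed in the nucleus
#' frame, spindle pole body at `psi = 0`), axis angle `theta` relative to the
#' cell long axis (world frame, resampled at every rescue), current length,
#' growth phase, the drawn catastrophe time and the clock progressing toward
#' it, the side the filament grows toward, and the buckling reference length
#' `l0` frozen at the first wall contact of the current growth excursion.
#'
#' @param anchor_angle Radians, nucleus frame.
#' @param axis_angle Radians in `(-pi/2, pi/2)`, world frame.
#' @param length Micrometers (>= 0).
#' @param phase `"growing"` or `"shrinking"`.
#' @param drawn_tau Catastrophe time drawn at the last rescue, seconds.
#' @param cat_clock Progress toward `drawn_tau`, seconds.
#' @param side `"right"` or `"left"`.
#' @param buckling_ref_length Micrometers, `NA` until first wall contact.
#' @export
microtubule_state <- function(anchor_angle = 0, axis_angle = 0, length = 0,
                              phase = c("growing", "shrinking"),
                              drawn_tau = NA_real_, cat_clock = 0,
                              side = c("right", "left"),
                              buckling_ref_length = NA_real_) {
  phase <- match.arg(phase)
  side <- match.arg(side)
  stopifnot(length >= 0, cat_clock >= 0,
            is.na(buckling_ref_length) || buckling_ref_length > 0)
  structure(list(anchor_angle = anchor_angle, axis_angle = axis_angle,
                 length = length, phase = phase, drawn_tau = drawn_tau,
                 cat_clock = cat_clock, side = side,
                 buckling_ref_length = buckling_ref_length),
            class = "microtubule_state")
}

#' Advance one microtubule by one time step
#'
#' Reference single-filament update. Growing filaments elongate at the free
#' velocity (or the contact velocity while touching the wall) and advance a
#' catastrophe clock toward the drawn catastrophe time; during contact the
#' clock runs faster by the factor `drawn_tau / rescaled(drawn_tau)`, so the
#' realized catastrophe time equals the force-rescaled one. Shrinking
#' filaments depolymerize; rescue is instantaneous at zero length, with a
#' fresh catastrophe time drawn from the gamma model and a fresh axis angle.
#'
#' The alternative `"hazard"` mode replaces the drawn-time clock by the
#' age-dependent per-step catastrophe probability
#' [catastrophe_probability()]; both modes produce the same free-growth
#' catastrophe-age distribution.
#'
#' @param mt A [microtubule_state()].
#' @param dt Time step, seconds.
#' @param in_contact Is the tip pressing on the cell boundary?
#' @param kinetics A [kinetic_params()].
#' @param mode Catastrophe bookkeeping, `"clock"` (default) or `"hazard"`.
#' @param theta_spread If non-`NULL`, scale (radians) used to resample the
#'   axis angle at rescue; otherwise the angle is kept.
#' @return The updated [microtubule_state()].
#' @export
step_microtubule <- function(mt, dt, in_contact, kinetics,
                             mode = c("clock", "hazard"),
                             theta_spread = NULL) {
  stopifnot(inherits(mt, "microtubule_state"),
            inherits(kinetics, "kinetic_params"), dt > 0)
  mode <- match.arg(mode)
  model <- kinetics$catastrophe
  v_ratio <- kinetics$v_contact / kinetics$v_grow

  if (mt$phase == "growing") {
    if (is.na(mt$drawn_tau) && mode == "clock")
      mt$drawn_tau <- rgamma(1, shape = model$step_parameter,
                             scale = model$timescale)
    if (in_contact) {
      mt$length <- mt$length + kinetics$v_contact * dt
      load <- if (mode == "clock") {
        max(1, mt$drawn_tau /
              rescale_quiet_(mt$drawn_tau, model$tau0, v_ratio))
      } else {
        mean_free <- model$step_parameter * model$timescale
        max(1, mean_free / rescale_quiet_(mean_free, model$tau0, v_ratio))
      }
    } else {
      mt$length <- mt$length + kinetics$v_grow * dt
      load <- 1
    }
    if (mode == "clock") {
      mt$cat_clock <- mt$cat_clock + load * dt
      if (mt$cat_clock >= mt$drawn_tau) mt$phase <- "shrinking"
    } else {
      age <- mt$cat_clock
      mt$cat_clock <- mt$cat_clock + dt
      if (runif(1) < catastrophe_probability(age, dt, model, load))
        mt$phase <- "shrinking"
    }
  } else {
    mt$length <- mt$length - kinetics$v_shrink * dt
    if (mt$length <= 0) {
      mt$length <- 0
      mt$phase <- "growing"
      mt$cat_clock <- 0
      mt$drawn_tau <- rgamma(1, shape = model$step_parameter,
                             scale = model$timescale)
      mt$buckling_ref_length <- NA_real_
      if (!is.null(theta_spread))
        mt$axis_angle <- sample_axis_angle(theta_spread)
    }
  }
  mt
}
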