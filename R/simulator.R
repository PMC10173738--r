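#' Simulation configuration
#'
#' All tunable inputs of the centering simulation: cell geometry, microtubule
#' kinetics, drag environment, microtubule census per side, the left/right
#' orientation-correlation mode, the axis-angle spread, and the integration
#' controls. Defaults are the calibrated wild-type-like condition: a 14 um
#' cell, 18 microtubules (9 per side), gamma catastrophe model `N = 3.6`,
#' `T = 35` s with `tau0 = 25` s, growth velocity 0.05 um/s (3 um/min),
#' contact velocity 0.017 um/s, shrinkage 0.15 um/s, stall force 5 pN, and
#' flexural rigidity 1.25 pN um^2.
#'
#' @param geometry A [cell_geometry()].
#' @param kinetics A [kinetic_params()].
#' @param drag A [drag_environment()].
#' @param n_right,n_left Number of microtubules growing toward the right/left
#'   cell tip (equal by default).
#' @param lr_mode `"independent"` (each rescue draws a fresh axis angle) or
#'   `"correlated"` (each left filament mirrors the orientation and the drawn
#'   catastrophe time of its paired right filament).
#' @param theta_spread Scale of the zero-centered truncated-normal axis-angle
#'   distribution, radians.
#' @param duration Simulated time, seconds (default 7200 s, one fission-yeast
#'   generation).
#' @param dt Integration step, seconds.
#' @param burn_in Initial transient discarded by [summarize_centering()],
#'   seconds.
#' @param record_dt Output sampling interval, seconds.
#' @param seed Integer seed; every source of randomness derives from it.
#' @param catastrophe_mode `"clock"` (drawn catastrophe times, force-rescaled)
#'   or `"hazard"` (age-dependent per-step catastrophe probability).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(geometry = cell_geometry(),
                       kinetics = kinetic_params(),
                       drag = drag_environment(),
                       n_right = 9, n_left = 9,
                       lr_mode = c("independent", "correlated"),
                       theta_spread = 0.3,
                       duration = 7200, dt = 0.05, burn_in = 1800,
                       record_dt = 1, seed = 1L,
                       catastrophe_mode = c("clock", "hazard")) {
  lr_mode <- match.arg(lr_mode)
  catastrophe_mode <- match.arg(catastrophe_mode)
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(kinetics, "kinetic_params"),
            inherits(drag, "drag_environment"),
            n_right >= 1, n_left >= 1,
            theta_spread >= 0, dt > 0, duration > 0, burn_in < duration,
            record_dt >= dt)
  structure(list(geometry = geometry, kinetics = kinetics, drag = drag,
                 n_right = as.integer(n_right), n_left = as.integer(n_left),
                 lr_mode = lr_mode, theta_spread = theta_spread,
                 duration = duration, dt = dt, burn_in = burn_in,
                 record_dt = record_dt, seed = as.integer(seed),
                 catastrophe_mode = catastrophe_mode),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "centering simulation config\n",
    "  cell: 2L = %g um, 2R = %g um; nucleus r = %g um\n",
    "  MTs: %d right + %d left, lr_mode = %s, theta spread = %g rad\n",
    "  kinetics: v+ = %g, v+f = %g, v- = %g um/s; fs = %g pN; kappa = %g pN um^2\n",
    "  catastrophe: N = %g, T = %g s, tau0 = %g s (%s mode)\n",
    "  run: %g s, dt = %g s, burn-in = %g s, seed = %d\n"),
    2 * x$geometry$half_length, 2 * x$geometry$half_width,
    x$drag$nucleus_radius, x$n_right, x$n_left, x$lr_mode, x$theta_spread,
    x$kinetics$v_grow, x$kinetics$v_contact, x$kinetics$v_shrink,
    x$kinetics$stall_force, x$kinetics$flexural_rigidity,
    x$kinetics$catastrophe$step_parameter, x$kinetics$catastrophe$timescale,
    x$kinetics$catastrophe$tau0, x$catastrophe_mode,
    x$duration, x$dt, x$burn_in, x$seed))
  invisible(x)
}

#' Draw a microtubule axis angle
#'
#' Axis angles are drawn from a zero-centered truncated normal distribution on
#' `(-pi/2, pi/2)` with scale `theta_spread` (a spread of zero gives perfectly
#' axis-aligned filaments). When a `partner_angle` is supplied (correlated
#' left/right mode) the partner's angle is reused: with the side convention
#' used here — a filament of side `s` grows along `(s cos(theta), sin(theta))`
#' — equal angles on paired left/right filaments are mirror images through the
#' cell midplane.
#'
#' @param theta_spread Scale in radians (>= 0).
#' @param n Number of draws.
#' @param partner_angle Optional partner angle to reuse (correlated mode).
#' @return Angles in radians.
#' @export
sample_axis_angle <- function(theta_spread, n = 1, partner_angle = NULL) {
  if (!is.null(partner_angle)) return(rep_len(partner_angle, n))
  stopifnot(theta_spread >= 0)
  if (theta_spread == 0) return(rep(0, n))
  lo <- pnorm(-pi / 2, 0, theta_spread)
  hi <- pnorm(pi / 2, 0, theta_spread)
  qnorm(lo + runif(n) * (hi - lo), 0, theta_spread)
}

#' Initialize the nucleus and microtubule population
#'
#' The number of nucleation sites (bundles) is the integer quotient of
#' `(n_right + n_left) / 4`, at least one. Anchor angles are drawn uniformly
#' on the circle; filaments are assigned to anchors uniformly at random; the
#' most-populated anchor is rotated to `psi = 0` and declared the spindle pole
#' body (ties break to the lowest anchor index, deterministically under a
#' fixed seed). All filaments start at zero length, growing, with a drawn
#' catastrophe time and an axis angle from the orientation distribution. The
#' nucleus starts at the left cell tip, `x = -(L - rnuc)`.
#'
#' Uses the current RNG stream; [simulate_centering()] seeds it from the
#' config.
#'
#' @param config A [sim_config()].
#' @return List with elements `nucleus` ([nucleus_state()]) and `mts` (a data
#'   frame of per-filament state in the layout the integrator consumes).
#' @export
initialize_sim <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ntot <- config$n_right + config$n_left
  nb <- ntot %/% 4L
  if (nb < 1L) {
    warning("fewer than 4 microtubules; bundle count clamped to 1")
    nb <- 1L
  }
  psi_anchor <- runif(nb, -pi, pi)
  assign <- sample.int(nb, ntot, replace = TRUE)
  counts <- tabulate(assign, nbins = nb)
  spb <- which.max(counts) # ties -> lowest index
  psi_anchor <- (psi_anchor - psi_anchor[spb] + pi) %% (2 * pi) - pi
  psi_anchor[spb] <- 0

  side <- c(rep(1L, config$n_right), rep(-1L, config$n_left))
  npair <- min(config$n_right, config$n_left)
  pair <- rep(-1L, ntot)

  theta <- sample_axis_angle(config$theta_spread, ntot)
  model <- config$kinetics$catastrophe
  tau <- rgamma(ntot, shape = model$step_parameter, scale = model$timescale)
  psi <- psi_anchor[assign]
  anchor_id <- assign

  if (config$lr_mode == "correlated" && npair > 0) {
    # Perfect correlation of the left and right force generators: each left
    # filament mirrors its right partner's orientation, drawn catastrophe
    # time, and nucleation-site placement (anchor reflected through the cell
    # midplane; mirror sites get their own anchor ids for the drag rule).
    li <- config$n_right + seq_len(npair)
    ri <- seq_len(npair)
    pair[li] <- ri - 1L # 0-based for the integrator
    theta[li] <- theta[ri]
    tau[li] <- tau[ri]
    psi[li] <- ((pi - psi[ri]) + pi) %% (2 * pi) - pi
    anchor_id[li] <- assign[ri] + nb
  }

  mts <- data.frame(
    psi = psi, theta = theta, length = 0,
    phase = 0L, drawn_tau = tau, cat_clock = 0,
    buckling_ref = NA_real_, side = side, anchor = anchor_id, pair = pair)
  nucleus <- nucleus_state(
    position = c(-(config$geometry$half_length - config$drag$nucleus_radius), 0),
    rotation = 0)
  list(nucleus = nucleus, mts = mts)
}

flat_core_config_ <- function(config) {
  list(half_length = config$geometry$half_length,
       half_width = config$geometry$half_width,
       nucleus_radius = config$drag$nucleus_radius,
       mt_radius = config$drag$mt_radius,
       viscosity = config$drag$viscosity,
       v_grow = config$kinetics$v_grow,
       v_contact = config$kinetics$v_contact,
       v_shrink = config$kinetics$v_shrink,
       stall_force = config$kinetics$stall_force,
       flexural_rigidity = config$kinetics$flexural_rigidity,
       shape = config$kinetics$catastrophe$step_parameter,
       timescale = config$kinetics$catastrophe$timescale,
       tau0 = config$kinetics$catastrophe$tau0,
       dt = config$dt, duration = config$duration,
       theta_spread = config$theta_spread,
       correlated = config$lr_mode == "correlated",
       cat_mode = if (config$catastrophe_mode == "clock") 0L else 1L,
       record_every = max(1L, as.integer(round(config$record_dt / config$dt))))
}

init_to_core_ <- function(init) {
  m <- init$mts
  list(psi = m$psi, theta = m$theta, length = m$length,
       phase = as.integer(m$phase), drawn_tau = m$drawn_tau,
       cat_clock = m$cat_clock, buckling_ref = m$buckling_ref,
       side = as.integer(m$side), anchor = as.integer(m$anchor),
       pair = as.integer(m$pair),
       x = init$nucleus$position[1], y = init$nucleus$position[2],
       omega = init$nucleus$rotation)
}

#' Simulate a nucleus-centering trajectory
#'
#' Runs the two-step Monte-Carlo integration (filament dynamics, then forward
#' Euler for the overdamped nucleus) for `config$duration` seconds and records
#' the nucleus centroid, rotation angle, and spindle pole body position on the
#' output grid. Thermal forces are neglected (their displacement scale is two
#' orders of magnitude below the active one). Fully reproducible: two runs
#' with the same config give bit-identical trajectories.
#'
#' @param config A [sim_config()].
#' @param init Optional initial state as returned by [initialize_sim()]; by
#'   default a fresh initialization drawn under the config seed.
#' @return A data frame of class `centering_trajectory` with columns `time`,
#'   `x`, `y`, `omega`, `spb_x`, `spb_y` and attributes `config`,
#'   `clamp_events` (count of hard-wall clamp interventions, zero in healthy
#'   runs) and `final_state`.
#' @examples
#' cfg <- sim_config(duration = 600, burn_in = 100, seed = 7)
#' traj <- simulate_centering(cfg)
#' summarize_centering(traj)
#' @export
simulate_centering <- function(config, init = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(init)) init <- initialize_sim(config)
  res <- .centering_core(flat_core_config_(config), init_to_core_(init))
  traj <- data.frame(time = res$time, x = res$x, y = res$y,
                     omega = res$omega, spb_x = res$spb_x, spb_y = res$spb_y)
  class(traj) <- c("centering_trajectory", "data.frame")
  attr(traj, "config") <- config
  attr(traj, "clamp_events") <- res$clamp_events
  attr(traj, "final_state") <- res$final
  traj
}

#' Sweep cell length and microtubule number
#'
#' Runs replicate simulations over a grid of cell lengths (`2L`, micrometers)
#' and total microtubule numbers (split equally between the two sides),
#' summarizes each replicate (reliability `delta`, robustness `sigma_x`), and
#' attaches the failure coefficient `Phi` computed against a fixed failure
#' threshold `xf`. When `xf` is not supplied it is derived from the
#' wild-type-like condition (`wt_length`): the replicate-pooled `delta` and
#' `sigma_x` of that condition parameterize a septum-offset surrogate sample
#' whose extreme-`quantile` absolute offset defines `xf`.
#'
#' Replicate seeds derive from the base config seed through a counter scheme,
#' so the grid is reproducible and any cell can be recomputed in isolation.
#'
#' @param base A [sim_config()]; geometry and census are overridden per cell.
#' @param cell_lengths Full cell lengths `2L` in micrometers.
#' @param mt_numbers Total microtubule numbers (even numbers split exactly;
#'   odd numbers put the extra filament on the right).
#' @param replicates Replicates per grid cell (>= 1).
#' @param xf Failure threshold in micrometers, or `NULL` to derive it.
#' @param wt_length Cell length used to anchor `xf`, micrometers.
#' @param placement_noise Septum placement noise of the surrogate, micrometers.
#' @param septum_n Surrogate sample size for the threshold.
#' @param quantile Extreme fraction defining failure (default 5%).
#' @return A data frame with columns `length`, `n_mt`, `replicate`, `seed`,
#'   `delta`, `sigma_x`, `sigma_y`, `phi` (attribute `xf` records the
#'   threshold; failed replicates are kept as `NA` rows and flagged in the
#'   `incomplete` attribute).
#' @export
sweep_centering <- function(base, cell_lengths, mt_numbers, replicates,
                            xf = NULL, wt_length = 14,
                            placement_noise = 0.3, septum_n = 2000,
                            quantile = 0.05) {
  stopifnot(inherits(base, "sim_config"), replicates >= 1)
  grid <- expand.grid(length = cell_lengths, n_mt = mt_numbers,
                      replicate = seq_len(replicates))
  rows <- vector("list", nrow(grid))
  counter <- 0L
  for (i in seq_len(nrow(grid))) {
    counter <- counter + 1L
    len <- grid$length[i]; nmt <- grid$n_mt[i]
    seed_i <- derive_seed_(base$seed, counter)
    cfg <- base
    cfg$geometry <- cell_geometry(half_length = len / 2,
                                  half_width = base$geometry$half_width)
    cfg$n_right <- as.integer(ceiling(nmt / 2))
    cfg$n_left <- as.integer(floor(nmt / 2))
    cfg$seed <- seed_i
    rows[[i]] <- tryCatch({
      traj <- simulate_centering(cfg)
      s <- summarize_centering(traj, burn_in = cfg$burn_in, n_boot = 0)
      data.frame(length = len, n_mt = nmt, replicate = grid$replicate[i],
                 seed = seed_i, delta = s$delta, sigma_x = s$sigma_x,
                 sigma_y = s$sigma_y)
    }, error = function(e) {
      warning(sprintf("replicate failed (length %g, %d MTs, rep %d): %s",
                      len, nmt, grid$replicate[i], conditionMessage(e)))
      data.frame(length = len, n_mt = nmt, replicate = grid$replicate[i],
                 seed = seed_i, delta = NA_real_, sigma_x = NA_real_,
                 sigma_y = NA_real_)
    })
  }
  out <- do.call(rbind, rows)

  if (is.null(xf)) {
    wt <- out[out$length == wt_length & !is.na(out$delta), ]
    if (nrow(wt) == 0)
      stop("cannot derive xf: no completed replicates at wt_length = ",
           wt_length, " um; pass xf explicitly")
    offs <- gen_septum_offsets(delta = mean(wt$delta),
                               sigma = mean(wt$sigma_x),
                               placement_noise = placement_noise,
                               n = septum_n,
                               seed = derive_seed_(base$seed, 999983L))
    xf <- failure_threshold(offs, quantile = quantile)
  }
  out$phi <- failure_coefficient(out$delta, out$sigma_x, xf)
  attr(out, "xf") <- xf
  attr(out, "incomplete") <- any(is.na(out$delta))
  out
}
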