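#' Cell geometry
#'
#' The cell is idealized as a two-dimensional rectangle of length `2L` along
#' the x axis and width `2R`, matching the imaging projection of a rod-shaped
#' fission yeast cell. Pushing forces arise only at the end walls `x = +/- L`.
#'
#' @param half_length Half cell length `L`, micrometers.
#' @param half_width Half cell width `R`, micrometers (`< half_length`).
#' @export
cell_geometry <- function(half_length = 7, half_width = 1.75) {
  stopifnot(half_length > half_width, half_width > 0)
  structure(list(half_length = half_length, half_width = half_width),
            class = "cell_geometry")
}

#' Viscous environment for drag calculations
#'
#' Cytoplasmic viscosity together with the radii entering the Stokes drag of
#' the nucleus and the slender-body drag of microtubules. Defaults are
#' calibration values (the internal unit system is micrometer-second-piconewton,
#' so viscosity is in pN s / um^2); all are overridable through the config.
#'
#' @param viscosity Cytoplasmic viscosity, pN s / um^2.
#' @param nucleus_radius Nucleus radius, micrometers.
#' @param mt_radius Microtubule radius, micrometers (slender-body limit
#'   assumes it is much smaller than typical filament lengths).
#' @export
drag_environment <- function(viscosity = 1, nucleus_radius = 1.4,
                             mt_radius = 0.0125) {
  stopifnot(viscosity > 0, nucleus_radius > 0, mt_radius > 0)
  structure(list(viscosity = viscosity, nucleus_radius = nucleus_radius,
                 mt_radius = mt_radius),
            class = "drag_environment")
}

#' Microtubule growth and force kinetics
#'
#' Free and contact growth velocities, shrinkage velocity, stall force,
#' flexural rigidity, and the catastrophe-time model. The drop from `v_grow`
#' to `v_contact` during wall contact sets the polymerization pushing force
#' through the force-velocity relation `fs * (1 - v_contact / v_grow)`.
#'
#' @param v_grow Free growth velocity `V+`, um/s.
#' @param v_contact Contact (dwell) growth velocity `V+f`, um/s,
#'   `0 < v_contact <= v_grow`.
#' @param v_shrink Shrinkage velocity `V-`, um/s.
#' @param stall_force Stall force `fs`, pN.
#' @param flexural_rigidity Flexural rigidity `kappa`, pN um^2.
#' @param catastrophe A [catastrophe_model()].
#' @export
kinetic_params <- function(v_grow = 0.05, v_contact = 0.017, v_shrink = 0.15,
                           stall_force = 5, flexural_rigidity = 1.25,
                           catastrophe = catastrophe_model()) {
  stopifnot(v_contact > 0, v_contact <= v_grow, v_shrink > 0,
            stall_force > 0, flexural_rigidity > 0,
            inherits(catastrophe, "catastrophe_model"))
  structure(list(v_grow = v_grow, v_contact = v_contact, v_shrink = v_shrink,
                 stall_force = stall_force,
                 flexural_rigidity = flexural_rigidity,
                 catastrophe = catastrophe),
            class = "kinetic_params")
}

#' Nucleus position and orientation
#'
#' Centroid position `X = (x, y)` of the rigid spherical nucleus and the
#' rotation angle `omega` between the cell long axis and the center-to-SPB
#' vector (the spindle pole body sits at anchor angle `psi = 0`).
#'
#' @param position Numeric length-2, micrometers.
#' @param rotation Radians.
#' @export
nucleus_state <- function(position = c(0, 0), rotation = 0) {
  stopifnot(length(position) == 2L, is.numeric(position), all(is.finite(position)))
  structure(list(position = as.numeric(position), rotation = rotation),
            class = "nucleus_state")
}

#' Polymerization pushing force
#'
#' Force-velocity relation for a polymerizing filament pressing on a wall:
#' `fs * (1 - v_contact / v_grow)`. Zero when contact does not slow growth,
#' approaching the stall force as contact growth stalls.
#'
#' @param kinetics A [kinetic_params()].
#' @return Force in pN, in `[0, stall_force)`.
#' @export
polymerization_force <- function(kinetics) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  kinetics$stall_force * (1 - kinetics$v_contact / kinetics$v_grow)
}

#' Critical Euler buckling force with a geometric floor
#'
#' `max(kappa * pi^2 / length^2, kappa * pi^2 / ref_length^2)`. The reference
#' length is the anchor-to-wall distance frozen at the first contact of the
#' current growth excursion, so that the buckling threshold never decays below
#' its value at contact; this emulates the geometric confinement of buckled
#' filaments inside the cell.
#'
#' @param length Current filament length, micrometers (> 0).
#' @param ref_length Buckling reference length, micrometers (> 0).
#' @param rigidity Flexural rigidity `kappa`, pN um^2.
#' @return Critical force in pN.
#' @export
buckling_force <- function(length, ref_length, rigidity) {
  stopifnot(all(length > 0), all(ref_length > 0), rigidity > 0)
  pmax(rigidity * pi^2 / length^2, rigidity * pi^2 / ref_length^2)
}

#' World-frame position of a nucleation site
#'
#' Anchors sit on the nucleus periphery and co-rotate with it:
#' `X + rnuc * (cos(omega + psi), sin(omega + psi))`.
#'
#' @param nucleus A [nucleus_state()].
#' @param anchor_angle Anchor angle `psi`, radians (nucleus frame).
#' @param nucleus_radius Nucleus radius, micrometers.
#' @return Numeric length-2 position, micrometers.
#' @export
anchor_world_position <- function(nucleus, anchor_angle, nucleus_radius) {
  stopifnot(inherits(nucleus, "nucleus_state"))
  a <- nucleus$rotation + anchor_angle
  nucleus$position + nucleus_radius * c(cos(a), sin(a))
}

#' Contact force and torque of one microtubule on the nucleus
#'
#' The filament exerts force only while growing with its tip at or beyond the
#' end wall of its side. The magnitude is the smaller of the polymerization
#' force and the critical buckling force; the direction opposes the growth
#' direction. The torque is the cross product of the anchor lever arm with the
#' force.
#'
#' @param mt A [microtubule_state()].
#' @param nucleus A [nucleus_state()].
#' @param geom A [cell_geometry()].
#' @param kinetics A [kinetic_params()].
#' @param nucleus_radius Nucleus radius, micrometers.
#' @return List with `force` (pN, length 2), `torque` (pN um, scalar) and
#'   `contact` (logical).
#' @export
contact_force <- function(mt, nucleus, geom, kinetics, nucleus_radius = 1.4) {
  stopifnot(inherits(mt, "microtubule_state"),
            inherits(nucleus, "nucleus_state"),
            inherits(geom, "cell_geometry"),
            inherits(kinetics, "kinetic_params"))
  zero <- list(force = c(0, 0), torque = 0, contact = FALSE)
  if (mt$phase != "growing" || mt$length <= 0) return(zero)
  anchor <- anchor_world_position(nucleus, mt$anchor_angle, nucleus_radius)
  sgn <- if (mt$side == "right") 1 else -1
  dir <- c(sgn * cos(mt$axis_angle), sin(mt$axis_angle))
  tip_x <- anchor[1] + mt$length * dir[1]
  in_contact <- if (sgn > 0) tip_x >= geom$half_length else
    tip_x <= -geom$half_length
  if (!in_contact) return(zero)
  fp <- polymerization_force(kinetics)
  ref <- if (is.na(mt$buckling_ref_length)) mt$length else mt$buckling_ref_length
  fe <- buckling_force(mt$length, ref, kinetics$flexural_rigidity)
  f <- min(fp, fe)
  force <- -f * dir
  lever <- anchor - nucleus$position
  torque <- lever[1] * force[2] - lever[2] * force[1]
  list(force = force, torque = torque, contact = TRUE)
}

#' Stokes drags of the nucleus
#'
#' Translational `6 pi eta r` and rotational `8 pi eta r^3` drag of a rigid
#' sphere in the cytoplasm.
#'
#' @param env A [drag_environment()].
#' @return Named numeric: `translational` (pN s / um), `rotational` (pN s um).
#' @export
nucleus_drags <- function(env) {
  stopifnot(inherits(env, "drag_environment"))
  c(translational = 6 * pi * env$viscosity * env$nucleus_radius,
    rotational = 8 * pi * env$viscosity * env$nucleus_radius^3)
}

#' Anisotropic slender-body drag of the attached microtubules
#'
#' Summed parallel and perpendicular translational drag of the longest
#' filament per anchoring site, using slender-body expressions
#' `2 pi eta l cos(theta) / (ln(l cos(theta) / 2 rMT) - 0.2)` (parallel to the
#' long axis) and `4 pi eta l sin(theta) / (ln(l sin(theta) / 2 rMT) + 0.84)`
#' (perpendicular). Projected lengths use `|cos|`, `|sin|` (drag cannot depend
#' on the orientation sign). A term whose logarithmic denominator is not
#' positive lies outside the slender-body regime and is skipped rather than
#' allowed to contribute a negative drag.
#'
#' @param lengths Lengths of the longest filament per anchor, micrometers.
#' @param angles Matching axis angles, radians.
#' @param env A [drag_environment()].
#' @return Named numeric: `parallel`, `perpendicular` (pN s / um).
#' @export
mt_drag_components <- function(lengths, angles, env) {
  stopifnot(inherits(env, "drag_environment"),
            length(lengths) == length(angles))
  if (length(lengths) == 0L)
    return(c(parallel = 0, perpendicular = 0))
  stopifnot(all(lengths > 0))
  eta <- env$viscosity
  proj_par <- lengths * abs(cos(angles))
  proj_perp <- lengths * abs(sin(angles))
  den_par <- log(proj_par / (2 * env$mt_radius)) - 0.2
  den_perp <- log(proj_perp / (2 * env$mt_radius)) + 0.84
  ok_par <- proj_par > 0 & den_par > 0
  ok_perp <- proj_perp > 0 & den_perp > 0
  c(parallel = sum(2 * pi * eta * proj_par[ok_par] / den_par[ok_par]),
    perpendicular = sum(4 * pi * eta * proj_perp[ok_perp] / den_perp[ok_perp]))
}

#' Series combination of nucleus and microtubule drag
#'
#' The nucleus and its attached filaments dissipate in series,
#' `1/zeta = 1/zeta_nuc + 1/zeta_MT`. With no attached filaments
#' (`mt_drag = 0`) the combination reduces to the nucleus drag alone, the
#' physical limit of a free sphere.
#'
#' @param nucleus_drag Nucleus translational drag, pN s / um (> 0).
#' @param mt_drag Microtubule drag along the same axis, pN s / um (>= 0).
#' @return Effective drag, pN s / um.
#' @export
effective_translational_drag <- function(nucleus_drag, mt_drag) {
  stopifnot(all(nucleus_drag > 0), all(mt_drag >= 0))
  ifelse(mt_drag == 0, nucleus_drag, 1 / (1 / nucleus_drag + 1 / mt_drag))
}
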