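#' Thromboembolus mechanical properties
#'
#' Rigid-sphere embolus model. The default 500 um diameter with density
#' 1.15 g/cc reproduces the bare-Stokes momentum response time of 0.004 s in
#' 4.0 cP blood (see [momentum_response_time()]); the density sits within
#' reported thrombus ranges. Wall-impact behaviour is governed by the dry
#' restitution coefficient and the critical impact Stokes number below which
#' elastohydrodynamic lubrication fully damps the rebound.
#'
#' @param diameter embolus diameter, um.
#' @param density embolus density, g/cc.
#' @param added_mass added-mass coefficient (0.5 for a sphere).
#' @param restitution dry restitution coefficient `e0` in (0, 1].
#' @param critical_stokes critical impact Stokes number `St_c`.
#' @param lift_coefficient Saffman lift prefactor.
#' @param lift,drag,flow_force flags toggling individual force terms
#'   (for ablation tests).
#' @return object of class `embolus_properties`.
#' @export
embolus_properties <- function(diameter = 500, density = 1.15,
                               added_mass = 0.5, restitution = 0.8,
                               critical_stokes = 10, lift_coefficient = 1.615,
                               lift = TRUE, drag = TRUE, flow_force = TRUE) {
  stopifnot(diameter > 0, density > 0, restitution > 0, restitution <= 1,
            added_mass >= 0, critical_stokes >= 0)
  structure(list(diameter_um = diameter, density = density,
                 added_mass = added_mass, restitution = restitution,
                 critical_stokes = critical_stokes,
                 lift_coefficient = lift_coefficient,
                 lift = lift, drag = drag, flow_force = flow_force),
            class = "embolus_properties")
}

#' Momentum response time
#'
#' `tau = rho_p d^2 / (18 mu)`: the time constant over which Stokes drag
#' relaxes the particle velocity toward the local fluid velocity.
#'
#' @param props an [embolus_properties()].
#' @param fluid a [fluid_properties()].
#' @return tau, s.
#' @export
momentum_response_time <- function(props = embolus_properties(),
                                   fluid = fluid_properties()) {
  d <- props$diameter_um * 1e-6           # m
  (props$density * 1000) * d^2 / (18 * fluid$viscosity * 1e-3)
}

#' Stokes number relative to a flow time scale
#'
#' `St = tau / T`; values much below one imply near-tracer behaviour.
#'
#' @param tau momentum response time, s.
#' @param period flow time scale (cardiac cycle), s.
#' @return dimensionless Stokes number.
#' @export
stokes_number <- function(tau, period) {
  stopifnot(tau > 0, period > 0)
  tau / period
}

#' Hydrodynamic acceleration on an embolus
#'
#' Total modified Maxey-Riley acceleration at the given state: Stokes drag
#' `(u - v)/tau` scaled by the added-mass factor `rho_p/(rho_p + Cm rho_f)`;
#' the undisturbed-flow plus pressure-gradient force
#' `(1 + Cm) rho_f/(rho_p + Cm rho_f) * Du/Dt`; and Saffman-type
#' shear-gradient lift perpendicular to slip and vorticity. Components are
#' returned separately for testing/ablation.
#'
#' @param state list with `position` (mm), `velocity` (mm/s), `time` (s).
#' @param field a [segment_velocity_field()].
#' @param props an [embolus_properties()].
#' @param fluid a [fluid_properties()].
#' @param segment_hint starting segment for the local search.
#' @return total acceleration (mm/s^2) with attribute `components`
#'   (`drag`, `flow_force`, `lift`).
#' @export
hydrodynamic_acceleration <- function(state, field,
                                      props = embolus_properties(),
                                      fluid = fluid_properties(),
                                      segment_hint = 1L) {
  hint <- .seg_index(field$network, segment_hint)
  res <- accel_cpp(field$net, field$flow, as.numeric(state$position),
                   as.numeric(state$velocity), state$time,
                   unclass(props), unclass(fluid), hint)
  structure(res$total,
            components = list(drag = res$drag, flow_force = res$flow_force,
                              lift = res$lift))
}

#' Resolve an embolus-wall collision
#'
#' Reverses the wall-normal velocity component scaled by the effective
#' restitution `e_eff(v_n) = e0 * max(0, 1 - St_c/St_n)` with impact Stokes
#' number `St_n = rho_p d v_n / (9 mu)`: slow impacts (`St_n <= St_c`) are
#' fully damped by the lubrication film and the embolus deposits tangentially;
#' fast impacts recover the dry restitution. Tangential velocity is preserved
#' (frictionless contact).
#'
#' @param state list with `velocity` (mm/s).
#' @param wall_normal unit normal pointing into the lumen.
#' @param props an [embolus_properties()].
#' @param fluid a [fluid_properties()].
#' @return list with the post-collision `velocity`, `collided` flag and the
#'   effective `restitution` used. Called with a separating velocity it is a
#'   no-op with a warning.
#' @export
resolve_wall_collision <- function(state, wall_normal,
                                   props = embolus_properties(),
                                   fluid = fluid_properties()) {
  res <- collide_cpp(as.numeric(state$velocity), as.numeric(wall_normal),
                     unclass(props), unclass(fluid))
  if (!res$collided)
    warning("resolve_wall_collision called with separating velocity; no-op")
  res
}
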