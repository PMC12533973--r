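#' Integrate a batch of emboli through the flow field
#'
#' Explicit Euler integration (position and velocity) of every released
#' embolus at the particle time step until it crosses an outlet plane or the
#' time horizon is exhausted. Wall contact is resolved every step with the
#' lubricated restitution model and a projection back to the wall-offset
#' surface. Particles are advanced independently (one-way coupling), so batch
#' results are identical to particle-by-particle integration.
#'
#' @param field a [segment_velocity_field()] (possibly [stitch_cycles()]d).
#' @param release data.frame from [sample_release()] (columns `x`, `y`, `z`,
#'   `t0`, `segment`), or any frame with those columns.
#' @param props an [embolus_properties()].
#' @param fluid a [fluid_properties()].
#' @param dt particle time step, s (default 0.05 ms).
#' @param horizon integration end time, s (default: the field's stitched
#'   horizon).
#' @param v0 optional n-by-3 matrix of initial velocities; default is the
#'   local fluid velocity at release.
#' @param record_every record every k-th position for trajectory export
#'   (0 = off).
#' @return object of class `trajectory_set`: a data.frame `fates` (status,
#'   outlet, exit_time, collisions, steps), the visited-segment lists, final
#'   states, and optional recorded trajectories.
#' @export
integrate_batch <- function(field, release, props = embolus_properties(),
                            fluid = fluid_properties(), dt = 5e-5,
                            horizon = NULL, v0 = NULL, record_every = 0) {
  stopifnot(inherits(field, "velocity_field"))
  n <- nrow(release)
  X0 <- as.matrix(release[, c("x", "y", "z")])
  seg0 <- vapply(release$segment, function(s) .seg_index(field$network, s),
                 integer(1))
  if (is.null(v0)) {
    v0 <- t(vapply(seq_len(n), function(i) {
      r <- field_eval_cpp(field$net, field$flow, X0[i, ], release$t0[i],
                          seg0[i])
      r$u
    }, numeric(3)))
  }
  if (is.null(horizon)) horizon <- field$horizon
  res <- integrate_batch_cpp(field$net, field$flow, X0, as.matrix(v0),
                             release$t0, as.integer(seg0),
                             unclass(props), unclass(fluid), dt, horizon,
                             as.integer(record_every))
  outlets <- field$network$outlets
  fates <- data.frame(
    status = ifelse(res$status == 1, "exited", "unresolved"),
    outlet = ifelse(res$outlet > 0, outlets[pmax(res$outlet, 1)], NA_character_),
    exit_time = res$exit_time, t_final = res$t_final,
    collisions = res$collisions, steps = res$steps,
    stringsAsFactors = FALSE)
  seg_names <- field$network$segments$name
  visited <- lapply(res$visited, function(v) seg_names[v])
  structure(list(fates = fates, visited = visited,
                 position = res$position, velocity = res$velocity,
                 trajectory = res$trajectory, release = release,
                 horizon = horizon, dt = dt),
            class = "trajectory_set")
}

#' Integrate a single embolus from release to destination
#'
#' @param release list with `position` (mm) and `time` (s).
#' @param field a [segment_velocity_field()].
#' @param props,fluid,dt,horizon,record_every see [integrate_batch()].
#' @param segment_hint release segment name.
#' @return a single-trajectory record: release state, exit outlet or
#'   unresolved flag, exit time, ordered segments visited, collision count,
#'   and cycles integrated.
#' @export
advance_and_integrate <- function(release, field,
                                  props = embolus_properties(),
                                  fluid = fluid_properties(), dt = 5e-5,
                                  horizon = NULL, segment_hint = "asc_aorta",
                                  record_every = 0) {
  wd <- wall_distance(field, release$position, segment_hint)
  if (!wd$inside || wd$wall_distance < props$diameter_um * 5e-4 - 1e-9)
    stop("release position must lie inside the lumen at wall distance >= ",
         "the embolus radius")
  rel <- data.frame(x = release$position[1], y = release$position[2],
                    z = release$position[3], t0 = release$time,
                    segment = segment_hint, stringsAsFactors = FALSE)
  ts <- integrate_batch(field, rel, props, fluid, dt = dt, horizon = horizon,
                        record_every = record_every)
  f <- ts$fates[1, ]
  list(release = release, status = f$status, outlet = f$outlet,
       exit_time = f$exit_time, segments_visited = ts$visited[[1]],
       collisions = f$collisions,
       cycles_integrated = (f$t_final - release$time) / field$period,
       trajectory = if (record_every > 0) ts$trajectory[[1]] else NULL,
       final_position = ts$position[1, ])
}
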