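# Marshalling of network and flow objects into the flat form consumed by the
# compiled sampler/integrator.

.net_cpp <- function(net) {
  segs <- net$segments
  nodes <- net$nodes
  idx <- function(id) match(id, nodes$id) - 1L
  p0 <- as.matrix(segs[, c("gx0", "gy0", "gz0")])
  p1 <- as.matrix(segs[, c("gx1", "gy1", "gz1")])
  sten <- as.integer(segs$severity > 0 & !segs$occluded)
  list(p0 = p0, p1 = p1, r0 = segs$r0, r1 = segs$r1,
       sten = sten,
       sc = ifelse(is.na(segs$sten_center), 0, segs$sten_center),
       shalf = ifelse(is.na(segs$sten_length), 1, segs$sten_length / 2),
       fth = 1 - ifelse(sten == 1, segs$severity, 0) / 100,
       occluded = as.integer(segs$occluded),
       prox = idx(segs$prox), dist = idx(segs$dist),
       outlet = ifelse(is.na(segs$outlet), 0L,
                       match(segs$outlet, net$outlets)),
       nnode = nrow(nodes),
       inlet_seg = which(segs$prox == net$inlet)[1] - 1L)
}

.flow_cpp <- function(solution) {
  list(T = solution$period, Q = solution$Q, dQdt = solution$dQdt)
}

#' Analytic space-time velocity field from a flow solution
#'
#' Reconstructs the in-vessel velocity field implied by the network flow
#' solution: inside each segment the axial velocity is the Poiseuille profile
#' `2 Q(t) / (pi R(s)^2) * (1 - (rho/R)^2)` along the centerline tangent,
#' plus the first-order radial component required by mass conservation where
#' the radius varies; junction zones blend the adjacent segment fields with
#' containment-depth-squared weights. The sampler also answers wall-distance
#' queries. Field samples are read-only snapshots of the flow solution: the
#' field is never modified by particle state (one-way coupling).
#'
#' @param solution a [solve_unsteady()] result.
#' @param network the matching `vessel_network`.
#' @param fluid a [fluid_properties()].
#' @return object of class `velocity_field`.
#' @export
segment_velocity_field <- function(solution, network,
                                   fluid = fluid_properties()) {
  stopifnot(inherits(solution, "flow_solution"),
            inherits(network, "vessel_network"))
  structure(list(net = .net_cpp(network), flow = .flow_cpp(solution),
                 network = network, fluid = fluid, period = solution$period,
                 horizon = solution$period),
            class = "velocity_field")
}

#' Sample the velocity field
#'
#' @param field a [segment_velocity_field()].
#' @param x position, mm (length-3).
#' @param t time, s.
#' @param segment_hint segment name or id to start the local search from.
#' @return list with `u` (mm/s), `dudt`, `grad` (1/s, `du_i/dx_j`), the host
#'   `segment`, local coordinates, `wall_distance` (mm) and `inside`. Queries
#'   outside the lumen are flagged `inside = FALSE` with zero velocity.
#' @export
sample_velocity <- function(field, x, t, segment_hint = 1L) {
  hint <- .seg_index(field$network, segment_hint)
  res <- field_eval_cpp(field$net, field$flow, as.numeric(x), t, hint)
  res$segment_name <- field$network$segments$name[res$segment]
  res
}

#' Wall distance and normal at a point
#' @inheritParams sample_velocity
#' @return list with `wall_distance` (mm, positive inside the lumen),
#'   `normal` (unit, pointing into the lumen), host `segment`, local `s`.
#' @export
wall_distance <- function(field, x, segment_hint = 1L) {
  hint <- .seg_index(field$network, segment_hint)
  locate_cpp(field$net, as.numeric(x), hint)
}

.seg_index <- function(net, segment) {
  if (is.character(segment)) {
    i <- match(segment, net$segments$name)
    if (is.na(i)) stop("unknown segment: ", segment)
    i
  } else as.integer(segment)
}

# axis-frame helpers for a segment (internal)
.seg_frame <- function(net, segment) {
  i <- .seg_index(net, segment)
  sg <- net$segments[i, ]
  p0 <- c(sg$gx0, sg$gy0, sg$gz0)
  p1 <- c(sg$gx1, sg$gy1, sg$gz1)
  ez <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  ref <- if (abs(ez[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * ez) * ez
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ez[2] * e1[3] - ez[3] * e1[2],
          ez[3] * e1[1] - ez[1] * e1[3],
          ez[1] * e1[2] - ez[2] * e1[1])
  list(i = i, sg = sg, p0 = p0, ez = ez, e1 = e1, e2 = e2)
}

#' Cross-sectional flux of the sampled velocity field
#'
#' Numerical quadrature (Gauss-Legendre in radius, uniform in azimuth) of the
#' axial velocity over the lumen cross-section of a segment at arc length `s`
#' and time `t`. For a pure Poiseuille segment this reproduces the solved
#' segment flow to quadrature accuracy.
#'
#' @param field a [segment_velocity_field()].
#' @param segment segment name.
#' @param s arc length from the proximal node, mm.
#' @param t time, s (may be a vector; flux is returned per time).
#' @param n_r,n_phi quadrature orders.
#' @return flux in mL/s (vector along `t`).
#' @export
cross_section_flux <- function(field, segment, s, t, n_r = 12, n_phi = 16) {
  fr <- .seg_frame(field$network, segment)
  if (s < 0 || s > fr$sg$L) stop("s outside segment")
  if (fr$sg$occluded) return(rep(0, length(t)))
  R <- segment_radius(field$network, fr$sg$name, s)
  gq <- pracma::gaussLegendre(n_r, 0, R)
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  centre <- fr$p0 + s * fr$ez
  vapply(t, function(tt) {
    tot <- 0
    for (k in seq_len(n_r)) for (ph in phi) {
      xq <- centre + gq$x[k] * (cos(ph) * fr$e1 + sin(ph) * fr$e2)
      res <- field_eval_cpp(field$net, field$flow, xq, tt, fr$i)
      tot <- tot + gq$w[k] * (2 * pi / n_phi) * gq$x[k] * sum(res$u * fr$ez)
    }
    tot / 1000  # mm^3/s -> mL/s
  }, numeric(1))
}

#' Cycle-averaged cross-sectional flux
#' @inheritParams cross_section_flux
#' @param n_t number of time samples over one period.
#' @return cycle-mean flux, mL/s.
#' @export
cycle_mean_flux <- function(field, segment, s, n_t = 24, n_r = 12, n_phi = 16) {
  ts <- (seq_len(n_t) - 1) * field$period / n_t
  mean(cross_section_flux(field, segment, s, ts, n_r = n_r, n_phi = n_phi))
}
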