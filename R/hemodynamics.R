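#' Mean arterial pressure
#'
#' `MAP = diastolic + (systolic - diastolic)/3`.
#'
#' @param systolic systolic pressure, mmHg.
#' @param diastolic diastolic pressure, mmHg.
#' @return MAP, mmHg.
#' @export
mean_arterial_pressure <- function(systolic = 120, diastolic = 80) {
  stopifnot(diastolic > 0)
  if (systolic < diastolic) stop("systolic pressure below diastolic")
  diastolic + (systolic - diastolic) / 3
}

#' Total arterial resistance
#'
#' `TAR = MAP / CO` in mmHg·s/mL.
#'
#' @param map mean arterial pressure, mmHg.
#' @param co cardiac output, mL/s.
#' @return TAR, mmHg·s/mL.
#' @export
total_arterial_resistance <- function(map, co) {
  stopifnot(map > 0, co > 0)
  map / co
}

#' Target outlet flow fractions
#'
#' The descending aorta receives its configured fraction of cardiac output
#' (default 65%); the six cerebral outlets receive configured per-outlet
#' fractions; the residual is split between the external carotids and
#' subclavians in proportion to their outlet cross-sectional areas. Fractions
#' sum to one.
#'
#' @param network a `vessel_network`.
#' @param desc_fraction descending-aorta fraction of cardiac output.
#' @param cerebral named per-side cerebral fractions of cardiac output
#'   (`mca`, `aca`, `pca`), applied to both sides.
#' @param map mean arterial pressure used for resistance initialisation, mmHg.
#' @param tolerance relative tuning tolerance per outlet.
#' @return object of class `flow_targets`: named fractions over the 11
#'   outlets, plus `map` and `tolerance`.
#' @export
target_flow_splits <- function(network,
                               desc_fraction = 0.65,
                               cerebral = c(mca = 0.034, aca = 0.018, pca = 0.020),
                               map = mean_arterial_pressure(),
                               tolerance = 0.01) {
  stopifnot(inherits(network, "vessel_network"),
            all(c("mca", "aca", "pca") %in% names(cerebral)))
  fr <- stats::setNames(numeric(length(network$outlets)), network$outlets)
  fr["desc_aorta"] <- desc_fraction
  for (side in c("L", "R")) {
    fr[paste0("mca_", side)] <- cerebral[["mca"]]
    fr[paste0("aca_", side)] <- cerebral[["aca"]]
    fr[paste0("pca_", side)] <- cerebral[["pca"]]
  }
  residual <- 1 - sum(fr)
  if (residual < 0) stop("configured fractions exceed 1")
  segs <- network$segments
  resid_outlets <- c("eca_L", "eca_R", "sub_L", "sub_R")
  area <- vapply(resid_outlets, function(o) {
    i <- which(!is.na(segs$outlet) & segs$outlet == o)
    pi * segs$r1[i]^2
  }, numeric(1))
  fr[resid_outlets] <- residual * area / sum(area)
  stopifnot(abs(sum(fr) - 1) < 1e-12)
  structure(list(fractions = fr, map = map, tolerance = tolerance),
            class = "flow_targets")
}

# Per-segment hydraulic coefficients (internal).
# Linear (Poiseuille) resistance R = (8 mu / pi) * I, I = int ds / r(s)^4,
# closed form for the linear base taper, numerical quadrature across the
# stenosis taper. Quadratic (Young-Tsai type) loss coefficient K such that
# dP = K * Q|Q| across a stenosis. Units mmHg, mL/s.
.segment_coefficients <- function(net, fluid, K_t = 1.52, nq = 2000) {
  segs <- net$segments
  mu <- fluid$viscosity           # cP
  rho <- fluid$density * 1000     # kg/m^3
  lin_integral <- function(r0, r1, L) {
    if (abs(r1 - r0) < 1e-12) L / r0^4
    else L / (3 * (r1 - r0)) * (1 / r0^3 - 1 / r1^3)
  }
  n <- nrow(segs)
  Rlin <- numeric(n); K <- numeric(n)
  for (i in seq_len(n)) {
    sg <- segs[i, ]
    if (sg$occluded) { Rlin[i] <- Inf; next }
    if (sg$severity > 0) {
      s <- seq(0, sg$L, length.out = nq)
      r <- segment_radius(net, sg$name, s)
      Rlin[i] <- pracma::trapz(s, 1 / r^4)
      r_th <- sg$r_ref * (1 - sg$severity / 100)
      A_ref <- pi * (sg$r_ref * 1e-3)^2      # m^2
      A_th <- pi * (r_th * 1e-3)^2
      K_SI <- K_t * rho * (A_ref / A_th - 1)^2 / (2 * A_ref^2)  # Pa s^2/m^6
      K[i] <- K_SI * (1e-6)^2 / 133.322
    } else {
      Rlin[i] <- lin_integral(sg$r0, sg$r1, sg$L)
    }
  }
  # (8 mu / pi) * I[mm^-3] -> mmHg s/mL
  Rlin <- 8 * mu * Rlin / (pi * 133.322)
  list(Rlin = Rlin, K = K)
}

# Steady nonlinear resistive network solve (internal).
# Prescribed inlet flow Qin, outlet resistances to zero reference pressure;
# stenosis quadratic losses handled by fixed-point iteration on the
# effective resistance R_eff = R_lin + K*|Q|.
.solve_steady <- function(net, coef, r_out, Qin, Q_warm = NULL,
                          tol = 1e-12, max_iter = 60) {
  segs <- net$segments
  live <- which(!segs$occluded)
  nodes <- net$nodes$id
  nn <- length(nodes)
  ni <- match(segs$prox, nodes); nj <- match(segs$dist, nodes)
  out_node <- match(net$nodes$id[net$nodes$kind == "outlet"], nodes)
  out_name <- vapply(net$nodes$id[net$nodes$kind == "outlet"], function(nd) {
    i <- which(segs$dist == nd & !is.na(segs$outlet))
    segs$outlet[i]
  }, character(1))
  g_out <- 1 / r_out[out_name]
  inlet_i <- match(net$inlet, nodes)
  Q <- if (is.null(Q_warm)) numeric(nrow(segs)) else Q_warm
  for (iter in seq_len(max_iter)) {
    Reff <- coef$Rlin + coef$K * abs(Q)
    G <- matrix(0, nn, nn)
    for (k in live) {
      g <- 1 / Reff[k]
      a <- ni[k]; b <- nj[k]
      G[a, a] <- G[a, a] + g; G[b, b] <- G[b, b] + g
      G[a, b] <- G[a, b] - g; G[b, a] <- G[b, a] - g
    }
    for (m in seq_along(out_node))
      G[out_node[m], out_node[m]] <- G[out_node[m], out_node[m]] + g_out[m]
    rhs <- numeric(nn); rhs[inlet_i] <- Qin
    P <- solve(G, rhs)
    Qnew <- numeric(nrow(segs))
    Qnew[live] <- (P[ni[live]] - P[nj[live]]) / Reff[live]
    if (max(abs(Qnew - Q)) < tol * max(1, abs(Qin))) { Q <- Qnew; break }
    Q <- Qnew
  }
  node_resid <- rhs
  for (k in live) {
    node_resid[ni[k]] <- node_resid[ni[k]] - Q[k]
    node_resid[nj[k]] <- node_resid[nj[k]] + Q[k]
  }
  node_resid[out_node] <- node_resid[out_node] - P[out_node] * g_out
  q_out <- stats::setNames(P[out_node] * g_out, out_name)
  list(P = stats::setNames(P, nodes), Q = Q, q_out = q_out,
       resid = max(abs(node_resid)))
}

#' Tune outlet resistances to target flow splits
#'
#' Iterative steady solves at mean inlet flow with multiplicative updates
#' `R_i <- R_i * (Q_i / Q_target_i)` until every outlet's mean-flow fraction
#' is within the relative tolerance of its target. Resistances are
#' initialised from the total arterial resistance apportioned inversely to
#' the target fractions (`R_i = MAP / (CO * f_i)`).
#'
#' @param network baseline (no-stenosis) `vessel_network`.
#' @param targets a [target_flow_splits()] object.
#' @param waveform a [cardiac_waveform()]; its mean flow is the tuning CO.
#' @param fluid a [fluid_properties()].
#' @param tol relative per-outlet tolerance (default from `targets`).
#' @param max_iter iteration cap.
#' @return object of class `outlet_resistance_set`: named resistances
#'   (mmHg·s/mL), iteration log, and the tuning conditions.
#' @export
tune_outlet_resistances <- function(network, targets, waveform,
                                    fluid = fluid_properties(),
                                    tol = targets$tolerance, max_iter = 200) {
  stopifnot(inherits(network, "vessel_network"),
            inherits(targets, "flow_targets"))
  if (any(network$segments$severity > 0))
    stop("outlet resistances are tuned on the baseline (no-stenosis) network")
  co <- waveform$mean_flow
  f <- targets$fractions
  r <- targets$map / (co * f)
  coef <- .segment_coefficients(network, fluid)
  log <- data.frame(iter = integer(0), max_rel_err = numeric(0))
  sol <- NULL
  for (it in seq_len(max_iter)) {
    sol <- .solve_steady(network, coef, r, co,
                         Q_warm = if (is.null(sol)) NULL else sol$Q)
    frac <- sol$q_out[names(f)] / co
    rel <- frac / f - 1
    log <- rbind(log, data.frame(iter = it, max_rel_err = max(abs(rel))))
    if (max(abs(rel)) <= tol) {
      return(structure(list(resistances = r, log = log, converged = TRUE,
                            map = targets$map, co = co, targets = f,
                            achieved = frac),
                       class = "outlet_resistance_set"))
    }
    r <- r * (frac / f)
  }
  stop("resistance tuning did not converge after ", max_iter,
       " iterations; residual fractions: ",
       paste(sprintf("%s=%.4f", names(f), sol$q_out[names(f)] / co),
             collapse = ", "))
}

#' @export
print.outlet_resistance_set <- function(x, ...) {
  cat("<outlet_resistance_set> tuned in", nrow(x$log), "iterations",
      sprintf("(max rel err %.2e)\n", x$log$max_rel_err[nrow(x$log)]))
  print(round(x$resistances, 3))
  invisible(x)
}

#' Solve pulsatile network hemodynamics over the cardiac cycle
#'
#' Quasi-static nonlinear resistive solve at every time step of the inlet
#' waveform: per-segment Poiseuille resistance integrated along the radius
#' profile plus a quadratic stenosis loss, prescribed inlet flow, resistance
#' outlet boundary conditions. The network carries no state, so the periodic
#' regime is reached immediately; the returned cycle is the converged
#' (third-cycle) solution. Interior-node flow residuals are tracked and must
#' stay below `1e-9` of the cardiac output.
#'
#' @param network a `vessel_network` (stenosed or baseline).
#' @param waveform a [cardiac_waveform()].
#' @param resistances an [tune_outlet_resistances()] result (or named vector).
#' @param fluid a [fluid_properties()].
#' @param dt_flow solver time step, s.
#' @param K_t quadratic stenosis loss coefficient.
#' @return object of class `flow_solution`: time grid `t`, period `T`,
#'   per-segment flows `Q` (mL/s, rows = segments, positive proximal to
#'   distal), their time derivatives `dQdt`, node pressures `P` (mmHg), and
#'   the maximum interior-node residual.
#' @export
solve_unsteady <- function(network, waveform, resistances,
                           fluid = fluid_properties(), dt_flow = 1e-3,
                           K_t = 1.52) {
  r_out <- if (inherits(resistances, "outlet_resistance_set"))
    resistances$resistances else resistances
  stopifnot(all(network$outlets %in% names(r_out)))
  .check_connected(network)
  coef <- .segment_coefficients(network, fluid, K_t = K_t)
  nt <- length(waveform$t)
  nseg <- nrow(network$segments)
  Q <- matrix(0, nseg, nt, dimnames = list(network$segments$name, NULL))
  P <- matrix(0, nrow(network$nodes), nt,
              dimnames = list(network$nodes$id, NULL))
  resid <- numeric(nt)
  sol <- NULL
  for (k in seq_len(nt)) {
    sol <- .solve_steady(network, coef, r_out, waveform$q[k],
                         Q_warm = if (is.null(sol)) NULL else sol$Q)
    Q[, k] <- sol$Q
    P[, k] <- sol$P
    resid[k] <- sol$resid
  }
  # periodic central difference for dQ/dt
  ip <- c(2:nt, 1); im <- c(nt, 1:(nt - 1))
  dQdt <- (Q[, ip, drop = FALSE] - Q[, im, drop = FALSE]) / (2 * dt_flow)
  structure(list(t = waveform$t, period = waveform$period, Q = Q, dQdt = dQdt,
                 P = P, resid_max = max(resid), co = waveform$mean_flow,
                 dt = dt_flow),
            class = "flow_solution")
}

#' Cycle-mean flow per segment
#' @param solution a `flow_solution`.
#' @return named vector of cycle-averaged segment flows, mL/s.
#' @export
mean_segment_flows <- function(solution) {
  rowMeans(solution$Q)
}

#' Cycle-mean outlet flow fractions of cardiac output
#' @param solution a `flow_solution`.
#' @param network the matching `vessel_network`.
#' @return named vector over the 11 outlets.
#' @export
outlet_flow_fractions <- function(solution, network) {
  segs <- network$segments
  term <- which(!is.na(segs$outlet))
  stats::setNames(rowMeans(solution$Q[term, , drop = FALSE]) / solution$co,
                  segs$outlet[term])
}

#' Cycle-mean flows through the Circle of Willis communicating segments
#'
#' Signed cycle-averaged flows (mL/min) for the anterior communicator, both
#' P1 segments, both posterior communicators, both internal carotids and the
#' basilar artery. Sign conventions follow the segment orientations: AcoA
#' positive = right to left; PcoA positive = posterior to anterior; P1
#' positive = basilar to posterior cerebral. Also reports the cervical
#' fractions of total cerebral blood flow (tCBF = LICA + RICA + BA).
#'
#' @param solution a `flow_solution`.
#' @param network the matching `vessel_network`.
#' @return list with `flows_ml_min` (named, signed) and
#'   `cervical_fractions` (LICA, RICA, BA fractions of tCBF).
#' @export
communicator_flow_map <- function(solution, network) {
  q <- mean_segment_flows(solution)
  pick <- c(acoa = "acoa", p1_L = "p1_L", p1_R = "p1_R",
            pcoa_L = "pcoa_L", pcoa_R = "pcoa_R",
            lica = "ica_L", rica = "ica_R", ba = "basilar")
  flows <- stats::setNames(q[pick] * 60, names(pick))
  cerv <- c(lica = unname(q["ica_L"]), rica = unname(q["ica_R"]),
            ba = unname(q["basilar"]))
  list(flows_ml_min = flows, cervical_fractions = cerv / sum(cerv))
}
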