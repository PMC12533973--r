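# Shared fixtures, built once per test run and cached.

.ef_cache <- new.env(parent = emptyenv())

ef_memo <- function(key, expr) {
  if (!exists(key, envir = .ef_cache)) assign(key, force(expr), envir = .ef_cache)
  get(key, envir = .ef_cache)
}

ef_fluid <- function() fluid_properties()
ef_props <- function(...) embolus_properties(...)

ef_wave <- function() ef_memo("wave", cardiac_waveform())

# steady inflow at the mean cardiac output (for closed-form physics oracles)
ef_wave_steady <- function() ef_memo("wave_steady", {
  wf <- cardiac_waveform()
  wf$q[] <- wf$mean_flow
  wf
})

ef_net <- function() ef_memo("net", build_baseline_network())

ef_resist <- function() ef_memo("resist", {
  tune_outlet_resistances(ef_net(), target_flow_splits(ef_net()), ef_wave())
})

ef_solution <- function(left = 0, right = 0, wave = ef_wave()) {
  key <- sprintf("sol_%g_%g_%d", left, right, identical(wave, ef_wave_steady()))
  ef_memo(key, {
    net <- ef_net()
    if (left > 0) net <- apply_stenosis(net, stenosis_spec("left", left))
    if (right > 0) net <- apply_stenosis(net, stenosis_spec("right", right))
    list(net = net, sol = solve_unsteady(net, wave, ef_resist()))
  })
}

ef_field <- function(left = 0, right = 0, cycles = 10, wave = ef_wave()) {
  s <- ef_solution(left, right, wave)
  stitch_cycles(segment_velocity_field(s$sol, s$net), cycles)
}

# a "steady tube" variant: untapered internal carotids and descending aorta,
# steady inflow; used for closed-form transit/relaxation oracles
ef_tube <- function() ef_memo("tube", {
  cfg <- network_template()
  for (nm in c("ica_R", "ica_L")) {
    i <- match(nm, cfg$segments$name)
    cfg$segments$r0[i] <- 3.0; cfg$segments$r1[i] <- 3.0
  }
  i <- match("desc_aorta", cfg$segments$name)
  cfg$segments$r0[i] <- 10; cfg$segments$r1[i] <- 10
  net <- build_baseline_network(cfg)
  rs <- tune_outlet_resistances(net, target_flow_splits(net), ef_wave_steady())
  sol <- solve_unsteady(net, ef_wave_steady(), rs)
  list(net = net, sol = sol,
       field = stitch_cycles(segment_velocity_field(sol, net), 50))
})

# point on a segment's axis at arc length s, offset rho along azimuth phi
ef_point <- function(net, segment, s, rho = 0, phi = 0) {
  fr <- emboflow:::.seg_frame(net, segment)
  fr$p0 + s * fr$ez + rho * (cos(phi) * fr$e1 + sin(phi) * fr$e2)
}

ef_axis <- function(net, segment) emboflow:::.seg_frame(net, segment)$ez

# exact Mann-Whitney p by exhaustive rank enumeration (oracle)
ef_mw_exact <- function(a, b, alternative = "two.sided") {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2  # U statistic for group a
  idx <- utils::combn(n + m, n)
  us <- apply(idx, 2, function(ii) sum(rank(pooled)[ii]) - n * (n + 1) / 2)
  switch(alternative,
         greater = mean(us >= w_obs),
         less = mean(us <= w_obs),
         two.sided = min(1, 2 * min(mean(us >= w_obs), mean(us <= w_obs))))
}
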