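test_that("mean arterial pressure follows the diastolic + pulse/3 formula", {
  expect_equal(mean_arterial_pressure(120, 80), 93.33, tolerance = 1e-3)
  expect_equal(mean_arterial_pressure(100, 100), 100)
  expect_equal(mean_arterial_pressure(90, 60), 70)
  expect_error(mean_arterial_pressure(70, 80), "below diastolic")
})

test_that("total arterial resistance is MAP over CO", {
  expect_equal(total_arterial_resistance(93.33, 79), 1.1814, tolerance = 1e-4)
  expect_equal(total_arterial_resistance(93.33, 93.33), 1)
  expect_equal(total_arterial_resistance(93.33, 2 * 79),
               total_arterial_resistance(93.33, 79) / 2)
})

test_that("target flow splits assign 65% to the descending aorta and sum to one", {
  tg <- target_flow_splits(ef_net())
  expect_equal(unname(tg$fractions["desc_aorta"]), 0.65)
  expect_equal(sum(tg$fractions), 1)
  # equal-area outlets share the residual equally
  expect_equal(unname(tg$fractions["eca_L"]), unname(tg$fractions["eca_R"]))
  expect_equal(unname(tg$fractions["sub_L"]), unname(tg$fractions["sub_R"]))
  expect_error(target_flow_splits(ef_net(), desc_fraction = 0.95,
                                  cerebral = c(mca = 0.05, aca = 0.01,
                                               pca = 0.01)),
               "exceed")
})

test_that("cardiac waveform is periodic with the exact configured mean", {
  wf <- ef_wave()
  expect_equal(mean(wf$q), 79, tolerance = 1e-9)
  expect_equal(wf$period, 0.83)
  expect_equal(waveform_flow(wf, 0.2), waveform_flow(wf, 0.2 + 0.83),
               tolerance = 1e-12)
  expect_true(all(wf$q > 0))
})

test_that("segment pressure drop matches the Poiseuille closed form", {
  # r = 3 mm, L = 100 mm, mu = 4 cP, Q = 10 mL/s -> dP ~ 0.94 mmHg
  R_mmhg <- 8 * (4e-3) * 0.1 / (pi * 3e-3^4) * 1e-6 / 133.322
  expect_equal(10 * R_mmhg, 0.943, tolerance = 2e-3)
  # the solver reproduces it on an untapered segment (P1, r = 1.1, L known)
  tube <- ef_tube()
  sol <- tube$sol
  i <- match("p1_R", tube$net$segments$name)
  sg <- tube$net$segments[i, ]
  Rseg <- 8 * (4e-3) * (sg$L * 1e-3) / (pi * (sg$r0 * 1e-3)^4) * 1e-6 / 133.322
  k <- 100
  dp <- unname(sol$P["ba_top", k] - sol$P["p_R", k])
  expect_equal(dp, unname(sol$Q[i, k]) * Rseg, tolerance = 1e-6)
})

test_that("resistance tuning converges to the targets within tolerance", {
  rs <- ef_resist()
  expect_true(rs$converged)
  expect_true(all(abs(rs$achieved / rs$targets - 1) <= 0.01))
  expect_true(all(rs$resistances > 0))
  expect_gt(nrow(rs$log), 0)
})

test_that("a symmetric network tunes to equal left/right resistances", {
  sym <- build_baseline_network(network_template(symmetric_arch = TRUE))
  rs <- tune_outlet_resistances(sym, target_flow_splits(sym), ef_wave())
  r <- rs$resistances
  for (o in c("mca", "aca", "pca", "eca", "sub"))
    expect_equal(unname(r[paste0(o, "_L")]), unname(r[paste0(o, "_R")]),
                 tolerance = 1e-6)
})

test_that("raising an outlet's target lowers its converged resistance", {
  net <- ef_net()
  t1 <- target_flow_splits(net)
  t2 <- target_flow_splits(net, desc_fraction = 0.64,
                           cerebral = c(mca = 0.039, aca = 0.018,
                                        pca = 0.020))
  r1 <- tune_outlet_resistances(net, t1, ef_wave())$resistances
  r2 <- tune_outlet_resistances(net, t2, ef_wave())$resistances
  expect_lt(r2[["mca_L"]], r1[["mca_L"]])
  expect_lt(r2[["mca_R"]], r1[["mca_R"]])
})

test_that("the unsteady solve conserves mass at interior nodes", {
  s <- ef_solution(40, 85)
  expect_lt(s$sol$resid_max, 1e-9 * 79)
  # inlet segment flow equals the waveform
  i <- match("asc_aorta", s$net$segments$name)
  expect_equal(unname(s$sol$Q[i, ]), unname(ef_wave()$q), tolerance = 1e-9)
  # occluded-free network: outlet fractions sum to one
  expect_equal(sum(outlet_flow_fractions(s$sol, s$net)), 1, tolerance = 1e-9)
})

test_that("outlet flow fractions are held nearly fixed across stenosis models", {
  base <- outlet_flow_fractions(ef_solution(0, 0)$sol, ef_net())
  for (mr in list(c(10, 85), c(40, 50), c(100, 25))) {
    s <- ef_solution(mr[1], mr[2])
    f <- outlet_flow_fractions(s$sol, s$net)
    expect_lt(max(abs(f - base[names(f)])), 0.01)
  }
})

test_that("cervical vessels recruit flow monotonically with carotid severity", {
  lica <- rica_ba <- numeric(0)
  for (sev in c(0, 50, 70, 85)) {
    s <- ef_solution(sev, 10)
    cf <- communicator_flow_map(s$sol, s$net)$cervical_fractions
    lica <- c(lica, cf[["lica"]])
    rica_ba <- c(rica_ba, cf[["rica"]] + cf[["ba"]])
  }
  expect_true(all(diff(lica) < 0))
  expect_true(all(diff(rica_ba) > 0))
})

test_that("AcoA flow routes toward the severely stenosed side and grows with severity", {
  a70 <- communicator_flow_map(ef_solution(70, 10)$sol,
                               ef_solution(70, 10)$net)$flows_ml_min[["acoa"]]
  a85 <- communicator_flow_map(ef_solution(85, 10)$sol,
                               ef_solution(85, 10)$net)$flows_ml_min[["acoa"]]
  expect_gt(a70, 0)  # positive = right -> left = toward the severe left side
  expect_gt(a85, a70)
  # mirrored pairing reverses the direction
  b85 <- communicator_flow_map(ef_solution(10, 85)$sol,
                               ef_solution(10, 85)$net)$flows_ml_min[["acoa"]]
  expect_lt(b85, 0)
  # cervical fractions of tCBF sum to one
  cf <- communicator_flow_map(ef_solution(10, 85)$sol,
                              ef_solution(10, 85)$net)$cervical_fractions
  expect_equal(sum(cf), 1, tolerance = 1e-12)
})

test_that("baseline cervical split is physiologic (ICA/ICA/BA near 39/37/24)", {
  cf <- communicator_flow_map(ef_solution(0, 0)$sol,
                              ef_net())$cervical_fractions
  expect_equal(unname(cf[["lica"]]), 0.39, tolerance = 0.12)
  expect_equal(unname(cf[["rica"]]), 0.37, tolerance = 0.12)
  expect_equal(unname(cf[["ba"]]), 0.24, tolerance = 0.12)
})

test_that("a network with disconnected outlets is rejected by name", {
  net <- ef_net()
  for (nm in c("basilar", "pcoa_L", "pcoa_R"))
    net$segments$occluded[match(nm, net$segments$name)] <- TRUE
  expect_error(solve_unsteady(net, ef_wave(), ef_resist()), "disconnected")
})

test_that("full occlusion carries zero flow", {
  s <- ef_solution(100, 25)
  i <- match("ica_L", s$net$segments$name)
  expect_true(all(s$sol$Q[i, ] == 0))
})
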