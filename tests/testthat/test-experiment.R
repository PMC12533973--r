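test_that("carotid release samples sit on the stenosis wall patch at the embolus-radius offset", {
  net <- ef_solution(40, 85)$net
  field <- ef_field(40, 85)
  rel <- sample_release("left_carotid", net, 60, radius = 0.25, seed = 3,
                        period = 0.83)
  sg <- net$segments[match("ica_L", net$segments$name), ]
  wd <- vapply(seq_len(nrow(rel)), function(i)
    wall_distance(field, unlist(rel[i, c("x", "y", "z")]), "ica_L")$wall_distance,
    numeric(1))
  expect_true(all(abs(wd - 0.25) < 1e-6))
  # axially within the stenosis patch
  fr <- emboflow:::.seg_frame(net, "ica_L")
  s <- vapply(seq_len(nrow(rel)), function(i)
    sum((unlist(rel[i, c("x", "y", "z")]) - fr$p0) * fr$ez), numeric(1))
  expect_true(all(s >= sg$sten_center - sg$sten_length / 2 - 1e-9))
  expect_true(all(s <= sg$sten_center + sg$sten_length / 2 + 1e-9))
  expect_true(all(rel$t0 >= 0 & rel$t0 < 0.83))
})

test_that("cardiogenic samples cover the inlet disc inside the rim offset", {
  net <- ef_net()
  rel <- sample_release("cardiogenic", net, 80, radius = 0.25, seed = 4,
                        period = 0.83)
  fr <- emboflow:::.seg_frame(net, "asc_aorta")
  rho <- vapply(seq_len(nrow(rel)), function(i) {
    d <- unlist(rel[i, c("x", "y", "z")]) - fr$p0
    sqrt(sum((d - sum(d * fr$ez) * fr$ez)^2))
  }, numeric(1))
  expect_true(all(rho <= segment_radius(net, "asc_aorta", 0.5) - 0.25 + 1e-9))
})

test_that("release sampling is reproducible per seed and never from an occluded carotid", {
  net <- ef_net()
  a <- sample_release("cardiogenic", net, 20, seed = 11)
  b <- sample_release("cardiogenic", net, 20, seed = 11)
  c <- sample_release("cardiogenic", net, 20, seed = 12)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$x, c$x)))
  occ <- apply_stenosis(net, stenosis_spec("left", 100))
  expect_error(sample_release("left_carotid", occ, 5), "occluded")
})

test_that("stitching extends the periodic field with no cycle-to-cycle variation", {
  field <- ef_field()
  f10 <- stitch_cycles(field, 10)
  expect_equal(f10$horizon, 10 * 0.83)
  expect_equal(stitch_cycles(field, 20)$horizon, 16.6)
  net <- ef_net()
  x <- ef_point(net, "cca_R", 20, 1.0)
  for (t in c(0.11, 0.47))
    expect_equal(sample_velocity(f10, x, t, "cca_R")$u,
                 sample_velocity(f10, x, t + 3 * 0.83, "cca_R")$u,
                 tolerance = 1e-9)
})

test_that("run_experiment conserves counts, is deterministic and flags extensions", {
  spec <- list(label = "40L85R", left = 40, right = 85,
               source = "left_carotid", n = 60, seed = 77)
  er <- run_experiment(spec, ef_net(), ef_resist(),
                       solution = ef_solution(40, 85)$sol)
  rec <- er$record
  expect_s3_class(rec, "distribution_record")
  expect_equal(sum(rec$counts) + rec$unresolved, 60)
  expect_identical(rec$label, "40L85R")
  er2 <- run_experiment(spec, ef_net(), ef_resist(),
                        solution = ef_solution(40, 85)$sol)
  expect_identical(rec$counts, er2$record$counts)
  expect_identical(rec$unresolved, er2$record$unresolved)
  expect_true(rec$cycles %in% c(10, 20))
  if (rec$extended) expect_equal(rec$cycles, 20)
})

test_that("CCO experiments never route emboli through the occluded carotid", {
  spec <- list(label = "100L50R", left = 100, right = 50,
               source = "right_carotid", n = 50, seed = 13)
  er <- run_experiment(spec, ef_net(), ef_resist())
  expect_false(any(vapply(er$visited, function(v) "ica_L" %in% v,
                          logical(1))))
  expect_equal(sum(er$record$counts) + er$record$unresolved, 50)
})

test_that("a small campaign runs end to end, resumes from cache and replays identically", {
  models <- enumerate_models(mild = 10, severe = 85, cco = FALSE)
  exps <- enumerate_experiments(models, n_per_source = 25, base_seed = 5)
  expect_equal(nrow(exps), 6)
  out <- withr::local_tempdir()
  camp <- run_campaign(exps, ef_net(), run_policy(n_per_source = 25),
                       resistances = ef_resist(), out_dir = out)
  expect_length(camp$records, 6)
  expect_length(camp$failures, 0)
  expect_true(file.exists(file.path(out, "manifest.json")))
  # resumable: cached records are reused and identical
  camp2 <- run_campaign(exps, ef_net(), run_policy(n_per_source = 25),
                        resistances = ef_resist(), out_dir = out)
  for (k in names(camp$records))
    expect_equal(camp$records[[k]]$counts, camp2$records[[k]]$counts)
  sm <- summarize_campaign(camp, ef_net())
  expect_equal(nrow(sm), 6)
  expect_true(all(sm$contralateral[!is.na(sm$contralateral)] >= 0))
})

test_that("contralateral fractions are stable across Monte Carlo sample sizes", {
  spec <- function(n) list(label = "10L85R", left = 10, right = 85,
                           source = "left_carotid", n = n, seed = 99)
  hm <- ef_net()$hemisphere_map
  f_small <- contralateral_fraction(
    run_experiment(spec(120), ef_net(), ef_resist(),
                   solution = ef_solution(10, 85)$sol)$record, "left", hm)
  f_large <- contralateral_fraction(
    run_experiment(spec(400), ef_net(), ef_resist(),
                   solution = ef_solution(10, 85)$sol)$record, "left", hm)
  se <- sqrt(f_large * (1 - f_large) * (1 / 120 + 1 / 400))
  expect_lt(abs(f_small - f_large), 3 * se + 0.02)
})
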