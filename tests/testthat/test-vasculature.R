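test_that("NASCET severity follows the diameter-ratio criterion", {
  expect_equal(nascet_severity(3.0, 3.0), 0)
  expect_equal(nascet_severity(0.0, 3.0), 100)
  expect_equal(nascet_severity(0.45, 3.0), 85)
  expect_error(nascet_severity(3.1, 3.0), "negative severity")
})

test_that("stenosis length is zero at zero severity and grows with severity", {
  expect_equal(stenosis_length(0, 20), 0)
  expect_equal(stenosis_length(40, 20, k = 0.5), 4)
  sev <- seq(0, 100, by = 5)
  L <- stenosis_length(sev, 37)
  expect_true(all(diff(L) > 0))
  expect_gt(stenosis_length(85, 20), stenosis_length(50, 20))
})

test_that("baseline network satisfies its structural invariants", {
  net <- ef_net()
  expect_length(net$outlets, 11)
  expect_identical(net$inlet, "root")
  expect_true(all(c("acoa", "pcoa_L", "pcoa_R", "p1_L", "p1_R") %in%
                    net$segments$name))
  expect_setequal(unname(net$hemisphere_map[c("mca_L", "aca_L", "pca_L")]),
                  "left")
  expect_setequal(unname(net$hemisphere_map[c("mca_R", "aca_R", "pca_R")]),
                  "right")
  expect_true(all(net$segments$L > 0))
  expect_true(all(net$segments$r0 > 0 & net$segments$r1 > 0))
  # segments connect distinct nodes
  expect_true(all(net$segments$prox != net$segments$dist))
})

test_that("a configuration without a complete Circle of Willis is rejected", {
  cfg <- network_template()
  cfg$segments <- cfg$segments[cfg$segments$name != "acoa", ]
  expect_error(build_baseline_network(cfg), "acoa")
})

test_that("network construction is deterministic", {
  a <- network_to_json(build_baseline_network())
  b <- network_to_json(build_baseline_network())
  expect_identical(as.character(a), as.character(b))
})

test_that("applying a stenosis shapes the throat and leaves the rest intact", {
  net <- ef_net()
  expect_identical(apply_stenosis(net, stenosis_spec("left", 0)), net)
  st <- apply_stenosis(net, stenosis_spec("left", 85))
  i <- match("ica_L", st$segments$name)
  sg <- st$segments[i, ]
  expect_equal(segment_radius(st, "ica_L", sg$sten_center),
               sg$r_ref * 0.15, tolerance = 1e-10)
  expect_equal(sg$r_ref * 0.15, 0.45, tolerance = 0.02)  # r_ref ~ 3 mm
  # outside the stenosis length the radius profile is untouched
  s_out <- sg$sten_center + sg$sten_length / 2 + 1
  expect_equal(segment_radius(st, "ica_L", s_out),
               segment_radius(net, "ica_L", s_out))
  expect_identical(st$segments[-i, ], net$segments[-i, ])
  expect_error(apply_stenosis(net, stenosis_spec("left", 50,
                                                 site_segment = "basilar")),
               "carotid")
})

test_that("stenosis severity is monotone in throat radius and length", {
  net <- ef_net()
  sev <- c(10, 25, 40, 50, 70, 85)
  throat <- vapply(sev, function(p) {
    st <- apply_stenosis(net, stenosis_spec("right", p))
    sg <- st$segments[match("ica_R", st$segments$name), ]
    segment_radius(st, "ica_R", sg$sten_center)
  }, numeric(1))
  len <- vapply(sev, function(p) {
    st <- apply_stenosis(net, stenosis_spec("right", p))
    st$segments$sten_length[match("ica_R", st$segments$name)]
  }, numeric(1))
  expect_true(all(diff(throat) < 0))
  expect_true(all(diff(len) > 0))
})

test_that("full occlusion flags the segment and the CoW keeps outlets reachable", {
  net <- ef_net()
  occ <- apply_stenosis(net, stenosis_spec("left", 100))
  i <- match("ica_L", occ$segments$name)
  expect_true(occ$segments$occluded[i])
  expect_equal(segment_radius(occ, "ica_L", 10), 0)
  # downstream cerebral outlets still connected (via AcoA / PcoA)
  expect_silent(emboflow:::.check_connected(occ))
})

test_that("left stenosis on the symmetric baseline mirrors a right stenosis", {
  sym <- build_baseline_network(network_template(symmetric_arch = TRUE))
  a <- apply_stenosis(sym, stenosis_spec("left", 70))
  b <- mirror_network(apply_stenosis(sym, stenosis_spec("right", 70)))
  cols <- c("L", "r0", "r1", "severity", "sten_center", "sten_length",
            "occluded")
  sa <- a$segments[order(a$segments$name), cols]
  sb <- b$segments[order(b$segments$name), cols]
  rownames(sa) <- rownames(sb) <- NULL
  expect_equal(sa, sb, tolerance = 1e-12)
  # endpoint geometry matches up to segment orientation
  ends <- function(net) {
    sg <- net$segments[order(net$segments$name), ]
    lapply(seq_len(nrow(sg)), function(i) {
      e1 <- round(c(sg$gx0[i], sg$gy0[i], sg$gz0[i]), 9) + 0
      e2 <- round(c(sg$gx1[i], sg$gy1[i], sg$gz1[i]), 9) + 0
      if (paste(e1, collapse = ",") <= paste(e2, collapse = ","))
        c(e1, e2) else c(e2, e1)
    })
  }
  expect_equal(ends(a), ends(b), tolerance = 1e-9)
})

test_that("model family enumeration reproduces the 30-model / 78-experiment design", {
  models <- enumerate_models()
  expect_equal(nrow(models), 30)
  expect_equal(sum(!models$is_cco), 18)
  expect_equal(sum(models$is_cco), 12)
  expect_true("10L50R" %in% models$label)
  expect_false(anyDuplicated(models$label) > 0)
  exps <- enumerate_experiments(models)
  expect_equal(nrow(exps), 78)
  expect_equal(sum(exps$n), 429000)
  expect_false(anyDuplicated(exps$seed) > 0)
  # CCO models never release from the occluded side
  cco <- exps[exps$is_cco, ]
  expect_false(any(cco$left >= 100 & cco$source == "left_carotid"))
  expect_false(any(cco$right >= 100 & cco$source == "right_carotid"))
  expect_true(all(table(exps$label[exps$is_cco]) == 2))
  expect_true(all(table(exps$label[!exps$is_cco]) == 3))
})

test_that("enumeration counts match brute force for arbitrary severity sets", {
  cases <- list(list(mild = 10, severe = 50),
                list(mild = c(10, 25), severe = c(50, 70, 85)),
                list(mild = c(10, 25, 40), severe = 70))
  for (cs in cases) {
    m <- enumerate_models(cs$mild, cs$severe, cco = TRUE)
    nb <- 2 * length(cs$mild) * length(cs$severe)
    nc <- 2 * (length(cs$mild) + length(cs$severe))
    expect_equal(nrow(m), nb + nc)
    e <- enumerate_experiments(m, n_per_source = 100)
    expect_equal(nrow(e), 3 * nb + 2 * nc)
  }
  expect_equal(nrow(enumerate_models(10, 50, cco = FALSE)), 2)
  expect_setequal(enumerate_models(10, 50, cco = FALSE)$label,
                  c("10L50R", "50L10R"))
  expect_equal(nrow(enumerate_models(numeric(0), numeric(0))), 0)
  expect_equal(nrow(enumerate_experiments(enumerate_models(numeric(0),
                                                           numeric(0)))), 0)
  expect_error(enumerate_models(c(10, 50), c(50, 70)), "overlap")
})
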