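mk_record <- function(counts, n = sum(counts) + unresolved, unresolved = 0,
                      source = "left_carotid", label = "10L85R") {
  all_out <- c("aca_L", "aca_R", "desc_aorta", "eca_L", "eca_R", "mca_L",
               "mca_R", "pca_L", "pca_R", "sub_L", "sub_R")
  cc <- stats::setNames(integer(length(all_out)), all_out)
  cc[names(counts)] <- counts
  structure(list(label = label, source = source, seed = 1, n = n,
                 counts = cc, unresolved = unresolved, extended = FALSE,
                 above_threshold = FALSE, cycles = 10),
            class = "distribution_record")
}

hm <- c(aca_L = "left", aca_R = "right", desc_aorta = "none", eca_L = "none",
        eca_R = "none", mca_L = "left", mca_R = "right", pca_L = "left",
        pca_R = "right", sub_L = "none", sub_R = "none")

test_that("outlet number fractions divide counts by released emboli", {
  r <- mk_record(c(mca_L = 50, mca_R = 50))
  d <- outlet_distribution(r)
  expect_equal(unname(d$fractions[c("mca_L", "mca_R")]), c(0.5, 0.5))
  expect_equal(sum(d$fractions) + d$unresolved, 1)
  r2 <- mk_record(integer(0), n = 40, unresolved = 40)
  d2 <- outlet_distribution(r2)
  expect_equal(sum(d2$fractions), 0)
  expect_equal(d2$unresolved, 1)
  expect_error(outlet_distribution(mk_record(integer(0), n = 0)), "empty")
})

test_that("hemispheric split separates the six cerebral outlets", {
  r <- mk_record(c(mca_L = 30, aca_L = 10, pca_L = 10,
                   mca_R = 25, aca_R = 15, pca_R = 10, desc_aorta = 500))
  hs <- hemisphere_split(r, hm)
  expect_equal(hs$left, 50)
  expect_equal(hs$right, 50)
  expect_equal(hs$cerebral_count, 100)
  all_left <- hemisphere_split(mk_record(c(mca_L = 7, aca_L = 3)), hm)
  expect_equal(all_left$left, 100)
  expect_equal(all_left$right, 0)
  expect_warning(hemisphere_split(mk_record(c(desc_aorta = 10)), hm),
                 "undefined")
})

test_that("contralateral fraction counts cerebral-destined crossings only", {
  r <- mk_record(c(mca_L = 80, aca_L = 15, mca_R = 5, desc_aorta = 200))
  expect_equal(contralateral_fraction(r, "left", hm), 0.05)
  expect_equal(contralateral_fraction(r, "right", hm), 0.95)
  ipsi <- mk_record(c(mca_L = 60, aca_L = 40))
  expect_equal(contralateral_fraction(ipsi, "left", hm), 0)
  # mirror symmetry: mirrored record with flipped side gives the same value
  mir <- mk_record(c(mca_R = 80, aca_R = 15, mca_L = 5, desc_aorta = 200))
  expect_equal(contralateral_fraction(mir, "right", hm),
               contralateral_fraction(r, "left", hm))
  cardio <- mk_record(c(mca_L = 10), source = "cardiogenic")
  expect_error(contralateral_fraction(cardio, "left", hm), "cardiogenic")
})

test_that("CCA recruitment split counts pathway membership", {
  visited <- c(replicate(60, c("asc_aorta", "brachiocephalic", "cca_R",
                               "ica_R"), simplify = FALSE),
               replicate(40, c("asc_aorta", "cca_L", "ica_L"),
                         simplify = FALSE),
               replicate(20, c("asc_aorta", "desc_aorta"), simplify = FALSE))
  cc <- cca_recruitment_split(visited)
  expect_equal(cc$right_pct, 60)
  expect_equal(cc$left_pct, 40)
  expect_equal(cc$n_excluded, 20)
  none <- cca_recruitment_split(replicate(5, "asc_aorta", simplify = FALSE))
  expect_equal(none$left_pct, 0)
  expect_equal(none$right_pct, 0)
  expect_equal(none$n_excluded, 5)
})

test_that("descriptive statistics use the sample (n-1) standard deviation", {
  d <- descriptive_stats(c(2, 4, 4, 4, 5, 5, 7, 9))
  expect_equal(d$mean, 5)
  expect_equal(d$sd, 2.138, tolerance = 1e-3)
  expect_equal(d$cv, d$sd / 5)
  const <- descriptive_stats(rep(4, 6))
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)
  scaled <- descriptive_stats(3 * c(2, 4, 4, 4, 5, 5, 7, 9))
  expect_equal(scaled$sd, 3 * d$sd)
  expect_equal(scaled$cv, d$cv)
  expect_warning(descriptive_stats(c(-1, 1)), "zero")
})

test_that("the one-sample signed-rank test matches the extreme-rank closed form", {
  x <- seq(0.5, 9, length.out = 18)  # 18 strictly positive values
  res <- stats_tests(x, test = "wilcoxon_one_sample", hypothesized_value = 0,
                     alternative = "greater")
  expect_equal(res$p_value, 2^-18, tolerance = 1e-10)
  deg <- stats_tests(rep(0, 10), test = "wilcoxon_one_sample")
  expect_true(deg$degenerate)
})

test_that("the Mann-Whitney test agrees with an exhaustive enumeration oracle", {
  a <- c(1.2, 2.4, 3.1, 4.8, 5.5)        # n = 5
  b <- c(6.1, 7.2, 7.9, 8.4, 9.9, 11.0)  # m = 6, fully separated
  for (alt in c("two.sided", "greater", "less")) {
    res <- stats_tests(a, b, test = "mann_whitney_u", alternative = alt)
    expect_equal(res$p_value, ef_mw_exact(a, b, alt), tolerance = 1e-10)
  }
  # interleaved groups
  a2 <- c(1, 3, 6, 8); b2 <- c(2, 4, 5, 7, 9)
  expect_equal(stats_tests(a2, b2, test = "mann_whitney_u")$p_value,
               ef_mw_exact(a2, b2), tolerance = 1e-10)
  # identical groups: two-sided p at 1 under the midrank convention
  ident <- suppressWarnings(
    stats_tests(c(1, 2, 3, 4), c(1, 2, 3, 4), test = "mann_whitney_u"))
  expect_gt(ident$p_value, 0.99)
})

test_that("the Shapiro-Wilk test flags clearly non-normal data", {
  set.seed(42)
  normal <- stats_tests(rnorm(50), test = "shapiro_wilk")
  expect_gt(normal$p_value, 0.01)
  skewed <- stats_tests(rexp(50)^2, test = "shapiro_wilk")
  expect_lt(skewed$p_value, 1e-4)
})

test_that("campaign summaries key one row per experiment with valid fractions", {
  recs <- list(a = mk_record(c(mca_L = 40, mca_R = 10), label = "10L85R"),
               b = mk_record(c(mca_L = 25, mca_R = 25),
                             source = "cardiogenic", label = "10L85R"))
  sm <- summarize_campaign(recs, ef_net())
  expect_equal(nrow(sm), 2)
  expect_true(all(sm$left_pct >= 0 & sm$left_pct <= 100))
  expect_equal(sm$contralateral[sm$source == "left_carotid"], 0.2)
  expect_true(is.na(sm$contralateral[sm$source == "cardiogenic"]))
})
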