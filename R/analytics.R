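.cerebral_outlets <- c("mca_L", "mca_R", "aca_L", "aca_R", "pca_L", "pca_R")

#' Outlet number fractions of a distribution record
#'
#' `fraction_i = count_i / n_released`; the unresolved fraction is reported
#' separately. Fractions plus the unresolved fraction sum to one.
#'
#' @param record a `distribution_record`.
#' @return list with `fractions` (named over the 11 outlets) and
#'   `unresolved`.
#' @export
outlet_distribution <- function(record) {
  if (record$n == 0) stop("empty record: no emboli released")
  list(fractions = record$counts / record$n,
       unresolved = record$unresolved / record$n)
}

#' Hemispheric split of cerebral emboli
#'
#' Left percentage = (L-MCA + L-ACA + L-PCA) / (all six cerebral outlets);
#' right is the complement.
#'
#' @param record a `distribution_record`.
#' @param hemisphere_map named outlet-to-hemisphere map (from the network).
#' @return list with `left` and `right` percentages and the cerebral count.
#' @export
hemisphere_split <- function(record, hemisphere_map) {
  cer <- record$counts[.cerebral_outlets]
  tot <- sum(cer)
  if (tot == 0) {
    warning("no cerebral-destined emboli; hemispheric split undefined")
    return(list(left = NA_real_, right = NA_real_, cerebral_count = 0))
  }
  left <- sum(cer[hemisphere_map[.cerebral_outlets] == "left"])
  list(left = 100 * left / tot, right = 100 * (tot - left) / tot,
       cerebral_count = tot)
}

#' Contralateral fraction of a carotid release
#'
#' Fraction of cerebral-destined emboli that landed in the hemisphere
#' opposite the release carotid (the denominator is the emboli reaching the
#' six cerebral outlets, not all released emboli).
#'
#' @param record a `distribution_record`.
#' @param release_side `"left"` or `"right"`.
#' @param hemisphere_map named outlet-to-hemisphere map.
#' @return proportion in `[0, 1]` (NA with a warning if no emboli reached the
#'   cerebral outlets).
#' @export
contralateral_fraction <- function(record, release_side = c("left", "right"),
                                   hemisphere_map) {
  release_side <- match.arg(release_side)
  if (!is.null(record$source) && record$source == "cardiogenic")
    stop("contralateral fraction is undefined for a cardiogenic source")
  cer <- record$counts[.cerebral_outlets]
  tot <- sum(cer)
  if (tot == 0) {
    warning("no cerebral-destined emboli; contralateral fraction undefined")
    return(NA_real_)
  }
  opposite <- if (release_side == "left") "right" else "left"
  sum(cer[hemisphere_map[.cerebral_outlets] == opposite]) / tot
}

#' Common carotid recruitment split of cardiogenic emboli
#'
#' Fraction of cardiogenic emboli whose path entered the left vs right common
#' carotid artery (emboli entering neither are excluded from the split and
#' reported separately).
#'
#' @param visited list of ordered visited-segment name vectors (one per
#'   trajectory), e.g. from an `experiment_result`.
#' @return list with `left_pct`, `right_pct` (of CCA-entering emboli),
#'   `n_left`, `n_right`, `n_excluded`.
#' @export
cca_recruitment_split <- function(visited) {
  inl <- vapply(visited, function(v) "cca_L" %in% v, logical(1))
  inr <- vapply(visited, function(v) "cca_R" %in% v, logical(1))
  n_left <- sum(inl); n_right <- sum(inr & !inl)
  n_cca <- n_left + n_right
  list(left_pct = if (n_cca > 0) 100 * n_left / n_cca else 0,
       right_pct = if (n_cca > 0) 100 * n_right / n_cca else 0,
       n_left = n_left, n_right = n_right,
       n_excluded = length(visited) - n_cca)
}

#' Descriptive statistics
#'
#' Mean, sample standard deviation (n-1 denominator) and coefficient of
#' variation.
#'
#' @param values numeric vector (length >= 2).
#' @return list with `mean`, `sd`, `cv`.
#' @export
descriptive_stats <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values); s <- stats::sd(values)
  cv <- if (abs(m) < .Machine$double.eps^0.5) {
    warning("mean is zero; coefficient of variation undefined")
    NA_real_
  } else s / m
  list(mean = m, sd = s, cv = cv)
}

#' Non-parametric hypothesis tests
#'
#' Thin dispatch over the tests used for distribution comparisons: one-sample
#' Wilcoxon signed-rank against a hypothesized median, two-sample
#' Mann-Whitney (Wilcoxon rank-sum), and Shapiro-Wilk normality. Exact
#' small-sample p-values are used where the implementation supports them
#' (signed-rank n <= 49 and rank-sum n*m without ties), a normal
#' approximation with tie correction otherwise.
#'
#' @param group_a numeric vector.
#' @param group_b numeric vector (Mann-Whitney only), else `NULL`.
#' @param test one of `"wilcoxon_one_sample"`, `"mann_whitney_u"`,
#'   `"shapiro_wilk"`.
#' @param hypothesized_value null-median for the one-sample test.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return list with `statistic`, `p_value`, `method`, `degenerate` flag.
#' @export
stats_tests <- function(group_a, group_b = NULL,
                        test = c("wilcoxon_one_sample", "mann_whitney_u",
                                 "shapiro_wilk"),
                        hypothesized_value = 0,
                        alternative = "two.sided") {
  test <- match.arg(test)
  out <- switch(test,
    wilcoxon_one_sample = {
      if (all(group_a == hypothesized_value))
        return(list(statistic = NA_real_, p_value = NA_real_,
                    method = "wilcoxon_one_sample", degenerate = TRUE))
      ht <- stats::wilcox.test(group_a, mu = hypothesized_value,
                               alternative = alternative)
      list(statistic = unname(ht$statistic), p_value = ht$p.value,
           method = "wilcoxon_one_sample", degenerate = FALSE)
    },
    mann_whitney_u = {
      if (is.null(group_b)) stop("mann_whitney_u requires two groups")
      ht <- stats::wilcox.test(group_a, group_b, alternative = alternative)
      list(statistic = unname(ht$statistic), p_value = ht$p.value,
           method = "mann_whitney_u", degenerate = FALSE)
    },
    shapiro_wilk = {
      ht <- stats::shapiro.test(group_a)
      list(statistic = unname(ht$statistic), p_value = ht$p.value,
           method = "shapiro_wilk", degenerate = FALSE)
    })
  out
}

#' Summarize a campaign into the per-experiment analysis table
#'
#' One row per completed experiment: outlet fractions aggregated to
#' hemisphere percentages, the contralateral fraction for carotid sources,
#' and the unresolved fraction.
#'
#' @param campaign a `campaign_result` (or plain list of
#'   `distribution_record`s).
#' @param network the baseline `vessel_network` (for the hemisphere map).
#' @return data.frame keyed by model label and source.
#' @export
summarize_campaign <- function(campaign, network) {
  records <- if (inherits(campaign, "campaign_result")) campaign$records
             else campaign
  hm <- network$hemisphere_map
  rows <- lapply(records, function(r) {
    hs <- suppressWarnings(hemisphere_split(r, hm))
    side <- if (r$source == "left_carotid") "left"
            else if (r$source == "right_carotid") "right" else NA
    cf <- if (!is.na(side))
      suppressWarnings(contralateral_fraction(r, side, hm)) else NA_real_
    data.frame(label = r$label, source = r$source, n = r$n,
               cerebral = hs$cerebral_count,
               left_pct = hs$left, right_pct = hs$right,
               contralateral = cf,
               unresolved_frac = r$unresolved / r$n,
               extended = r$extended, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
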