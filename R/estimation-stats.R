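# Estimation statistics: unpaired mean differences with BCa bootstrap
# confidence intervals (shared-control and two-group designs), plus the
# null-hypothesis layer (normality-routed omnibus + post hoc tests) and
# Tukey box statistics.

#' Unpaired mean difference with a BCa bootstrap confidence interval
#'
#' The estimate is `mean(b) - mean(a)`. The interval is bias-corrected and
#' accelerated: the bias correction z0 is the normal quantile of the fraction
#' of resampled differences below the observed one; the acceleration is the
#' jackknife skewness of the statistic over delete-one resamples of both
#' groups. Identical `(seed, n_resamples)` reproduce the interval
#' bit-exactly. Resampling is within group (unpaired design); the resampling
#' unit is whatever the caller passes — for this pipeline, wells.
#'
#' @param a,b numeric samples (n >= 3 each)
#' @param n_resamples bootstrap resamples (default 5000)
#' @param seed integer RNG seed
#' @param conf confidence level (default 0.95)
#' @param group_a,group_b labels carried into the result
#' @return an `estimation_result`: one-row data.frame with `group_a`,
#'   `group_b`, `n_a`, `n_b`, `difference`, `ci_low`, `ci_high`,
#'   `n_resamples`, `seed`, `degenerate`
#' @examples
#' mean_difference_bca(c(1, 2, 3), c(2, 3, 4), n_resamples = 500, seed = 1)
#' @export
mean_difference_bca <- function(a, b, n_resamples = 5000L, seed = 1L,
                                conf = 0.95, group_a = "a", group_b = "b") {
  check_that(length(a) >= 3 && length(b) >= 3, "need n >= 3 per group")
  a <- as.numeric(a); b <- as.numeric(b)
  obs <- mean(b) - mean(a)
  res <- data.frame(group_a = group_a, group_b = group_b,
                    n_a = length(a), n_b = length(b), difference = obs,
                    ci_low = NA_real_, ci_high = NA_real_,
                    n_resamples = as.integer(n_resamples),
                    seed = as.integer(seed), degenerate = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    res$ci_low <- obs; res$ci_high <- obs; res$degenerate <- TRUE
    class(res) <- c("estimation_result", class(res))
    return(res)
  }
  set.seed(seed)
  B <- as.integer(n_resamples)
  boots_a <- colMeans(matrix(sample(a, length(a) * B, replace = TRUE),
                             nrow = length(a)))
  boots_b <- colMeans(matrix(sample(b, length(b) * B, replace = TRUE),
                             nrow = length(b)))
  diffs <- boots_b - boots_a
  # bias correction
  prop <- mean(diffs < obs)
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))  # keep z0 finite
  z0 <- stats::qnorm(prop)
  # acceleration from delete-one jackknife over both groups
  jk <- c(vapply(seq_along(a), function(i) mean(b) - mean(a[-i]), numeric(1)),
          vapply(seq_along(b), function(i) mean(b[-i]) - mean(a), numeric(1)))
  u <- mean(jk) - jk
  acc <- sum(u^3) / (6 * sum(u^2)^1.5)
  if (!is.finite(acc)) acc <- 0
  alpha <- (1 - conf) / 2
  zlo <- stats::qnorm(alpha); zhi <- stats::qnorm(1 - alpha)
  a1 <- stats::pnorm(z0 + (z0 + zlo) / (1 - acc * (z0 + zlo)))
  a2 <- stats::pnorm(z0 + (z0 + zhi) / (1 - acc * (z0 + zhi)))
  ci <- unname(stats::quantile(diffs, c(a1, a2), type = 7))
  res$ci_low <- ci[1]; res$ci_high <- ci[2]
  class(res) <- c("estimation_result", class(res))
  res
}

#' Shared-control estimation design
#'
#' One BCa mean difference per non-control group against the common control
#' (the layout of a Cumming plot). Every comparison uses the same resample
#' count; each pair's seed is derived from the master seed and the group
#' label via [derive_seed()], so results are invariant to group order.
#'
#' @param values numeric vector of observations
#' @param groups group label per observation
#' @param control_label label of the shared control group
#' @param n_resamples,conf passed to [mean_difference_bca()]
#' @param seed master seed
#' @return data.frame of stacked `estimation_result` rows (control vs each
#'   other group, difference = group - control)
#' @export
shared_control_design <- function(values, groups, control_label,
                                  n_resamples = 5000L, seed = 1L,
                                  conf = 0.95) {
  groups <- as.character(groups)
  check_that(control_label %in% groups,
             "control group '%s' not present", control_label)
  # canonical within-group order makes the resampling stream, and hence the
  # intervals, invariant to how the input rows were ordered
  ctrl <- sort(values[groups == control_label])
  others <- setdiff(unique(groups), control_label)
  out <- lapply(sort(others), function(g) {
    mean_difference_bca(ctrl, sort(values[groups == g]),
                        n_resamples = n_resamples,
                        seed = derive_seed(seed, g), conf = conf,
                        group_a = control_label, group_b = g)
  })
  do.call(rbind, out)
}

#' Vulnerable-vs-resilient class comparison
#'
#' Groups observations into the two disease-vulnerability classes, runs an
#' independent two-group Mann-Whitney U test (exact when the combined n is at
#' most 20 and there are no ties, normal approximation with tie correction
#' otherwise) and computes the Gardner-Altman-style two-group BCa mean
#' difference alongside.
#'
#' @param values numeric vector
#' @param groups population label per observation (e.g. SNc, VTA, ...)
#' @param class_map named character vector mapping population label to
#'   `"vulnerable"` or `"resilient"`; the default encodes SNc, LC, R, DMV as
#'   vulnerable and VTA, XII, STR as resilient
#' @param n_resamples,seed passed to [mean_difference_bca()]
#' @return list with `test` (one-row data.frame: statistic, p, exact) and
#'   `estimation` (`estimation_result`, difference = resilient - vulnerable)
#' @export
class_comparison <- function(values, groups,
                             class_map = vulnerability_classes(),
                             n_resamples = 5000L, seed = 1L) {
  cls <- unname(class_map[as.character(groups)])
  check_that(!anyNA(cls), "unmapped population label(s): %s",
             paste(unique(groups[is.na(cls)]), collapse = ", "))
  v <- values[cls == "vulnerable"]; r <- values[cls == "resilient"]
  check_that(length(v) > 0 && length(r) > 0, "both classes must be non-empty")
  n_tot <- length(v) + length(r)
  has_ties <- anyDuplicated(c(v, r)) > 0
  exact <- n_tot <= 20 && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(v, r, exact = exact,
                                            correct = !exact))
  est <- mean_difference_bca(v, r, n_resamples = n_resamples, seed = seed,
                             group_a = "vulnerable", group_b = "resilient")
  list(test = data.frame(test = "mann_whitney_u",
                         statistic = unname(wt$statistic),
                         p = wt$p.value, exact = exact,
                         n_vulnerable = length(v), n_resilient = length(r)),
       estimation = est)
}

#' Population-to-class map for the vulnerability contrast
#' @return named character vector
#' @export
vulnerability_classes <- function() {
  c(SNc = "vulnerable", LC = "vulnerable", R = "vulnerable",
    DMV = "vulnerable",
    VTA = "resilient", XII = "resilient", STR = "resilient")
}

#' Omnibus test with routed post hoc comparisons
#'
#' Routes on a per-group Shapiro-Wilk normality screen at alpha 0.05 (the
#' declared convention for "evaluating whether the data are parametric"):
#' all groups normal leads to one-way ANOVA plus Tukey HSD; otherwise
#' Kruskal-Wallis plus pairwise Mann-Whitney with Bonferroni adjustment.
#' Either route can be forced with `route`.
#'
#' @param values numeric vector
#' @param groups group label per observation (>= 2 groups, each n >= 3)
#' @param route `"auto"` (default), `"parametric"` or `"nonparametric"`
#' @return data.frame of test rows: `test`, `comparison`, `statistic`,
#'   `p_raw`, `p_adjusted`, `adjustment`, `route`
#' @export
omnibus_and_posthoc <- function(values, groups,
                                route = c("auto", "parametric",
                                          "nonparametric")) {
  route <- match.arg(route)
  groups <- factor(groups)
  check_that(nlevels(groups) >= 2, "need >= 2 groups")
  sizes <- table(groups)
  check_that(all(sizes >= 3), "every group needs n >= 3")
  if (route == "auto") {
    shapiro_p <- vapply(levels(groups), function(g) {
      v <- values[groups == g]
      if (stats::var(v) == 0) return(0)      # degenerate: treat as non-normal
      stats::shapiro.test(v)$p.value
    }, numeric(1))
    route <- if (all(shapiro_p > 0.05)) "parametric" else "nonparametric"
  }
  if (route == "parametric") {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    omni <- data.frame(test = "one_way_anova", comparison = "omnibus",
                       statistic = an[["F value"]][1],
                       p_raw = an[["Pr(>F)"]][1],
                       p_adjusted = an[["Pr(>F)"]][1],
                       adjustment = "none", route = route)
    tk <- stats::TukeyHSD(fit)$groups
    post <- data.frame(test = "tukey_hsd", comparison = rownames(tk),
                       statistic = tk[, "diff"], p_raw = tk[, "p adj"],
                       p_adjusted = tk[, "p adj"], adjustment = "tukey",
                       route = route)
  } else {
    kw <- stats::kruskal.test(values, groups)
    omni <- data.frame(test = "kruskal_wallis", comparison = "omnibus",
                       statistic = unname(kw$statistic),
                       p_raw = kw$p.value, p_adjusted = kw$p.value,
                       adjustment = "none", route = route)
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2)
    raw <- apply(pairs, 2, function(pr) {
      suppressWarnings(stats::wilcox.test(values[groups == pr[1]],
                                          values[groups == pr[2]]))$p.value
    })
    post <- data.frame(test = "pairwise_mann_whitney",
                       comparison = paste(pairs[2, ], pairs[1, ], sep = "-"),
                       statistic = NA_real_, p_raw = raw,
                       p_adjusted = stats::p.adjust(raw, "bonferroni"),
                       adjustment = "bonferroni", route = route)
  }
  out <- rbind(omni, post)
  rownames(out) <- NULL
  out
}

#' Tukey box-and-whisker statistics
#'
#' Median, hinges as the linear-interpolation (type-7) 25th/75th percentiles,
#' and whiskers at the most extreme data values no further than 1.5 IQR
#' beyond the hinges.
#'
#' @param x numeric sample (n >= 5)
#' @return data.frame with `whisker_low`, `lower_hinge`, `median`,
#'   `upper_hinge`, `whisker_high`, `n`, `quartile_type`
#' @examples
#' tukey_box(1:100)
#' @export
tukey_box <- function(x) {
  check_that(length(x) >= 5, "need n >= 5")
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_candidates <- x[x >= q[1] - 1.5 * iqr]
  hi_candidates <- x[x <= q[3] + 1.5 * iqr]
  data.frame(whisker_low = min(lo_candidates), lower_hinge = q[1],
             median = q[2], upper_hinge = q[3],
             whisker_high = max(hi_candidates), n = length(x),
             quartile_type = "type7_linear_interpolation")
}
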