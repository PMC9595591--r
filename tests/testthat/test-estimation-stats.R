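test_that("mean difference is exact and the interval is reproducible", {
  r <- mean_difference_bca(c(1, 2, 3), c(2, 3, 4), n_resamples = 500,
                           seed = 1)
  expect_equal(r$difference, 1)

  same <- mean_difference_bca(c(1, 2, 3), c(1, 2, 3), n_resamples = 500,
                              seed = 2)
  expect_equal(same$difference, 0)
  expect_lte(same$ci_low, 0); expect_gte(same$ci_high, 0)

  a <- rnorm(15); b <- rnorm(15, 1)
  r1 <- mean_difference_bca(a, b, n_resamples = 2000, seed = 99)
  r2 <- mean_difference_bca(a, b, n_resamples = 2000, seed = 99)
  expect_identical(r1, r2)
  r3 <- mean_difference_bca(a, b, n_resamples = 2000, seed = 100)
  expect_false(identical(r1$ci_low, r3$ci_low))

  degen <- mean_difference_bca(rep(2, 5), rep(7, 5), seed = 1)
  expect_true(degen$degenerate)
  expect_equal(c(degen$ci_low, degen$ci_high), c(5, 5))

  expect_error(mean_difference_bca(1:2, 1:5), "n >= 3")
})

test_that("BCa reduces to the percentile interval on a symmetric case", {
  # symmetric samples: jackknife skewness (acceleration) is exactly 0 and
  # the bias correction is near 0, so BCa ~ percentile
  a <- seq(-2, 2, length.out = 21)
  b <- seq(-1.5, 2.5, length.out = 21)
  r <- mean_difference_bca(a, b, n_resamples = 4000, seed = 7)
  set.seed(7)
  B <- 4000
  boots_a <- colMeans(matrix(sample(a, length(a) * B, replace = TRUE),
                             nrow = length(a)))
  boots_b <- colMeans(matrix(sample(b, length(b) * B, replace = TRUE),
                             nrow = length(b)))
  diffs <- boots_b - boots_a
  perc <- unname(quantile(diffs, c(0.025, 0.975), type = 7))
  scale <- diff(perc)
  expect_lt(abs(r$ci_low - perc[1]) / scale, 0.05)
  expect_lt(abs(r$ci_high - perc[2]) / scale, 0.05)
})

test_that("BCa interval agrees with the boot package on the same problem", {
  skip_if_not_installed("boot")
  set.seed(9)
  a <- rnorm(20); b <- rnorm(20, 0.5)
  r <- mean_difference_bca(a, b, n_resamples = 9999, seed = 2)
  dat <- data.frame(v = c(a, b), g = rep(1:2, each = 20))
  bt <- boot::boot(dat, function(d, i) {
    d2 <- d[i, ]; mean(d2$v[d2$g == 2]) - mean(d2$v[d2$g == 1])
  }, R = 9999, strata = dat$g)
  ci <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  sd_scale <- sd(c(a, b))
  expect_lt(abs(r$ci_low - ci[1]) / sd_scale, 0.1)
  expect_lt(abs(r$ci_high - ci[2]) / sd_scale, 0.1)
})

test_that("shared-control design is order-invariant and complete", {
  set.seed(5)
  groups <- rep(c("SNc", "VTA", "LC", "R", "DMV", "XII", "STR"), each = 6)
  values <- rnorm(length(groups)) + (groups == "VTA")
  r <- shared_control_design(values, groups, "SNc", n_resamples = 500,
                             seed = 11)
  expect_equal(nrow(r), 6)
  expect_setequal(r$group_b, setdiff(unique(groups), "SNc"))
  # permuting input order leaves each labeled comparison identical
  p <- sample(length(values))
  r2 <- shared_control_design(values[p], groups[p], "SNc",
                              n_resamples = 500, seed = 11)
  r2 <- r2[match(r$group_b, r2$group_b), ]
  expect_equal(r$ci_low, r2$ci_low)
  expect_equal(r$difference, r2$difference)
  expect_error(shared_control_design(values, groups, "nope"), "control")
  # control against itself: difference exactly 0
  self <- mean_difference_bca(values[groups == "SNc"],
                              values[groups == "SNc"], n_resamples = 200,
                              seed = 1)
  expect_equal(self$difference, 0)
})

test_that("Mann-Whitney class comparison matches exact enumeration", {
  # complete separation, 5 + 5: two-sided exact p = 2/252
  v <- c(1, 2, 3, 4, 5); r <- c(10, 11, 12, 13, 14)
  cc <- class_comparison(c(v, r), c(rep("SNc", 5), rep("VTA", 5)),
                         n_resamples = 200, seed = 1)
  expect_equal(cc$test$p, 2 / 252, tolerance = 1e-12)
  expect_true(cc$test$exact)

  # agreement with full enumeration for several small samples without ties
  set.seed(21)
  for (i in 1:5) {
    x <- round(rnorm(5), 3); y <- round(rnorm(6, 0.4), 3)
    cc2 <- class_comparison(c(x, y), c(rep("LC", 5), rep("STR", 6)),
                            n_resamples = 200, seed = i)
    expect_equal(cc2$test$p, mw_exact_p_enumeration(x, y), tolerance = 1e-10)
  }

  # rank invariance under adding a constant
  cc3 <- class_comparison(c(v, r) + 100, c(rep("SNc", 5), rep("VTA", 5)),
                          n_resamples = 200, seed = 1)
  expect_equal(cc3$test$statistic, cc$test$statistic)
  expect_equal(cc3$test$p, cc$test$p)

  # identical class distributions: U at midpoint, large p
  same <- class_comparison(rep(c(1, 2, 3, 4), 2),
                           c(rep("SNc", 4), rep("VTA", 4)),
                           n_resamples = 200, seed = 2)
  expect_equal(same$test$statistic, 8)   # n1 n2 / 2
  expect_gt(same$test$p, 0.9)

  expect_error(class_comparison(1:4, c("SNc", "SNc", "LC", "R")),
               "non-empty")
})

test_that("omnibus routing and Bonferroni adjustment behave as declared", {
  set.seed(33)
  g <- rep(c("a", "b", "c"), each = 20)
  v_null <- rnorm(60)
  res <- omnibus_and_posthoc(v_null, g)
  expect_gt(res$p_raw[res$comparison == "omnibus"], 0.05)

  v_sep <- v_null + 5 * (g == "b")
  res2 <- omnibus_and_posthoc(v_sep, g)
  expect_lt(res2$p_raw[res2$comparison == "omnibus"], 0.001)
  b_rows <- grepl("b", res2$comparison) & res2$comparison != "omnibus"
  expect_true(all(res2$p_adjusted[b_rows] < 0.001))

  # forced nonparametric route: adjusted p = min(1, m * raw)
  res3 <- omnibus_and_posthoc(v_sep, g, route = "nonparametric")
  post <- res3[res3$test == "pairwise_mann_whitney", ]
  expect_equal(post$p_adjusted, pmin(1, nrow(post) * post$p_raw))
  expect_true(all(post$p_adjusted >= post$p_raw))

  # skewed data routes nonparametric, normal data parametric
  set.seed(41)
  v_skew <- exp(rnorm(60, sd = 1.5))
  expect_equal(unique(omnibus_and_posthoc(v_skew, g)$route), "nonparametric")
  expect_equal(unique(omnibus_and_posthoc(v_null, g)$route), "parametric")

  expect_error(omnibus_and_posthoc(1:5, c("a", "a", "a", "b", "b")), "n >= 3")
})

test_that("Tukey box statistics follow the hinge and whisker definitions", {
  b <- tukey_box(1:100)
  expect_equal(b$median, 50.5)
  expect_equal(b$lower_hinge, 25.75)
  expect_equal(b$upper_hinge, 75.25)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 100)

  const <- tukey_box(rep(3, 10))
  expect_equal(unlist(const[1, 1:5], use.names = FALSE), rep(3, 5))

  # an extreme outlier is left beyond the whisker
  x <- c(1:20, 1000)
  bo <- tukey_box(x)
  expect_equal(bo$whisker_high, 20)
  expect_true(bo$whisker_high <= bo$upper_hinge + 1.5 *
                (bo$upper_hinge - bo$lower_hinge))
  expect_error(tukey_box(1:4), "n >= 5")
})
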