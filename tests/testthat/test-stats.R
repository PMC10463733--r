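test_that("pooled two-sample t-test matches the textbook formula", {
  # delta mean 1, pooled sd sqrt(2.5), SE 1 -> t = -1
  r <- two_sample_ttest(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(r$statistic, -1, tolerance = 1e-12)
  expect_equal(r$df, 8)
  expect_false(r$significant)
  # identical samples: t = 0, p = 1
  r0 <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # single-element sample errors
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
  # Welch variant runs and reports fractional df
  rw <- two_sample_ttest(c(1, 2, 3, 9), c(2, 2.1, 2.2), variant = "welch")
  expect_s3_class(tidy(rw), "tbl_df")
  expect_identical(rw$variant, "welch")
})

test_that("univariate regression is exact on noiseless lines", {
  # a noiseless line triggers R's perfect-fit warnings in summary(); they
  # are expected here
  r <- suppressWarnings(univariate_regression(1:10, 2 * (1:10) + 1))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  expect_error(univariate_regression(rep(2, 5), 1:5), "constant")
  expect_error(univariate_regression(1:2, 1:2), "at least 3")
  g <- glance(r)
  expect_equal(g$r.squared, 1)
  td <- suppressWarnings(tidy(r))
  expect_setequal(td$term, c("(Intercept)", "x"))
})

test_that("OLS recovers a noisy slope within 3 standard errors", {
  set.seed(7)
  n <- 200; beta <- 0.8; sigma <- 0.5
  x <- runif(n, 0, 4)
  y <- beta * x + rnorm(n, 0, sigma)
  r <- univariate_regression(x, y)
  expect_lt(abs(r$slope - beta), 3 * r$slope_se)
  # confidence band contains the fit and is ordered
  band <- r$ci_band(seq(0, 4, by = 0.5))
  expect_true(all(band$lwr <= band$fit & band$fit <= band$upr))
})

test_that("leave-one-out report flags a single point driving significance", {
  # constructed example: no association in the bulk, one extreme point
  # (low x, high y) creates a significant negative slope
  set.seed(42)
  x <- c(rnorm(12, 10, 0.8), 3)
  y <- c(rnorm(12, 1, 0.12), 3)
  r <- univariate_regression(x, y)
  expect_true(r$significant)
  flagged <- r$leverage[r$leverage$flips_significance, ]
  expect_gte(nrow(flagged), 1)
  expect_true(13 %in% flagged$dropped)   # removing it removes significance
})

test_that("group summary reports mean +/- SD and flags significance", {
  tab <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:12),
    group = rep(c("control", "af"), each = 6),
    la_ef = c(rnorm(6, 53, 0.5), rnorm(6, 43, 0.5)),
    lv_ef = rep(67, 12))
  gs <- group_summary(tab, fields = c("la_ef", "lv_ef"))
  expect_true(gs$significant[gs$field == "la_ef"])
  expect_equal(gs$p_value[gs$field == "lv_ef"], 1)  # identical groups
  # missing value errors naming subject and field
  tab2 <- tab
  tab2$la_ef[3] <- NA
  expect_error(group_summary(tab2, fields = "la_ef"), "s03")
  expect_error(group_summary(tab[tab$group == "af", ], fields = "la_ef"),
               "nonempty")
})

test_that("shape subgroup analysis degrades gracefully at n = 1", {
  tab <- tibble::tibble(
    group = rep("af", 6),
    laa_shape_label = c(rep("chicken_wing", 5), "non_chicken_wing"),
    rt_la_with_laa = c(1.1, 1.2, 1.3, 1.2, 1.1, 1.15),
    rt_la_without_laa = c(1, 1.1, 1.2, 1.1, 1, 1.05),
    rt_laa = c(2.5, 2.7, 2.9, 2.6, 2.4, 2.55))
  res <- shape_subgroup_analysis(tab)
  expect_true(all(is.na(res$p_value)))     # n = 1 subgroup: no test
  expect_equal(res$n_non_cw[1], 1)
  # both subgroups >= 2: a p-value is produced
  tab2 <- tab
  tab2$laa_shape_label[5] <- "non_chicken_wing"
  res2 <- shape_subgroup_analysis(tab2)
  expect_true(all(is.finite(res2$p_value)))
  # all same label: descriptive only
  tab3 <- tab
  tab3$laa_shape_label <- "chicken_wing"
  res3 <- shape_subgroup_analysis(tab3)
  expect_true(all(is.na(res3$p_value)))
})

test_that("null subgroup split yields calibrated (uniform-ish) p-values", {
  # labels split 16/5 with identical RT distributions: p should not be
  # systematically small
  set.seed(123)
  ps <- replicate(400, {
    rt <- rnorm(21, 1.2, 0.3)
    two_sample_ttest(rt[1:16], rt[17:21])$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
  expect_gt(mean(ps), 0.4)
})
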