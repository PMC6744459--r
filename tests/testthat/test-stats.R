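test_that("two-group F equals the squared pooled t statistic", {
  set.seed(41)
  for (i in 1:5) {
    v1 <- rnorm(12, 0.4, 0.1)
    v2 <- rnorm(10, 0.5, 0.12)
    tab <- oneway_anova_table(make_metric_table(v1, v2), family = 1)
    tt <- t.test(v1, v2, var.equal = TRUE)
    expect_equal(tab$F, unname(tt$statistic)^2, tolerance = 1e-12)
    expect_equal(tab$p, tt$p.value, tolerance = 1e-12)
  }
})

test_that("Bonferroni correction and invariances behave as declared", {
  set.seed(42)
  v1 <- rnorm(8); v2 <- rnorm(8, 1)
  t1 <- oneway_anova_table(make_metric_table(v1, v2), family = 10)
  expect_equal(t1$p_corr, min(1, 10 * t1$p))
  expect_gte(t1$p_corr, t1$p)
  t2 <- oneway_anova_table(make_metric_table(v1, v2), family = 455)
  expect_lte(t2$significant, t1$significant)   # larger family, fewer hits
  # F invariant to adding a constant to every observation
  t3 <- oneway_anova_table(make_metric_table(v1 + 7, v2 + 7), family = 10)
  expect_equal(t3$F, t1$F, tolerance = 1e-10)
  expect_error(oneway_anova_table(make_metric_table(rnorm(1), rnorm(5))),
               "fewer than 2")
})

test_that("assumption checks detect unequal variances and flag degenerate groups", {
  set.seed(43)
  hits <- sum(vapply(1:5, function(i) {
    v <- c(rnorm(30, 0, 1), rnorm(30, 0, sqrt(10)))
    g <- rep(c("a", "b"), each = 30)
    assumption_checks(v, g)$levene_p < 0.05
  }, logical(1)))
  expect_gte(hits, 4)
  # equal-variance groups rarely rejected
  eq <- assumption_checks(c(rnorm(30), rnorm(30)),
                          rep(c("a", "b"), each = 30))
  expect_true(all(eq$normality_p > 0))
  dg <- assumption_checks(c(rep(1, 5), rnorm(5)),
                          rep(c("a", "b"), each = 5))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$levene_p))
  expect_error(assumption_checks(rnorm(4), c("a", "a", "b", "b")),
               "3 subjects")
})

test_that("contrast maps bin corrected p-values into signed tiers", {
  stats <- data.frame(
    unit = c("u1", "u2", "u3", "u4"), interval = "IV",
    F = 1, p = 1,
    p_corr = c(0.5, 0.04, 0.009, 0.0005),
    mean_a = c(1, 1, 1, 1), mean_b = c(2, 0.5, 2, 0.2),
    stringsAsFactors = FALSE
  )
  cm <- contrast_maps(stats)
  expect_equal(cm$tier, c(0, 1, 2, 3))
  expect_equal(cm$signed_tier, c(0, -1, 2, -3))
})
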