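test_that("coef_variation matches its definition and validates input", {
  expect_identical(coef_variation(c(2, 4, 6)), 0.5)
  expect_error(coef_variation(5), "at least 2")
  expect_error(coef_variation(c(-1, 1)), "zero mean")
  expect_identical(coef_variation(c(3, 3, 3)), 0)
})

test_that("levene_median_test handles degenerate input", {
  expect_error(levene_median_test(1:2, 1:5), "n >= 3")
  z <- levene_median_test(c(1, 1, 1), c(2, 2, 2))
  expect_identical(z$statistic, 0)
  expect_identical(z$p.value, 1)
})

test_that("levene_median_test agrees with the reference implementation", {
  skip_if_not_installed("car")
  set.seed(42)
  a <- rnorm(15, 0, 1); b <- rnorm(20, 0, 3)
  mine <- levene_median_test(a, b)
  ref <- car::leveneTest(c(a, b), factor(rep(1:2, c(15, 20))),
                         center = median)
  expect_equal(mine$statistic, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(mine$p.value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("percent_change validates and vectorises", {
  expect_error(percent_change(0, 1), "before > 0")
  expect_identical(percent_change(c(5, 6), c(3, 5)),
                   c(-40, 100 * (5 - 6) / 6))
})

test_that("paired_t_test matches stats::t.test and rejects zero variance", {
  set.seed(9)
  a <- rnorm(12); b <- a + rnorm(12, 0.3)
  mine <- paired_t_test(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  expect_error(paired_t_test(1:5, 1:5 + 2), "zero variance")
})

test_that("linear_regression drops non-finite pairs and flags degenerate x", {
  x <- c(1, 2, 3, 4, NA)
  y <- c(2.1, 3.9, 6.2, 7.8, 1)
  f <- linear_regression(x, y)
  expect_identical(f$n, 4L)
  ref <- oracle_ols(x[1:4], y[1:4])
  expect_equal(f$slope, ref$slope, tolerance = 1e-12)
  expect_equal(f$r.squared, ref$r.squared, tolerance = 1e-12)
  expect_error(linear_regression(rep(1, 5), rnorm(5)), "var\\(x\\)")
})

test_that("one_way_anova pairwise Holm-Sidak adjustment is monotone and bounded", {
  set.seed(5)
  gs <- list(a = rnorm(10, 0), b = rnorm(10, 1), c = rnorm(10, 2))
  out <- one_way_anova(gs, pairwise = TRUE)
  pw <- out$pairwise
  expect_identical(nrow(pw), 3L)
  expect_true(all(pw$p.adjusted >= pw$p.value - 1e-15))
  expect_true(all(pw$p.adjusted <= 1))
  # the adjusted values preserve the raw ordering
  expect_identical(order(pw$p.adjusted), order(pw$p.value))
  # single-step check of the smallest raw p: 1 - (1 - p)^m
  i <- which.min(pw$p.value)
  expect_equal(pw$p.adjusted[i], 1 - (1 - pw$p.value[i])^3, tolerance = 1e-12)
})
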