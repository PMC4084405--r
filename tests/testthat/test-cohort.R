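test_that("cohort generation is a pure function of config and seed", {
  cfg <- cohort_config()
  c1 <- generate_cohort(cfg, seed = 4)
  c2 <- generate_cohort(cfg, seed = 4)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_cohort(cfg, seed = 5)
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
  df <- as.data.frame(c1)
  expect_identical(nrow(df), 34L)
  expect_true(all(df$h >= cfg$h_floor))
  expect_true(all(df$d >= cfg$d_floor))
  expect_true(all(df$category %in%
                    c("antidromic-only", "mixed", "orthodromic-only")))
})

test_that("the population h distribution matches its nominal moments", {
  cfg <- cohort_config(n_animals = 2000)
  df <- as.data.frame(generate_cohort(cfg, seed = 1))
  expect_lt(abs(mean(df$h) - 2.9), 0.15)
  expect_lt(abs(sd(df$h) - 1.3), 0.1)
  # category split close to the observed 24.6 / 68.1 / 7.2 percent (the low
  # tail is slightly thinned by the truncation floor)
  frac <- table(df$category) / nrow(df)
  expect_lt(abs(frac[["antidromic-only"]] - 0.246), 0.04)
  expect_lt(abs(frac[["orthodromic-only"]] - 0.072), 0.04)
})

test_that("lesion loss grows with h and stays within bounds", {
  set.seed(2)
  lo <- replicate(500, lesion_loss(0.5, n_max = 8))
  hi <- replicate(500, lesion_loss(5.5, n_max = 8))
  expect_true(all(lo >= 0 & lo <= 8))
  expect_true(all(hi >= 0 & hi <= 8))
  expect_gt(mean(hi), mean(lo) + 2)
})

test_that("count generators respect their floors and caps", {
  cfg <- cohort_config()
  a_hi <- virtual_animal(h = 6, d = 0.8)
  set.seed(1)
  les <- replicate(200, generate_motor_count(a_hi, lesioned = TRUE,
                                             config = cfg))
  expect_true(all(les >= 1 & les <= 10))
  int <- replicate(200, generate_motor_count(a_hi, lesioned = FALSE,
                                             config = cfg))
  expect_true(all(int >= 2 & int <= 10))
  beh <- replicate(200, generate_behavior(a_hi, lesioned = TRUE, config = cfg))
  expect_true(all(beh >= 0 & beh <= 10))
  # a high-h animal mostly fails to swim after the lesion
  expect_gt(mean(beh <= 1), 0.5)
})

test_that("dual-site fixtures carry their ground truth", {
  fx <- generate_dual_site_fixture("mixed", n_bursts = 5, seed = 3)
  expect_s3_class(fx, "episode_recording")
  expect_identical(fx$condition$category, "mixed")
  expect_identical(length(fx$nerve_impulse_times), nrow(fx$soma_events))
  expect_error(generate_dual_site_fixture("mixed", delay = 0), "delay")
})

test_that("population calibration returns a deterministic, well-formed report", {
  grid <- expand.grid(alpha = c(-2.3, -1.7), beta = c(1.0, 1.2), gamma = 1.0)
  r1 <- calibrate_population_model(grid = grid, seed = 42, n_rep = 20)
  r2 <- calibrate_population_model(grid = grid, seed = 42, n_rep = 20)
  expect_s3_class(r1, "population_calibration")
  expect_identical(r1$coef, r2$coef)
  expect_identical(r1$achieved, r2$achieved)
  expect_named(r1$achieved, names(population_targets()), ignore.order = TRUE)
  expect_true(is.logical(r1$converged))
  expect_identical(nrow(r1$grid), 4L)
  expect_true(all(is.finite(r1$grid$score)))
})

test_that("an impossible calibration target reports failure instead of erroring", {
  bad <- population_targets()
  bad["motor_mean_pc"] <- -95
  grid <- expand.grid(alpha = -2.3, beta = 1.2, gamma = 1.0)
  r <- calibrate_population_model(targets = bad, grid = grid, seed = 1,
                                  n_rep = 10)
  expect_false(r$converged)
})
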