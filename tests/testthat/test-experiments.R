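test_that("behavior lesion experiment unmasks variance in the cut arm only", {
  res <- run_behavior_lesion(experiment_spec("behavior_lesion", seed = 1))
  expect_s3_class(res, "cohort_result")
  expect_identical(nrow(res$rows), 11L * 2L * 4L)
  s <- res$summary
  # the cut arm becomes much more variable after surgery; the sham arm not
  expect_gt(s$cov_cut_post, 2 * s$cov_cut_pre)
  expect_lt(abs(s$cov_sham_post - s$cov_cut_pre), 0.15)
  # pre-surgery means indistinguishable between arms
  tp1 <- s$timepoints[1, ]
  expect_lt(abs(tp1$mean_cut - tp1$mean_sham), 1)
})

test_that("motor lesion experiment reproduces the dispersion signature", {
  res <- run_motor_lesion(experiment_spec("motor_lesion", seed = 1))
  expect_identical(nrow(res$rows), 34L * 4L)
  s <- res$summary
  expect_gt(s$cov_post, 1.8 * s$cov_pre)
  expect_lt(s$mean_percent_change, -15)
  expect_gt(s$mean_percent_change, -40)
  # repeated intact episodes are stable
  expect_gt(s$stability_t_1v3$p.value, 0.05)
  # variance increase is significant at this N
  expect_lt(s$levene$p.value, 0.05)
  # the lesioned change spans enhancement to abolition across animals
  expect_gt(max(s$percent_change), 0)
  expect_lt(min(s$percent_change), -60)
})

test_that("correlation suite: susceptibility tracks the hidden hyperpolarization", {
  res <- run_correlation_suite(experiment_spec("correlation_suite", seed = 1))
  s <- res$summary
  expect_lt(s$pc_vs_hyp$slope, 0)
  expect_lt(s$pc_vs_hyp$p.value, 1e-4)
  expect_lt(s$post_vs_hyp$slope, 0)
  expect_lt(s$post_vs_hyp$p.value, 0.01)
  # nulls: the intact pattern carries no trace of the hidden amplitude
  expect_gt(s$intact_vs_hyp$p.value, 0.05)
  expect_gt(s$intact_vs_c2$p.value, 0.05)
  expect_gt(s$pc_vs_dep$p.value, 0.05)
})

test_that("propagation census classifies every fixture and orders susceptibility", {
  res <- run_propagation_census(experiment_spec("propagation_census", seed = 1))
  s <- res$summary
  expect_identical(s$classification_accuracy, 1)
  expect_identical(nrow(res$rows), 69L)
  # the three categories are all present, mixed the most common
  expect_true(all(c("antidromic-only", "mixed", "orthodromic-only") %in%
                    names(s$category_percent)))
  expect_gt(s$category_percent[["mixed"]], 50)
  # antidromic-only animals are hit hardest, orthodromic-only least
  pc <- s$mean_pc_by_category
  expect_lt(pc[["antidromic-only"]], pc[["mixed"]])
  expect_lt(pc[["mixed"]], pc[["orthodromic-only"]])
  expect_lt(s$anova$p.value, 0.05)
})

test_that("dynamic clamp suite: structural invariance when intact, rescue when lesioned", {
  res <- run_dynclamp_suite(experiment_spec("dynclamp_suite", seed = 1),
                            arm_n = c(intact_add = 6L, intact_subtract = 5L,
                                      lesioned_add = 6L,
                                      lesioned_subtract = 6L))
  s <- res$summary$arms
  expect_identical(s$intact_add$mean_diff, 0)
  expect_identical(s$intact_subtract$mean_diff, 0)
  expect_lt(s$lesioned_add$mean_diff, -1)
  expect_gt(s$lesioned_subtract$mean_diff, 1)
  # with the artificial synapse on, intact spiking is distal in origin
  expect_gt(res$summary$intact_add_frac_antidromic, 0.9)
})

test_that("experiments are pure functions of their spec", {
  r1 <- run_motor_lesion(experiment_spec("motor_lesion", seed = 3))
  r2 <- run_motor_lesion(experiment_spec("motor_lesion", seed = 3))
  expect_identical(r1$rows, r2$rows)
  r3 <- run_motor_lesion(experiment_spec("motor_lesion", seed = 4))
  expect_false(identical(r1$rows, r3$rows))
})
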