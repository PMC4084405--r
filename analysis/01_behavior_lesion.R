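#!/usr/bin/env Rscript
# Behavioral lesion experiment: paired nerve-cut vs sham cohorts, three
# pre-surgery swims and one post-surgery swim per animal.
source("analysis/00_common.R")

res <- run_behavior_lesion(experiment_spec("behavior_lesion", seed = 1))
print(res)

save_rows(res$rows, "behavior_lesion_swims")
save_json(list(
  timepoints = res$summary$timepoints,
  cov_cut_pre = res$summary$cov_cut_pre,
  cov_cut_post = res$summary$cov_cut_post,
  cov_sham_post = res$summary$cov_sham_post,
  levene_post = res$summary$levene_post), "behavior_lesion")
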