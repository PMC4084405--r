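#!/usr/bin/env Rscript
# Propagation census: classify dual-site soma/nerve recordings across the
# cohort and relate the propagation category to lesion susceptibility.
source("analysis/00_common.R")

res <- run_propagation_census(experiment_spec("propagation_census", seed = 1))
print(res)

save_rows(res$rows, "propagation_census_animals")
save_json(list(
  category_percent = as.list(res$summary$category_percent),
  classification_accuracy = res$summary$classification_accuracy,
  mean_pc_by_category = as.list(res$summary$mean_pc_by_category),
  anova = res$summary$anova), "propagation_census")
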