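#!/usr/bin/env Rscript
# Correlation suite: measured Hi-Di PSP amplitudes vs lesion susceptibility,
# with the intact-pattern null regressions.
source("analysis/00_common.R")

res <- run_correlation_suite(experiment_spec("correlation_suite", seed = 1))
print(res)

save_rows(res$rows, "correlation_suite_animals")
save_json(res$summary, "correlation_suite")
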