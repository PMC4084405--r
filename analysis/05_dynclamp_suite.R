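#!/usr/bin/env Rscript
# Dynamic-clamp suite: artificial C2-to-VSI synapse added to or subtracted
# from intact and lesioned circuits, paired off/on episodes per animal.
source("analysis/00_common.R")

res <- run_dynclamp_suite(experiment_spec("dynclamp_suite", seed = 1))
print(res)

save_rows(res$rows, "dynclamp_suite_animals")
save_json(res$summary, "dynclamp_suite")
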