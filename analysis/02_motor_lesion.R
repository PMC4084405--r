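#!/usr/bin/env Rscript
# Motor-pattern lesion experiment: four episodes per preparation, PdN6
# blocked between episodes 3 and 4.
source("analysis/00_common.R")

res <- run_motor_lesion(experiment_spec("motor_lesion", seed = 1))
print(res)

save_rows(res$rows, "motor_lesion_episodes")
save_json(res$summary, "motor_lesion")
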