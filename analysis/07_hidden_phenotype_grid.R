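#!/usr/bin/env Rscript
# Hidden-phenotype property grid: burst counts of the circuit model across
# the hyperpolarization range, intact vs lesioned, plus the dynamic-clamp
# conductance series on the lesioned circuit.
source("analysis/00_common.R")

episode_count <- function(h, s, lesion = FALSE, mode = "off", g = 1000) {
  circ <- build_circuit(virtual_animal(h = h, d = 0.8))
  if (lesion) circ <- apply_lesion(circ)
  if (mode != "off")
    circ <- attach_dynamic_clamp(circ, synapse_kinetics(g_syn = g),
                                 mode = mode)
  count_vsi_bursts(simulate_episode(circ, stim_swim(), duration = 80,
                                    seed = s))
}

hs <- c(0, 0.5, 1.5, 2.9, 4.0, 5.5)
seeds <- 1:8
grid <- do.call(rbind, lapply(hs, function(h)
  do.call(rbind, lapply(seeds, function(s)
    data.frame(h = h, seed = s,
               intact = episode_count(h, s),
               lesioned = episode_count(h, s, lesion = TRUE))))))
g_series <- do.call(rbind, lapply(c(0, 500, 1000, 1500), function(g)
  data.frame(g_nS = g, mean_bursts = mean(sapply(seeds, function(s)
    episode_count(2.9, s, lesion = TRUE, mode = "add", g = g))))))

print(aggregate(cbind(intact, lesioned) ~ h, grid, mean))
print(g_series)

save_rows(grid, "hidden_phenotype_grid")
save_json(list(
  intact_mean_by_h = tapply(grid$intact, grid$h, mean),
  lesioned_mean_by_h = tapply(grid$lesioned, grid$h, mean),
  lesioned_add_clamp_series = g_series), "hidden_phenotype")
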