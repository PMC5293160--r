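#!/usr/bin/env Rscript
# Simulate single-cell GAL induction experiments for the five nutrient
# histories and write the track tables under results/.
#
# Each experiment is a microchemostat field of ~300 cells imaged every
# 20 min (fluorescence) and 2 min (bright field) for 25 h after the
# switch to galactose. Ground truth (escape times, true plateaus,
# lineage, deaths) is written alongside for validation.

library(galfield)

seed <- 20170101
out <- "results"
dir.create(file.path(out, "tracks"), recursive = TRUE, showWarnings = FALSE)

histories <- c("glycerol", "reinduction", "ltgr", "mix015", "mix030")
for (i in seq_along(histories)) {
  h <- histories[i]
  sim <- simulate_population(
    sim_config(seed = seed + i, n_cells = 300, history = h))
  write_table(sim$tracks, file.path(out, "tracks", paste0(h, ".csv")))
  write_table(sim$truth, file.path(out, "tracks", paste0(h, "_truth.csv")))
  write_table(sim$bf, file.path(out, "tracks", paste0(h, "_bf.csv")))
  message(sprintf(
    "%-11s %5d cells, %6d track rows, %4d divisions, %3d deaths, %3d washouts",
    h, length(unique(sim$tracks$cell_id)), nrow(sim$tracks),
    sim$meta$n_divisions, sim$meta$n_deaths, sim$meta$n_washouts))
}
message("Findings: glycerol/reinduction/mix fields grow steadily after a ",
        "brief pause; the LTGR field is static for hours, loses cells to ",
        "death, and is then taken over by the lineages of early escapers.")
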