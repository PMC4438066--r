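#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- a three-species brain-specificity
# panel with planted switch events, contaminated electrophoresis lanes, and a
# neural differentiation time course -- and write every raw input table.
# Downstream stages (02-05) see only these files, never the generator state.

suppressPackageStartupMessages(library(switchscreen))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 42)
study <- simulate_study(cfg)

write_assays(study$assays, "results/assays.tsv")
write_orthologs(study$ortholog_map, "results/orthologs.tsv")
readr::write_tsv(study$truth, "results/truth.tsv", na = "NA")
for (sp in cfg$species) {
  write_psi(study$psi_true[[sp]], sprintf("results/psi_true_%s.tsv", sp))
  write_peaks(study$peaks[[sp]]$peaks, sprintf("results/peaks_%s.csv", sp))
  readr::write_tsv(study$peaks[[sp]]$lane_truth,
                   sprintf("results/lane_truth_%s.tsv", sp), na = "NA")
}
write_psi(study$timecourse$tc, "results/timecourse.tsv")
readr::write_tsv(study$timecourse$truth, "results/timecourse_truth.tsv", na = "NA")

cat(sprintf("Simulated %d events across %s (seed %d).\n", cfg$n_ases,
            paste(cfg$species, collapse = "/"), cfg$seed))
cat(sprintf("Planted: %d switch-like in %s, of which %d conserved in all species\n",
            sum(study$truth$is_switch), cfg$species[1],
            sum(study$truth$is_conserved)))
cat(sprintf("Time course: %d series, %d planted switches, pivot in (%g, %g)\n",
            cfg$tc_n_series, cfg$tc_n_switch,
            cfg$pivot_interval[1], cfg$pivot_interval[2]))
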