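#!/usr/bin/env Rscript
# Stage 2: convert each species' electropherogram peak tables to molarity,
# purity and PSI, applying the >75% purity gate; QC-failing lanes become
# missing cells of the PSI matrices.

suppressPackageStartupMessages(library(switchscreen))

assays <- read_assays("results/assays.tsv")
species <- unique(assays$species)

for (sp in species) {
  peaks <- read_peaks(sprintf("results/peaks_%s.csv", sp))
  q <- quantify_table(peaks, assays[assays$species == sp, ])
  readr::write_tsv(q, sprintf("results/quant_%s.tsv", sp), na = "NA")
  write_psi(quant_to_psi(q), sprintf("results/psi_%s.tsv", sp))
  cat(sprintf("%-10s %5d lanes, %5d pass QC (%.1f%%), median purity %.3f\n",
              sp, nrow(q), sum(q$qc_pass), 100 * mean(q$qc_pass),
              stats::median(q$purity, na.rm = TRUE)))
}
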