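#!/usr/bin/env Rscript
# Stage 3: per-species switch screen.  For each species, keep events complete
# in every tissue, compute the brain-vs-nearest-tissue shift, call switches at
# the strict 50-point rule, and test cassette-exon enrichment among the
# discovery species' hits.  A clustered heat map of the discovery matrix goes
# to scratch/ when pheatmap is available.

suppressPackageStartupMessages(library(switchscreen))

assays <- read_assays("results/assays.tsv")
species <- unique(assays$species)

for (sp in species) {
  psi <- read_psi(sprintf("results/psi_%s.tsv", sp))
  complete <- suppressMessages(qc_filter(psi))
  calls <- screen_psi(psi, reference = "brain", threshold = 50)
  readr::write_tsv(calls, sprintf("results/screen_%s.tsv", sp), na = "NA")
  cat(sprintf("%-10s %4d events, %4d complete, %3d switch-like (>50 points)\n",
              sp, nrow(psi), nrow(complete), sum(calls$is_switch)))
}

mouse_calls <- readr::read_tsv("results/screen_mouse.tsv", show_col_types = FALSE)
enr <- enrichment_test(mouse_calls, assays)
jsonlite::write_json(list(counts = as.vector(enr$counts),
                          odds_ratio = enr$odds_ratio, p_value = enr$p_value),
                     "results/enrich.json", auto_unbox = TRUE, digits = NA)
cat(sprintf("Cassette enrichment among switch events: OR %.2f, p = %.3g\n",
            enr$odds_ratio, enr$p_value))

mouse_complete <- suppressMessages(qc_filter(read_psi("results/psi_mouse.tsv")))
ord <- cluster_order(mouse_complete, axis = "rows")
readr::write_tsv(tibble::tibble(leaf_position = seq_along(ord),
                                ase_id = mouse_complete$ase_id[ord]),
                 "results/cluster_order_mouse.tsv")
if (requireNamespace("pheatmap", quietly = TRUE)) {
  dir.create("scratch", showWarnings = FALSE)
  m <- as.matrix(mouse_complete[, -1])
  rownames(m) <- mouse_complete$ase_id
  pheatmap::pheatmap(m, clustering_method = "average", show_rownames = FALSE,
                     filename = "scratch/heatmap_mouse.png")
  cat("Heat map written to scratch/heatmap_mouse.png\n")
}
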