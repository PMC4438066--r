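#!/usr/bin/env Rscript
# Stage 4: cross-species conservation.  Join the per-species switch calls
# through the ortholog map and run the staged funnel: discovery hits ->
# orthologs assayed -> complete in the validation species -> switch-like
# versus all its tissues -> confirmed with a consistent direction in the
# third species.

suppressPackageStartupMessages(library(switchscreen))

map <- read_orthologs("results/orthologs.tsv")
species <- c("mouse", "human", "zebrafish")
calls <- lapply(species, function(sp) {
  readr::read_tsv(sprintf("results/screen_%s.tsv", sp), show_col_types = FALSE)
})
names(calls) <- species

funnel <- staged_screen(calls$mouse, calls$human, calls$zebrafish, map,
                        species_names = species)
jsonlite::write_json(as.list(funnel$counts), "results/funnel.json",
                     auto_unbox = TRUE, digits = NA)
readr::write_tsv(funnel$conserved, "results/conserved.tsv", na = "NA")

cat("Conservation funnel:\n")
for (nm in names(funnel$counts)) {
  cat(sprintf("  %-24s %4d\n", nm, funnel$counts[nm]))
}
truth <- readr::read_tsv("results/truth.tsv", show_col_types = FALSE)
cat(sprintf(paste0("Planted conserved events: %d; confirmed through the ",
                   "funnel: %d\n(the funnel only sees events with ",
                   "QC-complete data in every species,\nso lane attrition ",
                   "removes planted events before conservation is tested)\n"),
            sum(truth$is_conserved), nrow(funnel$conserved)))
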