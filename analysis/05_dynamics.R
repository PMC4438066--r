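#!/usr/bin/env Rscript
# Stage 5: splicing dynamics over the differentiation time course -- net
# first-to-last shift, switch classification, and the pivot interval where
# each switch concentrates its change.

suppressPackageStartupMessages(library(switchscreen))

tc <- read_psi("results/timecourse.tsv")
dyn <- dynamics_screen(tc, threshold = 50)
readr::write_tsv(dyn, "results/dynamics.tsv", na = "NA")

cat(sprintf("%d of %d series complete; %d shift more than 50 points net\n",
            attr(dyn, "n_complete"), attr(dyn, "n_total"), sum(dyn$is_switch)))
sw <- dyn[dyn$is_switch, ]
piv <- table(sprintf("(%g, %g)", sw$pivot_lo, sw$pivot_hi))
cat("Pivot intervals of the switch-like series:\n")
for (nm in names(piv)) cat(sprintf("  %-10s %3d\n", nm, piv[nm]))

truth <- readr::read_tsv("results/timecourse_truth.tsv", show_col_types = FALSE)
m <- merge(sw, truth, by = "ase_id")
cat(sprintf("Planted midpoints inside the called pivot interval: %d / %d\n",
            sum(m$pivot_lo <= m$midpoint & m$midpoint <= m$pivot_hi), nrow(m)))
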