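#!/usr/bin/env Rscript
# Stage 1: simulate the study dataset.
#
# Generates a 137-compound, 5-family activity table with planted
# substituent effects (noise 0.3 pIC50), plus injected duplicate /
# missing / ranged rows so curation has real work to do. Writes the raw
# table and the ground truth under results/.

library(kmosar)
seed <- 1L
dir.create("results", showWarnings = FALSE)

spec <- planted_sar_spec(n_compounds = 137, n_families = 5,
                         noise_sd = 0.3, seed = seed)
tab <- generate_activity_table(spec)
write_activity_csv(tab, "results/raw_activity.csv")
utils::write.csv(attr(tab, "clean"), "results/truth_clean.csv",
                 row.names = FALSE)
utils::write.csv(as.data.frame(attr(tab, "design")),
                 "results/truth_design.csv")

cat(sprintf("raw table: %d rows (%d clean + %d injected)\n",
            nrow(tab), nrow(attr(tab, "clean")),
            nrow(tab) - nrow(attr(tab, "clean"))))
cat(sprintf("families: %s\n",
            paste(names(table(attr(tab, "clean")$family)),
                  table(attr(tab, "clean")$family), collapse = ", ")))
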