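#!/usr/bin/env Rscript
# Stage 2: curate the raw activity table and profile the survivors.
#
# Removes duplicates / missing / ranged / unparseable rows (logged),
# converts IC50 (nM) to pIC50, assigns the 7.6 activity cutoff, then
# computes the eight physicochemical descriptors, their summary
# statistics and the Pearson correlation structure against pIC50.

library(kmosar)

raw <- utils::read.csv("results/raw_activity.csv",
                       colClasses = "character")
rec <- curate(raw, cutoff = 7.6)
write_curated(rec, "results/curated.csv", "results/curation_log.txt")
cat(sprintf("curated records: %d (%d removals logged)\n",
            nrow(rec), nrow(attr(rec, "log"))))
cat(sprintf("actives (pIC50 >= 7.6): %d; inactives: %d\n",
            sum(rec$activity_class == 1), sum(rec$activity_class == 0)))

ph <- compute_physchem(rec)
utils::write.csv(ph, "results/physchem.csv", row.names = FALSE)
sm <- summarize_physchem(ph, rec$activity_class)
utils::write.csv(sm, "results/physchem_summary.csv", row.names = FALSE)
print(sm)

r <- correlation_matrix(ph[vapply(ph, function(x)
  !is.numeric(x) || stats::sd(x) > 0, logical(1))], rec$pic50)
utils::write.csv(correlation_long(r), "results/correlations_long.csv",
                 row.names = FALSE)
cat(sprintf("strongest descriptor-activity correlation: %s (r = %.3f)\n",
            {
              l <- correlation_long(r)
              l <- l[l$var2 == "pic50" | l$var1 == "pic50", ]
              l$var1[which.max(l$abs_r)]
            },
            max(correlation_long(r)$abs_r[
              correlation_long(r)$var1 == "pic50" |
                correlation_long(r)$var2 == "pic50"])))
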