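#!/usr/bin/env Rscript
# Stage 4: applicability domain and chemical space network.
#
# Computes leverage values over the selected descriptor panel
# (h* = 3p/n) for training and test sets, then builds the Tc >= 0.68
# chemical space network with components, greedy-modularity communities
# and similarity-tier statistics of the largest component.

library(kmosar)

rec <- utils::read.csv("results/curated.csv")
ph <- utils::read.csv("results/physchem.csv")
sp <- utils::read.csv("results/split_map.csv")

feats <- pretreat(ph[setdiff(names(ph), "molecule_id")])
tr <- sp$set == "train"
lev <- leverage(feats[tr, , drop = FALSE], feats[!tr, , drop = FALSE])
write_ad_csv(lev, "results/ad_williams.csv")
rep <- ad_report(lev)
cat(sprintf("h* = 3*%d/%d = %.3f\n", lev$p, lev$n, lev$h_star))
print(rep$counts)
if (nrow(rep$outliers)) {
  cat("outliers (descending leverage):\n")
  print(utils::head(rep$outliers, 5))
} else cat("no compounds outside the applicability domain\n")

net <- build_csn(rec, edge_threshold = 0.68)
print(net)
write_csn(net, "results/csn")
for (k in 1:min(3, max(igraph::V(net$graph)$component))) {
  ts <- tier_statistics(csn_component(net, k))
  cat(sprintf("subgraph %d tiers: %s\n", k,
              paste(sprintf("%s %d (%.2f%%)", ts$tier, ts$n_pairs,
                            ts$percent), collapse = ", ")))
}
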