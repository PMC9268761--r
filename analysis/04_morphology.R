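#!/usr/bin/env Rscript
# Stage 4: morphological arm.
#
# Per-trait one-way ANOVA across genotypes with Fisher's LSD pairwise
# comparisons and compact letter display, then a dendrogram from z-scored
# trait means under Euclidean distance, WPGMA, cut at k = 2.

library(markerdiv)

traits <- read_trait_table("results/trait_table.csv")
summ <- summarize_traits(traits)

rows <- lapply(sort(unique(traits$trait)), function(tr) {
  r <- lsd_test(traits, tr, alpha = 0.05)
  cbind(trait = tr, F = r$F, p = r$p_value, lsd = r$lsd, r$means)
})
lsd_report <- do.call(rbind, rows)
utils::write.table(format(lsd_report, digits = 4), "results/lsd_report.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")

cat("per-trait ANOVA + LSD letters (alpha = 0.05):\n")
for (tr in sort(unique(traits$trait))) {
  r <- lsd_test(traits, tr, alpha = 0.05)
  lab <- paste(sprintf("%s:%s", r$means$genotype, r$means$letters),
               collapse = " ")
  cat(sprintf("  %-20s F = %8.2f  p = %.3g  LSD = %.3f  %s\n",
              tr, r$F, r$p_value, r$lsd, lab))
}

d <- morpho_distance(summ)
tree <- wpgma(d)
write_newick(tree, "results/morpho_dendrogram.nwk")
clusters <- cut_tree(tree, k = 2)
utils::write.table(clusters, "results/morpho_clusters.csv", sep = ",",
                   quote = FALSE, row.names = FALSE, eol = "\n")

cat("morphological tree:", write_newick(tree), "\n")
cat("k = 2 groups:\n")
print(clusters)
cat("-> results/lsd_report.tsv, morpho_dendrogram.nwk, morpho_clusters.csv\n")
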