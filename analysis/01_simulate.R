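#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
#
# No gel-scored band matrix or raw trait measurements are available for the
# five kalanchoe genotypes, so the pipeline starts from the synthetic fixture:
# a band matrix whose per-primer locus-class counts equal the published
# survey's counts (70 loci over 4 RAPD + 4 ISSR + 4 SCoT primers), and a
# trait table drawn around the published trait maxima with 10 replicate
# plants per genotype.

library(markerdiv)

seed <- if (length(commandArgs(TRUE)) >= 1) as.integer(commandArgs(TRUE)[1]) else 2024L
dir.create("results", showWarnings = FALSE)

fx <- kalanchoe_fixture(seed = seed)
band <- generate_band_matrix(fx$band)
traits <- generate_trait_table(fx$morpho)

write_band_matrix(band, "results/band_matrix.csv")
write_trait_table(traits, "results/trait_table.csv")

cat(sprintf("simulated %d genotypes x %d loci (seed %d) -> results/band_matrix.csv\n",
            nrow(band$values), ncol(band$values), seed))
cat(sprintf("simulated %d trait records over %d traits -> results/trait_table.csv\n",
            nrow(traits), length(unique(traits$trait))))
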