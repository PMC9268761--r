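#!/usr/bin/env Rscript
# Stage 2: marker statistics.
#
# Classifies every locus of the simulated band matrix as monomorphic,
# polymorphic or unique, tabulates per-primer and per-system counts with
# polymorphism percentages (floored per primer; system average = mean of the
# floored values), and computes the RAPD/SCoT percentage-fidelity index.

library(markerdiv)

band <- read_band_matrix("results/band_matrix.csv")
report <- marker_report(band)

rapd <- system_summary(band, "RAPD")
scot <- system_summary(band, "SCoT")
issr <- system_summary(band, "ISSR")
fid <- fidelity_percent(rapd, scot)

write_marker_report(report, "results/marker_report.tsv",
                    json_path = "results/marker_report.json", fidelity = fid)

grand <- report[report$system == "All", ]
cat(sprintf("scored %d loci: %d monomorphic, %d polymorphic (%d unique)\n",
            grand$n_total, grand$n_monomorphic, grand$n_polymorphic,
            grand$n_unique))
cat(sprintf("loci per system: RAPD %d, ISSR %d, SCoT %d\n",
            rapd$n_total, issr$n_total, scot$n_total))
cat(sprintf("average polymorphism: RAPD %.2f%%, ISSR %.2f%%, SCoT %.2f%%\n",
            rapd$avg_polymorphism_pct, issr$avg_polymorphism_pct,
            scot$avg_polymorphism_pct))
print(fid)
cat("report -> results/marker_report.tsv / .json\n")
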