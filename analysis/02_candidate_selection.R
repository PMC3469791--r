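#!/usr/bin/env Rscript
# Stage 2: panel QC and candidate-SNP selection.
#
# Loads the simulated frequency panel, applies the panel exclusion filters
# (availability, per-group call rate >= 95%, HWE exact p >= 1e-7), computes
# the two pairwise White-vs-comparison allele-frequency differences per SNP,
# assigns the four candidate categories, and allocates the study-wide alpha
# of 0.05 across them (0.0125 per subgroup, Bonferroni-divided by each
# subgroup's SNP count).

library(ethdiff)

dir.create("results", showWarnings = FALSE)
panel <- load_panel("results/sim/panel.tsv", "freq_tsv")

qc <- apply_panel_qc(panel)
print(qc$report)

profiles <- difference_profiles(qc$panel)
write.table(profiles, "results/difference_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

candidates <- select_candidates(qc$panel)
counts <- attr(candidates, "category_counts")
cat("candidate SNPs by category:\n")
print(counts)

th <- category_thresholds(counts, study_alpha = 0.05)
print(th)
write.table(th$table, "results/category_thresholds.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(candidates, "results/candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("\n%d of %d SNPs met a frequency-difference criterion (%.1f%%)\n",
            nrow(candidates), n_snps(qc$panel),
            100 * nrow(candidates) / n_snps(qc$panel)))
stopifnot("snp00001" %in% candidates$snp_id)
cat("the planted locus snp00001 falls in category:",
    candidates$category[candidates$snp_id == "snp00001"], "\n")
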