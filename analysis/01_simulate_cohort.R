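#!/usr/bin/env Rscript
# Stage 1: simulate the study materials.
#
# Builds a three-group (White / East Asian / African) allele-frequency panel
# under the Balding-Nichols model, with a handful of strongly differentiated
# loci planted on top of the null background, and draws a White discovery
# case-control cohort in which one of the differentiated loci carries a real
# per-allele effect (OR 1.8, comparison-enriched allele protective).
# Everything downstream (02-05) reads the TSVs written here.

library(ethdiff)

out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260928

cfg <- sim_config(
  n_snps = 600,
  group_sizes = c(White = 215, EastAsian = 250, African = 257),
  fst_per_group = c(White = 0.2, EastAsian = 0.2, African = 0.2),
  missing_rate = 0.01,
  planted_snps = list(planted_effect(1, 1.8, risk_allele = "ref")),
  n_cases = 692, n_controls = 3992,
  baseline_risk = 0.005,
  case_control_group = "White",
  seed = seed)

panel <- simulate_frequency_panel(cfg)
# plant a strongly differentiated causal locus: the reference allele is
# common in Whites and rare in the comparison groups
panel$freq[1, ] <- c(White = 0.90, EastAsian = 0.12, African = 0.15)

cc <- simulate_case_control(panel, cfg)

# persist the panel as group-level pseudo-counts so stage 02 can reload it
counts <- round(panel$freq * 2 * rep(cfg$group_sizes,
                                     each = n_snps(panel)))
panel_out <- pop_panel(panel$snps, counts / (2 * rep(cfg$group_sizes,
                                                     each = n_snps(panel))),
                       ref_count = counts,
                       n_alleles = matrix(2 * rep(cfg$group_sizes,
                                                  each = n_snps(panel)),
                                          nrow = n_snps(panel),
                                          dimnames = dimnames(panel$freq)))
write_freq_tsv(panel_out, file.path(out_dir, "panel.tsv"))
write_genotype_tsv(cc$genotypes, file.path(out_dir, "genotypes.tsv"))
write_phenotype_tsv(cc$phenotypes, file.path(out_dir, "phenotypes.tsv"))

cat(sprintf("simulated %d SNPs x 3 groups; cohort %d cases / %d controls\n",
            n_snps(panel), sum(cc$phenotypes$status),
            sum(1 - cc$phenotypes$status)))
cat(sprintf("stream disease incidence in Whites: %.4f (baseline %.3f)\n",
            cc$empirical_incidence, cfg$baseline_risk))
cat(sprintf("planted locus snp00001: White 0.90 / EastAsian 0.12 / African 0.15, OR 1.8\n"))
cat("wrote", file.path(out_dir, c("panel.tsv", "genotypes.tsv",
                                  "phenotypes.tsv")), sep = "\n  ")
cat("\n")
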