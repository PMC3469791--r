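test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_snps = 60, n_cases = 50, n_controls = 50,
                    planted_snps = list(planted_effect(2, 1.8)),
                    baseline_risk = 0.02, seed = 123)
  p1 <- simulate_frequency_panel(cfg)
  p2 <- simulate_frequency_panel(cfg)
  expect_identical(p1$freq, p2$freq)
  g1 <- simulate_genotypes(p1, cfg)
  g2 <- simulate_genotypes(p2, cfg)
  expect_identical(g1$dosage, g2$dosage)
  cc1 <- simulate_case_control(p1, cfg)
  cc2 <- simulate_case_control(p2, cfg)
  expect_identical(cc1$genotypes$dosage, cc2$genotypes$dosage)
  expect_identical(cc1$phenotypes, cc2$phenotypes)
  # a different seed moves the draws
  cfg2 <- sim_config(n_snps = 60, seed = 124)
  expect_false(identical(simulate_frequency_panel(cfg2)$freq, p1$freq))
})

test_that("vanishing differentiation collapses group frequencies to the ancestral", {
  cfg <- sim_config(n_snps = 1000,
                    fst_per_group = c(White = 1e-9, EastAsian = 1e-9,
                                      African = 1e-9),
                    seed = 21)
  panel <- simulate_frequency_panel(cfg)
  anc <- attr(panel, "ancestral_freq")
  expect_lt(max(abs(panel$freq - anc)), 1e-3)
})

test_that("group frequencies have the Balding-Nichols variance F p (1 - p)", {
  cfg <- sim_config(n_snps = 10000,
                    ancestral_freq_range = c(0.5, 0.5),
                    fst_per_group = c(White = 0.1, EastAsian = 0.1,
                                      African = 0.1),
                    seed = 22)
  panel <- simulate_frequency_panel(cfg)
  v <- apply(panel$freq, 2, var)
  # closed form: 0.1 * 0.5 * 0.5 = 0.025, within Monte-Carlo error
  expect_true(all(abs(v - 0.025) < 0.0025))
  expect_true(all(abs(colMeans(panel$freq) - 0.5) < 0.01))
})

test_that("F outside (0,1) is rejected", {
  expect_error(sim_config(fst_per_group = c(White = 0, EastAsian = 0.1,
                                            African = 0.1)), "F must lie")
  expect_error(sim_config(fst_per_group = c(White = 1, EastAsian = 0.1,
                                            African = 0.1)), "F must lie")
})

test_that("genotypes follow HWE at the group frequency with MCAR missingness", {
  snps <- data.frame(snp_id = c("m1", "m2"), chrom = "1", pos = c(1L, 2L),
                     reference_allele = "A", other_allele = "B")
  panel <- pop_panel(snps, cbind(G = c(0, 0.5)))
  cfg <- sim_config(n_snps = 2, group_sizes = c(G = 10000),
                    fst_per_group = c(G = 0.05), missing_rate = 0.1, seed = 31)
  geno <- simulate_genotypes(panel, cfg)
  d1 <- geno$dosage["m1", ]
  expect_true(all(d1[!is.na(d1)] == 0))  # ref freq 0: homozygous other allele
  d2 <- geno$dosage["m2", ]
  het <- mean(d2[!is.na(d2)] == 1)
  expect_lt(abs(het - 0.5), 0.02)        # 2pq = 0.5 at p = 0.5
  expect_lt(abs(mean(is.na(geno$dosage)) - 0.10), 0.01)
})

test_that("without planted effects cases and controls share allele frequencies", {
  cfg <- sim_config(n_snps = 100, n_cases = 400, n_controls = 400,
                    missing_rate = 0, baseline_risk = 0.05, seed = 41)
  panel <- simulate_frequency_panel(cfg)
  cc <- simulate_case_control(panel, cfg)
  d <- cc$genotypes$dosage
  case <- cc$phenotypes$status == 1
  f_case <- rowMeans(d[, case]) / 2
  f_ctrl <- rowMeans(d[, !case]) / 2
  p_pool <- (f_case + f_ctrl) / 2
  se <- sqrt(p_pool * (1 - p_pool) * (1 / (2 * 400) + 1 / (2 * 400)))
  z <- abs(f_case - f_ctrl) / se
  # multiplicity allowance over 100 null SNPs: no |z| beyond 4.5
  expect_lt(max(z, na.rm = TRUE), 4.5)
})

test_that("the planted per-allele odds ratio is recovered by logistic regression", {
  hits <- 0
  ors <- numeric(20)
  for (r in 1:20) {
    cfg <- sim_config(n_snps = 1, group_sizes = c(G = 100),
                      fst_per_group = c(G = 0.05),
                      ancestral_freq_range = c(0.3, 0.3),
                      missing_rate = 0,
                      planted_snps = list(planted_effect(1, 2.0)),
                      n_cases = 1000, n_controls = 1000,
                      baseline_risk = 0.01, case_control_group = "G",
                      seed = 500 + r)
    panel <- simulate_frequency_panel(cfg)
    cc <- simulate_case_control(panel, cfg)
    fit <- fit_additive_logistic(cc$genotypes$dosage[1, ], cc$phenotypes$status)
    ors[r] <- fit$or
    if (fit$ci_low <= 2 && 2 <= fit$ci_high) hits <- hits + 1
  }
  expect_gt(hits, 15)                      # 95% CIs cover the truth
  expect_lt(abs(mean(ors) - 2), 0.25)      # near-unbiased on the OR scale
})

test_that("empirical incidence ratio matches the analytic IRR for a planted locus", {
  # risk-allele frequencies 0.8 vs 0.2 with GRR (1, 2, 3): analytic IRR 1.86
  snps <- data.frame(snp_id = "m1", chrom = "1", pos = 1L,
                     reference_allele = "A", other_allele = "B")
  panel <- pop_panel(snps, cbind(G1 = 0.8, G2 = 0.2))
  cfg <- sim_config(n_snps = 1, group_sizes = c(G1 = 10, G2 = 10),
                    fst_per_group = c(G1 = 0.05, G2 = 0.05),
                    missing_rate = 0,
                    planted_snps = list(planted_effect(1, 2.0,
                                                       grr_scale = "additive_risk")),
                    baseline_risk = 0.02, case_control_group = "G1", seed = 77)
  inc <- simulate_incidence(panel, cfg, n_per_group = 4e5)
  analytic <- incidence_rate_ratio(c(G1 = 0.8, G2 = 0.2), 2.0, c("G1", "G2"))
  expect_equal(analytic, 2.6 / 1.4, tolerance = 1e-12)
  expect_lt(abs(inc[["G1"]] / inc[["G2"]] - analytic), 0.12)
})

test_that("impossible planted risk products are rejected", {
  expect_error(
    sim_config(planted_snps = list(planted_effect(1, 6),
                                   planted_effect(2, 6)),
               baseline_risk = 0.05),
    "exceeds 1")
})
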