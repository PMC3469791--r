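test_that("panel QC excludes by availability, call rate, then HWE", {
  # 10 SNPs: 3 fail call rate, 2 fail HWE (disjoint), 5 clean
  pops <- c("P1", "P2", "P3")
  nsnp <- 10
  snps <- data.frame(snp_id = sprintf("s%02d", 1:nsnp), chrom = "1",
                     pos = 1:nsnp, reference_allele = "A", other_allele = "B")
  ref_count <- matrix(50, nsnp, 3, dimnames = list(NULL, pops))
  n_alleles <- matrix(100, nsnp, 3, dimnames = list(NULL, pops))
  call_rate <- matrix(1, nsnp, 3, dimnames = list(NULL, pops))
  hwe_p <- matrix(1, nsnp, 3, dimnames = list(NULL, pops))
  call_rate[1:3, 2] <- 0.90            # below the 95% floor in one population
  hwe_p[4:5, 3] <- 1e-9                # HWE failures in one source
  panel <- pop_panel(snps, ref_count / n_alleles, ref_count = ref_count,
                     n_alleles = n_alleles, call_rate = call_rate,
                     hwe_p = hwe_p)
  res <- apply_panel_qc(panel)
  expect_equal(res$report$n_retained, 5)
  expect_equal(res$report$n_excluded_callrate, 3)
  expect_equal(res$report$n_excluded_hwe, 2)
  # report is a partition of the input
  expect_equal(res$report$n_input,
               res$report$n_retained + res$report$n_excluded_callrate +
                 res$report$n_excluded_hwe + res$report$n_excluded_missing_source)
  expect_equal(n_snps(res$panel), 5)
})

test_that("one group below the call-rate floor excludes the SNP", {
  pops <- c("White", "EastAsian", "African")
  snps <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = 1:2,
                     reference_allele = "A", other_allele = "B")
  mk <- function(v) matrix(v, 2, 3, byrow = TRUE, dimnames = list(NULL, pops))
  panel <- pop_panel(snps, mk(c(0.5, 0.5, 0.5)),
                     ref_count = mk(50), n_alleles = mk(100),
                     call_rate = mk(c(0.96, 0.94, 0.99, 0.99, 0.99, 0.99)),
                     hwe_p = mk(1))
  res <- apply_panel_qc(panel)
  expect_equal(res$panel$snps$snp_id, "b")
  expect_equal(res$report$n_excluded_callrate, 1)
})

test_that("QC exclusion order attributes each SNP to its first failing filter", {
  pops <- "P1"
  snps <- data.frame(snp_id = "s1", chrom = "1", pos = 1L,
                     reference_allele = "A", other_allele = "B")
  one <- function(v) matrix(v, 1, 1, dimnames = list(NULL, pops))
  # fails both call rate and HWE: must count once, under call rate
  panel <- pop_panel(snps, one(0.5), ref_count = one(50), n_alleles = one(100),
                     call_rate = one(0.5), hwe_p = one(1e-12))
  res <- apply_panel_qc(panel)
  expect_equal(res$report$n_excluded_callrate, 1)
  expect_equal(res$report$n_excluded_hwe, 0)
})

test_that("case-control QC drops low-call-rate samples then failing SNPs", {
  set.seed(8)
  nsnp <- 100
  d <- matrix(rbinom(nsnp * 60, 2, 0.4), nsnp, 60,
              dimnames = list(sprintf("snp%03d", 1:nsnp), sprintf("s%02d", 1:60)))
  groups <- setNames(rep(c("case", "control"), each = 30), colnames(d))
  # sample s01: 5% missing -> dropped at the 98% floor; the two extra missing
  # entries per sample below leave everyone else at 99% call rate
  d[sample(nsnp, 5), 1] <- NA
  # snp001: >5% missing among the 29 surviving cases
  d["snp001", 2:3] <- NA
  # snp002: gross heterozygote excess in controls
  d["snp002", groups == "control"] <- 1
  res <- apply_casecontrol_qc(geno_matrix(d), groups,
                              control_groups = "control")
  expect_equal(res$sample_report$n_excluded_callrate, 1)
  expect_false("s01" %in% colnames(res$genotypes$dosage))
  expect_false("snp001" %in% rownames(res$genotypes$dosage))
  expect_false("snp002" %in% rownames(res$genotypes$dosage))
  expect_equal(res$snp_report$n_excluded_missing_group, 1)
  expect_equal(res$snp_report$n_excluded_hwe, 1)
})

test_that("a clean matrix passes case-control QC unchanged", {
  set.seed(9)
  d <- matrix(rbinom(200, 2, 0.5), 10, 20,
              dimnames = list(sprintf("snp%02d", 1:10), sprintf("s%02d", 1:20)))
  groups <- setNames(rep(c("case", "control"), each = 10), colnames(d))
  res <- apply_casecontrol_qc(geno_matrix(d), groups)
  expect_equal(res$genotypes$dosage, d)
  expect_equal(res$sample_report$n_excluded_callrate, 0)
  expect_equal(res$snp_report$n_retained, 10)
})
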