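write_toy_freq_tsv <- function(path) {
  lines <- c(
    paste(c("snp_id", "chrom", "pos", "reference_allele", "other_allele",
            "CEU_ref_count", "CEU_total", "TSI_ref_count", "TSI_total"),
          collapse = "\t"),
    "rs1\t1\t100\tA\tG\t12\t20\t30\t100",
    "rs2\t1\t200\tC\tT\t20\t20\t70\t100",
    "rs3\t2\t300\tG\tA\t0\t20\t50\t100")
  writeLines(lines, path)
  path
}

test_that("freq_tsv loads counts into frequencies and call rates", {
  f <- write_toy_freq_tsv(withr::local_tempfile(fileext = ".tsv"))
  panel <- load_panel(f, "freq_tsv", pop_sizes = c(CEU = 10, TSI = 50))
  expect_equal(unname(panel$freq[, "CEU"]), c(0.6, 1.0, 0.0))
  expect_equal(unname(panel$call_rate[, "CEU"]), c(1, 1, 1))
  expect_equal(panel$snps$pos, c(100L, 200L, 300L))
  # round trip through the writer preserves counts
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_freq_tsv(panel, f2)
  panel2 <- load_panel(f2, "freq_tsv")
  expect_equal(panel2$freq, panel$freq)
})

test_that("malformed and duplicated freq_tsv input is rejected with context", {
  f <- withr::local_tempfile(fileext = ".tsv")
  lines <- readLines(write_toy_freq_tsv(withr::local_tempfile(fileext = ".tsv")))
  writeLines(c(lines, "rs4\t1\t400"), f)           # truncated line
  expect_error(load_panel(f, "freq_tsv"), "malformed line 5")
  writeLines(c(lines, lines[2]), f)                # duplicate rs1
  expect_error(load_panel(f, "freq_tsv"), "duplicate snp_id")
})

test_that("genotype TSV yields allele-counted frequencies and call rates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  # 20 samples; snpA has exactly 1 missing entry (call rate 0.95)
  set.seed(5)
  d <- rbind(snpA = c(NA, rep(c(0, 1, 2), length.out = 19)),
             snpB = rep(c(1, 1, 0, 2), 5))
  tab <- data.frame(snp_id = rownames(d), d, check.names = FALSE)
  colnames(tab) <- c("snp_id", sprintf("s%02d", 1:20))
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  panel <- load_panel(f, "genotype_tsv")
  expect_equal(unname(panel$call_rate["snpA", "ALL"]), 0.95)
  expect_equal(unname(panel$freq["snpB", "ALL"]), mean(rep(c(1, 1, 0, 2), 5)) / 2)
  expect_true(all(panel$hwe_p >= 0 & panel$hwe_p <= 1))
})

test_that("VCF genotypes are counted on the REF allele and multi-allelics dropped", {
  skip_if_not_installed("vcfR")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t300\trs3\tT\tC\t.\tPASS\t.\tGT\t0/1\t./.\t0/1"), f)
  expect_warning(panel <- load_panel(f, "vcf"), "multi-allelic")
  expect_equal(panel$snps$snp_id, c("rs1", "rs3"))
  expect_equal(unname(panel$freq["rs1", "ALL"]), 0.5)
  expect_equal(unname(panel$call_rate["rs3", "ALL"]), 2 / 3)
})

test_that("a simulated cohort round-trips through the minimal VCF writer", {
  skip_if_not_installed("vcfR")
  cfg <- sim_config(n_snps = 12, group_sizes = c(White = 30),
                    fst_per_group = c(White = 0.05), missing_rate = 0.1,
                    seed = 3)
  panel0 <- simulate_frequency_panel(cfg)
  geno <- simulate_genotypes(panel0, cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(geno, panel0$snps, f)
  panel <- load_panel(f, "vcf")
  d <- geno$dosage
  expect_equal(unname(panel$freq[, "ALL"]),
               unname(rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d)))))
})

test_that("pooling is allele-count-weighted and flags missing sources", {
  panel <- toy_source_panel()
  pooled <- pool_groups(panel)
  # counts 30/100 and 70/100 pool to 0.5
  expect_equal(unname(pooled$freq["rs1", "White"]), 0.5)
  # identical source frequencies are unchanged by pooling
  expect_equal(unname(pooled$freq["rs2", "White"]), 0.20)
  # weighted-mean oracle with unequal chromosome counts
  p2 <- panel
  p2$n_alleles[1, "CEU"] <- 226; p2$ref_count[1, "CEU"] <- 45
  p2$n_alleles[1, "TSI"] <- 204; p2$ref_count[1, "TSI"] <- 61
  p2$freq <- p2$ref_count / p2$n_alleles
  pooled2 <- pool_groups(p2)
  expect_equal(unname(pooled2$freq["rs1", "White"]),
               stats::weighted.mean(c(45 / 226, 61 / 204), c(226, 204)))
  # a missing source population propagates NA to the pooled group
  p3 <- panel
  p3$ref_count[2, "CHB"] <- NA
  expect_true(is.na(pool_groups(p3)$freq["rs2", "EastAsian"]))
  expect_false(anyNA(pool_groups(p3)$freq[, "White"]))
})

test_that("pooling is idempotent and commutes with record order", {
  panel <- toy_source_panel()
  pooled <- pool_groups(panel)
  # identity pooling of an already-pooled panel changes nothing
  again <- pool_groups(pooled, list(White = "White", EastAsian = "EastAsian",
                                    African = "African"))
  expect_equal(again$freq, pooled$freq)
  # reversing SNP order then pooling equals pooling then reversing
  rev_panel <- toy_source_panel()
  ord <- rev(seq_len(n_snps(rev_panel)))
  rev_panel$snps <- rev_panel$snps[ord, ]
  for (m in c("freq", "ref_count", "n_alleles", "call_rate")) {
    rev_panel[[m]] <- rev_panel[[m]][ord, ]
  }
  pooled_rev <- pool_groups(rev_panel)
  expect_equal(pooled_rev$freq[pooled$snps$snp_id, ], pooled$freq)
})
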