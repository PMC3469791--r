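qc_report <- function(n_input, exclusions, n_retained) {
  .assert(n_retained + sum(unlist(exclusions)) == n_input,
          "QC accounting error: exclusions + retained != input")
  structure(c(list(n_input = n_input), exclusions,
              list(n_retained = n_retained)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  for (f in names(x)) cat(sprintf("  %-28s %d\n", f, x[[f]]))
  invisible(x)
}

#' Panel-level SNP quality control
#'
#' Applies the frequency-panel exclusion filters: a SNP is retained only if
#' (1) every analysis group has a defined pooled frequency, (2) the pooled
#' call rate is at least `callrate_min` in every group, and (3) the
#' Hardy-Weinberg exact p-value is at least `hwe_alpha` in every source
#' population where it is assessable. Filters are applied in that order
#' (availability, call rate, HWE) and each excluded SNP is tallied under
#' its first failing filter, so the report counts partition the input.
#'
#' @param panel a source-population `pop_panel`; pooled groups are taken
#'   from `group_definitions` (defaulting to each population as its own
#'   group).
#' @param callrate_min minimum per-group call rate (default 0.95).
#' @param hwe_alpha HWE exclusion threshold (default 1e-7).
#' @param group_definitions named list group -> source populations.
#' @return list with `panel` (the filtered source-level panel) and
#'   `report` (a `qc_report`).
#' @export
apply_panel_qc <- function(panel, callrate_min = 0.95, hwe_alpha = 1e-7,
                           group_definitions = panel$group_definitions) {
  .assert(inherits(panel, "pop_panel"), "panel must be a pop_panel")
  .assert(callrate_min >= 0 && callrate_min <= 1, "callrate_min must be in [0,1]")
  .assert(hwe_alpha > 0 && hwe_alpha < 1, "hwe_alpha must be in (0,1)")
  if (is.null(group_definitions)) {
    group_definitions <- as.list(setNames(panel_populations(panel),
                                          panel_populations(panel)))
  }
  nsnp <- n_snps(panel)
  can_pool <- !is.null(panel$ref_count) && !is.null(panel$n_alleles)
  if (can_pool) {
    pooled <- pool_groups(panel, group_definitions)
    gfreq <- pooled$freq
    gcall <- pooled$call_rate
  } else {
    # frequency-only panels: evaluate availability/call rate per source
    gfreq <- panel$freq
    gcall <- panel$call_rate
  }
  missing_any <- rowSums(is.na(gfreq)) > 0
  if (is.null(gcall)) gcall <- matrix(1, nsnp, 1)
  low_call <- rowSums(gcall < callrate_min, na.rm = TRUE) > 0
  if (is.null(panel$hwe_p)) {
    hwe_fail <- rep(FALSE, nsnp)
  } else {
    hwe_fail <- rowSums(panel$hwe_p < hwe_alpha, na.rm = TRUE) > 0
  }
  first_fail <- rep("retained", nsnp)
  first_fail[hwe_fail] <- "hwe"
  first_fail[low_call] <- "callrate"
  first_fail[missing_any] <- "missing_source"
  keep <- first_fail == "retained"
  report <- qc_report(
    n_input = nsnp,
    exclusions = list(
      n_excluded_missing_source = sum(first_fail == "missing_source"),
      n_excluded_callrate = sum(first_fail == "callrate"),
      n_excluded_hwe = sum(first_fail == "hwe")),
    n_retained = sum(keep))
  list(panel = .subset_panel(panel, keep), report = report)
}

.subset_panel <- function(panel, keep) {
  sub <- function(m) if (is.null(m)) NULL else m[keep, , drop = FALSE]
  pop_panel(panel$snps[keep, , drop = FALSE],
            sub(panel$freq), ref_count = sub(panel$ref_count),
            n_alleles = sub(panel$n_alleles), call_rate = sub(panel$call_rate),
            hwe_p = sub(panel$hwe_p),
            group_definitions = panel$group_definitions)
}

#' Case-control genotyping quality control
#'
#' Sample-then-SNP QC for a case-control genotype matrix: samples with a
#' call rate below `sample_callrate_min` are dropped first; then SNPs are
#' excluded that deviate from Hardy-Weinberg equilibrium in any designated
#' control group (exact p below `control_hwe_alpha`) or that have more
#' than `max_group_missing` missing data in any subject group. SNP
#' exclusions are tallied by first failing filter (HWE, then missingness).
#'
#' @param geno a `geno_matrix`.
#' @param subject_groups named character vector sample_id -> subject-group
#'   label (e.g., study-by-status strata).
#' @param control_groups labels of `subject_groups` whose samples are
#'   controls for the HWE check; defaults to none (HWE check skipped).
#' @param sample_callrate_min minimum per-sample call rate (default 0.98).
#' @param control_hwe_alpha HWE exclusion threshold in controls
#'   (default 1e-5).
#' @param max_group_missing maximum missingness per subject group
#'   (default 0.05, exclusive bound: > 5\% missing fails).
#' @return list with `genotypes` (filtered `geno_matrix`),
#'   `sample_report`, and `snp_report`.
#' @export
apply_casecontrol_qc <- function(geno, subject_groups,
                                 control_groups = character(0),
                                 sample_callrate_min = 0.98,
                                 control_hwe_alpha = 1e-5,
                                 max_group_missing = 0.05) {
  .assert(inherits(geno, "geno_matrix"), "geno must be a geno_matrix")
  samples <- colnames(geno$dosage)
  .assert(all(samples %in% names(subject_groups)),
          "subject_groups must cover every sample")
  .assert(all(control_groups %in% subject_groups),
          "control_groups must be labels used in subject_groups")

  sample_cr <- colMeans(!is.na(geno$dosage))
  keep_samples <- sample_cr >= sample_callrate_min
  d <- geno$dosage[, keep_samples, drop = FALSE]
  grp <- unname(subject_groups[colnames(d)])

  nsnp <- nrow(d)
  hwe_fail <- rep(FALSE, nsnp)
  for (cg in control_groups) {
    dc <- d[, grp == cg, drop = FALSE]
    n2 <- rowSums(dc == 2, na.rm = TRUE)
    n1 <- rowSums(dc == 1, na.rm = TRUE)
    n0 <- rowSums(dc == 0, na.rm = TRUE)
    p <- vapply(seq_len(nsnp), function(i) {
      if (n2[i] + n1[i] + n0[i] == 0) return(NA_real_)
      hwe_exact_test(n2[i], n1[i], n0[i])
    }, numeric(1))
    hwe_fail <- hwe_fail | (!is.na(p) & p < control_hwe_alpha)
  }
  miss_fail <- rep(FALSE, nsnp)
  for (g in unique(grp)) {
    dg <- d[, grp == g, drop = FALSE]
    miss_fail <- miss_fail | (rowMeans(is.na(dg)) > max_group_missing)
  }
  first_fail <- rep("retained", nsnp)
  first_fail[miss_fail] <- "missing"
  first_fail[hwe_fail] <- "hwe"
  keep_snps <- first_fail == "retained"

  sample_report <- qc_report(
    n_input = length(samples),
    exclusions = list(n_excluded_callrate = sum(!keep_samples)),
    n_retained = sum(keep_samples))
  snp_report <- qc_report(
    n_input = nsnp,
    exclusions = list(n_excluded_hwe = sum(first_fail == "hwe"),
                      n_excluded_missing_group = sum(first_fail == "missing")),
    n_retained = sum(keep_snps))

  out <- geno_matrix(d[keep_snps, , drop = FALSE],
                     sample_info = geno$sample_info[keep_samples, , drop = FALSE],
                     coded_allele = geno$coded_allele[keep_snps])
  list(genotypes = out, sample_report = sample_report, snp_report = snp_report)
}
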