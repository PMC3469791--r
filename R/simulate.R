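#' Simulate a multi-group allele-frequency panel (Balding-Nichols)
#'
#' Draws, for each SNP, an ancestral reference-allele frequency p uniformly
#' from the configured range, then one frequency per group from a Beta
#' distribution with mean p and variance F p(1 - p), where F is that
#' group's differentiation parameter (the Balding-Nichols model). Loci are
#' independent; the panel carries ideal QC metadata (call rate 1) since
#' group frequencies here are population parameters, not sample estimates.
#'
#' @param config a [sim_config()].
#' @return A [pop_panel()] whose columns are the configured groups, with
#'   the ancestral frequencies stored in `attr(panel, "ancestral_freq")`.
#' @export
simulate_frequency_panel <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(.substream(config$seed, 1L))
  nsnp <- config$n_snps
  groups <- names(config$group_sizes)
  p0 <- runif(nsnp, config$ancestral_freq_range[1], config$ancestral_freq_range[2])
  freq <- matrix(NA_real_, nsnp, length(groups),
                 dimnames = list(NULL, groups))
  for (g in groups) {
    f <- config$fst_per_group[[g]]
    freq[, g] <- rbeta(nsnp, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  }
  snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(nsnp)),
                     chrom = "1", pos = seq_len(nsnp) * 1000L,
                     reference_allele = "A", other_allele = "B",
                     stringsAsFactors = FALSE)
  call_rate <- matrix(1, nsnp, length(groups),
                      dimnames = list(snps$snp_id, groups))
  panel <- pop_panel(snps, freq, call_rate = call_rate)
  attr(panel, "ancestral_freq") <- p0
  attr(panel, "config") <- config
  panel
}

#' Simulate group genotypes under Hardy-Weinberg equilibrium
#'
#' Draws diploid genotypes per group from the panel's group frequencies
#' under HWE (dosage of the reference allele ~ Binomial(2, p)), then
#' injects missingness completely at random at the configured rate.
#'
#' @param panel a `pop_panel` with one column per configured group.
#' @param config a [sim_config()].
#' @return A [geno_matrix()] whose `sample_info` carries each sample's
#'   group.
#' @export
simulate_genotypes <- function(panel, config) {
  .assert(inherits(panel, "pop_panel"), "panel must be a pop_panel")
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  groups <- names(config$group_sizes)
  .assert(all(groups %in% panel_populations(panel)),
          "panel must have a frequency column for every group")
  set.seed(.substream(config$seed, 2L))
  nsnp <- n_snps(panel)
  blocks <- lapply(groups, function(g) {
    n <- config$group_sizes[[g]]
    matrix(rbinom(nsnp * n, 2, rep(panel$freq[, g], times = n)), nrow = nsnp)
  })
  dosage <- do.call(cbind, blocks)
  grp <- rep(groups, times = config$group_sizes[groups])
  colnames(dosage) <- sprintf("%s_%04d", grp, unlist(lapply(
    config$group_sizes[groups], seq_len)))
  rownames(dosage) <- panel$snps$snp_id
  if (config$missing_rate > 0) {
    drop <- runif(length(dosage)) < config$missing_rate
    dosage[drop] <- NA_real_
  }
  geno_matrix(dosage,
              sample_info = data.frame(sample_id = colnames(dosage),
                                       group = grp,
                                       stringsAsFactors = FALSE),
              coded_allele = panel$snps$reference_allele)
}

# internal: per-subject disease probability from planted genotypes.
# `risk_dosage` is a matrix (planted SNPs x subjects) of risk-allele copies.
.planted_risk <- function(risk_dosage, planted, baseline) {
  risk <- rep(baseline, ncol(risk_dosage))
  for (i in seq_along(planted)) {
    g <- grr_from_or(planted[[i]]$per_allele_or, planted[[i]]$grr_scale)
    risk <- risk * c(g$g0, g$g1, g$g2)[risk_dosage[i, ] + 1]
  }
  risk
}

# internal: risk-allele dosage from reference-allele dosage
.to_risk_dosage <- function(ref_dosage, planted) {
  out <- ref_dosage
  for (i in seq_along(planted)) {
    if (planted[[i]]$risk_allele == "alt") out[i, ] <- 2 - out[i, ]
  }
  out
}

#' Simulate a case-control cohort under a planted disease model
#'
#' Samples subjects from one configured group, assigns disease status with
#' probability `baseline_risk` multiplied by the genotypic relative risk of
#' each planted SNP (risks multiply across loci; genotypes at distinct loci
#' are independent), and accumulates subjects until the case and control
#' quotas are both met. Non-planted SNPs are null: their genotypes are
#' drawn from the same group frequencies independently of status.
#' Missingness is injected into the returned genotypes at the configured
#' rate (status is determined by the true genotypes).
#'
#' @param panel a `pop_panel` from [simulate_frequency_panel()].
#' @param config a [sim_config()]; `case_control_group`, `n_cases`,
#'   `n_controls`, `baseline_risk` and `planted_snps` drive the sampler.
#' @return list with `genotypes` (a [geno_matrix()], reference-allele
#'   dosage), `phenotypes` (data.frame `sample_id`, `status`, `group`),
#'   and `empirical_incidence` (disease rate observed in the sampling
#'   stream before quota selection).
#' @export
simulate_case_control <- function(panel, config) {
  .assert(inherits(panel, "pop_panel"), "panel must be a pop_panel")
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  grp <- config$case_control_group
  .assert(grp %in% panel_populations(panel),
          "case_control_group missing from panel")
  set.seed(.substream(config$seed, 3L))
  planted <- config$planted_snps
  pidx <- vapply(planted, `[[`, integer(1), "snp_index")
  p_grp <- panel$freq[, grp]
  nsnp <- n_snps(panel)

  n_needed <- c(cases = config$n_cases, controls = config$n_controls)
  case_geno <- list(); control_geno <- list()
  n_have <- c(cases = 0L, controls = 0L)
  n_stream <- 0L; n_diseased <- 0L
  batch <- max(10000L, 4L * (config$n_cases + config$n_controls))
  guard <- 0L
  while (any(n_have < n_needed)) {
    guard <- guard + 1L
    .assert(guard <= 10000L, "case/control sampling did not reach quotas")
    # planted-SNP genotypes for the batch (reference-allele dosage)
    if (length(pidx) > 0) {
      pg <- matrix(rbinom(length(pidx) * batch, 2,
                          rep(p_grp[pidx], times = batch)),
                   nrow = length(pidx))
      risk <- .planted_risk(.to_risk_dosage(pg, planted), planted,
                            config$baseline_risk)
    } else {
      pg <- matrix(numeric(0), nrow = 0, ncol = batch)
      risk <- rep(config$baseline_risk, batch)
    }
    status <- rbinom(batch, 1, risk)
    n_stream <- n_stream + batch
    n_diseased <- n_diseased + sum(status)
    take_case <- which(status == 1)[seq_len(min(sum(status == 1),
                                                n_needed["cases"] - n_have["cases"]))]
    take_ctrl <- which(status == 0)[seq_len(min(sum(status == 0),
                                                n_needed["controls"] - n_have["controls"]))]
    if (length(take_case)) case_geno[[length(case_geno) + 1L]] <-
      pg[, take_case, drop = FALSE]
    if (length(take_ctrl)) control_geno[[length(control_geno) + 1L]] <-
      pg[, take_ctrl, drop = FALSE]
    n_have <- n_have + c(length(take_case), length(take_ctrl))
  }
  n_total <- sum(n_needed)
  planted_dosage <- do.call(cbind, c(case_geno, control_geno))
  status <- rep(c(1L, 0L), times = n_needed)

  # null SNPs are independent of status, so they are drawn only for the
  # retained subjects (exchangeable with drawing them for the full stream)
  dosage <- matrix(rbinom(nsnp * n_total, 2, rep(p_grp, times = n_total)),
                   nrow = nsnp)
  if (length(pidx) > 0) dosage[pidx, ] <- planted_dosage
  rownames(dosage) <- panel$snps$snp_id
  colnames(dosage) <- sprintf("subj_%05d", seq_len(n_total))
  if (config$missing_rate > 0) {
    drop <- runif(length(dosage)) < config$missing_rate
    dosage[drop] <- NA_real_
  }
  phenotypes <- data.frame(sample_id = colnames(dosage), status = status,
                           group = grp, stringsAsFactors = FALSE)
  list(genotypes = geno_matrix(dosage,
                               sample_info = phenotypes[, c("sample_id", "group")],
                               coded_allele = panel$snps$reference_allele),
       phenotypes = phenotypes,
       empirical_incidence = n_diseased / n_stream)
}

#' Empirical disease incidence per group under the planted model
#'
#' Simulates `n_per_group` subjects in each group, applies the planted
#' genotypic-relative-risk disease model, and returns the observed disease
#' rate per group. As `n_per_group` grows, the ratio of two groups' rates
#' converges to the analytic single-locus [incidence_rate_ratio()] (for
#' one planted SNP) since both are HWE-weighted averages of the GRRs.
#'
#' @param panel a `pop_panel`.
#' @param config a [sim_config()] with planted effects.
#' @param n_per_group subjects to simulate per group.
#' @return named numeric vector of disease rates.
#' @export
simulate_incidence <- function(panel, config, n_per_group = 1e5) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(.substream(config$seed, 4L))
  planted <- config$planted_snps
  pidx <- vapply(planted, `[[`, integer(1), "snp_index")
  groups <- names(config$group_sizes)
  out <- setNames(numeric(length(groups)), groups)
  for (g in groups) {
    if (length(pidx) > 0) {
      pg <- matrix(rbinom(length(pidx) * n_per_group, 2,
                          rep(panel$freq[pidx, g], times = n_per_group)),
                   nrow = length(pidx))
      risk <- .planted_risk(.to_risk_dosage(pg, planted), planted,
                            config$baseline_risk)
    } else {
      risk <- rep(config$baseline_risk, n_per_group)
    }
    out[g] <- mean(rbinom(n_per_group, 1, risk))
  }
  out
}
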