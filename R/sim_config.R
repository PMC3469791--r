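#' Planted disease effect at a simulated SNP
#'
#' Describes a single locus that carries disease risk in the simulated
#' case-control cohort: which allele is the risk allele, the per-allele odds
#' ratio, and how the homozygote genotypic relative risk (GRR) is built from
#' it. Under `additive_risk` the GRRs for 0/1/2 risk-allele copies are
#' (1, OR, 1 + 2(OR - 1)); under `multiplicative` they are (1, OR, OR^2).
#'
#' @param snp_index 1-based index of the SNP in the simulated panel.
#' @param per_allele_or positive per-allele odds ratio of the risk allele.
#' @param risk_allele `"ref"` (the panel's reference allele) or `"alt"`.
#' @param grr_scale `"multiplicative"` or `"additive_risk"`.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(snp_index, per_allele_or,
                           risk_allele = c("ref", "alt"),
                           grr_scale = c("multiplicative", "additive_risk")) {
  risk_allele <- match.arg(risk_allele)
  grr_scale <- match.arg(grr_scale)
  .assert(is.numeric(snp_index) && length(snp_index) == 1 && snp_index >= 1,
          "snp_index must be a positive index")
  .assert(is.numeric(per_allele_or) && per_allele_or > 0,
          "per_allele_or must be > 0")
  structure(list(snp_index = as.integer(snp_index),
                 per_allele_or = per_allele_or,
                 risk_allele = risk_allele,
                 grr_scale = grr_scale),
            class = "planted_effect")
}

#' Simulation configuration for panels and case-control cohorts
#'
#' One configuration object drives the three simulator stages (frequency
#' panel, group genotypes, case-control cohort). Defaults emulate a
#' HapMap-III-like three-group design: group sizes match the unrelated
#' sample counts of the pooled CEU+TSI, CHB+JPT, and YRI+LWK panels, and
#' the case/control quotas match a discovery set of 692 cases and 3,992
#' controls. Differentiation is controlled per group by a Balding-Nichols
#' F parameter relative to a shared ancestral frequency.
#'
#' @param n_snps number of independent SNPs to simulate.
#' @param group_sizes named vector of diploid sample counts per group.
#' @param fst_per_group named vector of Balding-Nichols differentiation
#'   parameters in (0, 1), one per group.
#' @param ancestral_freq_range range the ancestral reference-allele
#'   frequency is drawn from (uniform).
#' @param missing_rate genotype missingness proportion, missing completely
#'   at random, in `[0, 1)`.
#' @param planted_snps list of [planted_effect()] objects (possibly empty).
#' @param n_cases,n_controls case/control quotas for the cohort sampler.
#' @param baseline_risk disease probability for a subject with zero risk
#'   alleles at every planted SNP; multiplied by each planted GRR.
#' @param case_control_group which group the case-control cohort is drawn
#'   from (the study design samples a single ancestry).
#' @param seed integer seed; every simulator stage derives its own
#'   deterministic sub-stream from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_snps = 1000,
                       group_sizes = c(White = 215, EastAsian = 250, African = 257),
                       fst_per_group = c(White = 0.05, EastAsian = 0.12, African = 0.15),
                       ancestral_freq_range = c(0.05, 0.95),
                       missing_rate = 0.02,
                       planted_snps = list(),
                       n_cases = 692,
                       n_controls = 3992,
                       baseline_risk = 0.005,
                       case_control_group = names(group_sizes)[1],
                       seed = 1L) {
  .assert(is.numeric(n_snps) && n_snps >= 1, "n_snps must be a positive count")
  .assert(length(group_sizes) >= 1 && !is.null(names(group_sizes)) &&
            all(nzchar(names(group_sizes))), "group_sizes must be named")
  .assert(all(group_sizes >= 1), "group sizes must be positive")
  .assert(identical(sort(names(group_sizes)), sort(names(fst_per_group))),
          "fst_per_group must name the same groups as group_sizes")
  .assert(all(fst_per_group > 0 & fst_per_group < 1),
          "Balding-Nichols F must lie in (0, 1)")
  .assert(length(ancestral_freq_range) == 2 &&
            all(ancestral_freq_range > 0 & ancestral_freq_range < 1) &&
            ancestral_freq_range[1] <= ancestral_freq_range[2],
          "ancestral_freq_range must be an increasing pair in (0, 1)")
  .assert(is.numeric(missing_rate) && missing_rate >= 0 && missing_rate < 1,
          "missing_rate must be in [0, 1)")
  .assert(is.list(planted_snps) &&
            all(vapply(planted_snps, inherits, logical(1), "planted_effect")),
          "planted_snps must be a list of planted_effect objects")
  idx <- vapply(planted_snps, `[[`, integer(1), "snp_index")
  .assert(!anyDuplicated(idx), "planted SNP indices must be distinct")
  .assert(all(idx <= n_snps), "planted SNP indices must be <= n_snps")
  .assert(n_cases >= 1 && n_controls >= 1, "case/control quotas must be positive")
  .assert(is.numeric(baseline_risk) && baseline_risk > 0 && baseline_risk < 1,
          "baseline_risk must be in (0, 1)")
  .assert(case_control_group %in% names(group_sizes),
          "case_control_group must be one of the defined groups")
  # the planted model multiplies risks, so the largest achievable risk must
  # still be a probability
  max_grr <- prod(vapply(planted_snps, function(pe) {
    g <- grr_from_or(pe$per_allele_or, pe$grr_scale)
    max(g$g0, g$g1, g$g2)
  }, numeric(1)))
  if (length(planted_snps) == 0) max_grr <- 1
  .assert(baseline_risk * max_grr <= 1,
          "baseline_risk x maximal planted GRR exceeds 1 (not a probability)")

  structure(list(n_snps = as.integer(n_snps),
                 group_sizes = group_sizes,
                 fst_per_group = fst_per_group[names(group_sizes)],
                 ancestral_freq_range = ancestral_freq_range,
                 missing_rate = missing_rate,
                 planted_snps = planted_snps,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 baseline_risk = baseline_risk,
                 case_control_group = case_control_group,
                 seed = as.integer(seed)),
            class = "sim_config")
}
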