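#' Genotypic relative risk model
#'
#' Holds the relative disease risks (g0, g1, g2) for carrying 0, 1, or 2
#' copies of a risk allele, with g0 fixed at 1. On the `additive_risk`
#' scale the homozygote risk is 1 + 2(g1 - 1); on the `multiplicative`
#' scale it is g1^2; `explicit` accepts any positive pair.
#'
#' @param g1 relative risk for one risk-allele copy (> 0).
#' @param g2 relative risk for two copies; required (and only allowed) when
#'   `scale = "explicit"`.
#' @param scale how g2 is derived from g1.
#' @return A `grr_model` list with elements `g0`, `g1`, `g2`, `scale`.
#' @examples
#' grr_model(2, 3, scale = "explicit")   # the classic 1/2/3 worked example
#' grr_model(1.39)                       # additive-risk: g2 = 1.78
#' @export
grr_model <- function(g1, g2 = NULL,
                      scale = c("additive_risk", "multiplicative", "explicit")) {
  scale <- match.arg(scale)
  .assert(is.numeric(g1) && length(g1) == 1 && g1 > 0, "g1 must be > 0")
  if (scale == "explicit") {
    .assert(!is.null(g2) && is.numeric(g2) && g2 > 0,
            "explicit scale requires g2 > 0")
  } else {
    .assert(is.null(g2), "g2 may only be supplied with scale = 'explicit'")
    g2 <- switch(scale,
                 additive_risk = 1 + 2 * (g1 - 1),
                 multiplicative = g1^2)
    .assert(g2 > 0, "derived g2 is not positive; use the multiplicative scale for strong protective alleles")
  }
  structure(list(g0 = 1, g1 = g1, g2 = g2, scale = scale), class = "grr_model")
}

# internal: GRR model from a per-allele OR on a named scale
grr_from_or <- function(per_allele_or, grr_scale) {
  grr_model(per_allele_or, scale = grr_scale)
}

#' Re-express frequencies and odds ratio on the risk allele
#'
#' The incidence-rate-ratio attribution on the additive-risk GRR scale is
#' not invariant to which allele the inputs describe, so frequencies are
#' always re-expressed for the allele with OR >= 1: if the supplied
#' per-allele OR is below 1, every frequency is complemented and the OR is
#' inverted; otherwise the inputs pass through unchanged.
#'
#' @param freqs numeric vector of allele frequencies (typically named by
#'   population group).
#' @param per_allele_or positive per-allele odds ratio for the allele the
#'   frequencies describe.
#' @return list with elements `freqs` (risk-allele frequencies) and `or`
#'   (oriented odds ratio, >= 1).
#' @examples
#' orient_to_risk_allele(c(White = 0.23, EastAsian = 0.70), 0.68)
#' @export
orient_to_risk_allele <- function(freqs, per_allele_or) {
  .assert(is.numeric(per_allele_or) && length(per_allele_or) == 1 &&
            is.finite(per_allele_or) && per_allele_or > 0,
          "per_allele_or must be > 0")
  .assert(.is_prob(freqs), "frequencies must lie in [0, 1]")
  if (per_allele_or >= 1) {
    list(freqs = freqs, or = per_allele_or)
  } else {
    list(freqs = 1 - freqs, or = 1 / per_allele_or)
  }
}

#' Normalized incidence rate under Hardy-Weinberg proportions
#'
#' Weights the three genotype classes implied by a risk-allele frequency p
#' (proportions q^2, 2pq, p^2 under HWE) by their genotypic relative risks:
#' rate = q^2 g0 + 2pq g1 + p^2 g2. The result is proportional to the
#' population disease incidence under a single-locus model, so ratios of
#' normalized rates between groups estimate incidence rate ratios.
#'
#' @param p_risk risk-allele frequency (vectorized).
#' @param grr a [grr_model()].
#' @return numeric vector of normalized rates.
#' @examples
#' normalized_rate(0.8, grr_model(2, 3, "explicit"))  # 2.60
#' normalized_rate(0.2, grr_model(2, 3, "explicit"))  # 1.40
#' @export
normalized_rate <- function(p_risk, grr) {
  .assert(inherits(grr, "grr_model"), "grr must be a grr_model")
  .assert(.is_prob(p_risk), "p_risk must lie in [0, 1]")
  q <- 1 - p_risk
  q^2 * grr$g0 + 2 * p_risk * q * grr$g1 + p_risk^2 * grr$g2
}

#' Incidence rate ratio attributable to one locus
#'
#' Converts a SNP's per-allele odds ratio and its allele frequencies in two
#' population groups into the disease incidence rate ratio the locus alone
#' would produce. Inputs are first oriented to the risk allele (OR >= 1),
#' a GRR model is built with the heterozygote risk equal to the oriented OR,
#' and the ratio of HWE-weighted normalized rates for the ordered pair is
#' returned.
#'
#' @param freqs named frequencies of one allele per group (any orientation).
#' @param per_allele_or per-allele odds ratio for that allele.
#' @param pair length-2 character vector: numerator group, denominator group.
#' @param grr_scale `"additive_risk"` (default) or `"multiplicative"`.
#' @return positive scalar IRR.
#' @examples
#' incidence_rate_ratio(c(White = 0.23, EastAsian = 0.70, African = 0.02),
#'                      0.68, pair = c("White", "EastAsian"))  # ~1.34
#' @export
incidence_rate_ratio <- function(freqs, per_allele_or,
                                 pair = c("White", "EastAsian"),
                                 grr_scale = c("additive_risk", "multiplicative")) {
  grr_scale <- match.arg(grr_scale)
  .assert(length(pair) == 2, "pair must name two groups")
  .assert(all(pair %in% names(freqs)),
          "pair groups '%s' must appear in names(freqs)", paste(pair, collapse = ","))
  o <- orient_to_risk_allele(freqs, per_allele_or)
  grr <- grr_model(o$or, scale = grr_scale)
  rates <- normalized_rate(o$freqs, grr)
  unname(rates[pair[1]] / rates[pair[2]])
}

#' Per-locus IRR attribution table
#'
#' Batch form of [incidence_rate_ratio()] over a table of loci, appending
#' White/East-Asian and White/African IRR columns. The input mirrors a
#' susceptibility-locus summary: one row per SNP with the reference-allele
#' frequency in each group and the per-allele odds ratio of the reference
#' allele.
#'
#' @param loci data.frame with columns `snp_id`, `or`, and one frequency
#'   column per group named in `groups`.
#' @param groups named character vector mapping the roles `white`,
#'   `east_asian`, `african` to the frequency columns of `loci`.
#' @param grr_scale GRR scale passed through.
#' @param digits rounding applied to the reported IRR columns (reported
#'   attributions conventionally print 2 decimals); use `NULL` for full
#'   precision.
#' @return `loci` with columns `irr_white_east_asian`, `irr_white_african`.
#' @export
irr_attribution <- function(loci,
                            groups = c(white = "White", east_asian = "EastAsian",
                                       african = "African"),
                            grr_scale = "additive_risk",
                            digits = 2) {
  .assert(all(c("snp_id", "or", groups) %in% names(loci)),
          "loci must have snp_id, or, and the group frequency columns")
  n <- nrow(loci)
  we <- wa <- numeric(n)
  for (i in seq_len(n)) {
    f <- c(W = loci[[groups[["white"]]]][i],
           E = loci[[groups[["east_asian"]]]][i],
           A = loci[[groups[["african"]]]][i])
    we[i] <- incidence_rate_ratio(f, loci$or[i], c("W", "E"), grr_scale)
    wa[i] <- incidence_rate_ratio(f, loci$or[i], c("W", "A"), grr_scale)
  }
  if (!is.null(digits)) {
    we <- round(we, digits)
    wa <- round(wa, digits)
  }
  loci$irr_white_east_asian <- we
  loci$irr_white_african <- wa
  loci
}

#' IRR surface over GRR models and frequency pairs
#'
#' Evaluates the single-locus IRR on a grid, one row per combination of a
#' GRR model and a (numerator, denominator) pair of risk-allele
#' frequencies. Suitable for contour/line plots of attributable IRR against
#' the comparison group's allele frequency at several effect sizes.
#'
#' @param grr_models list of [grr_model()] objects.
#' @param freq_pairs list of length-2 numeric vectors
#'   `(p_risk numerator group, p_risk denominator group)`.
#' @return data.frame with columns `g1`, `g2`, `scale`, `p_num`, `p_den`,
#'   `irr`.
#' @export
irr_surface <- function(grr_models, freq_pairs) {
  .assert(length(grr_models) > 0 && length(freq_pairs) > 0,
          "grids must be nonempty")
  .assert(all(vapply(grr_models, inherits, logical(1), "grr_model")),
          "grr_models must be grr_model objects")
  rows <- expand.grid(m = seq_along(grr_models), f = seq_along(freq_pairs))
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    grr <- grr_models[[rows$m[i]]]
    fp <- freq_pairs[[rows$f[i]]]
    data.frame(g1 = grr$g1, g2 = grr$g2, scale = grr$scale,
               p_num = fp[1], p_den = fp[2],
               irr = normalized_rate(fp[1], grr) / normalized_rate(fp[2], grr))
  }))
  rownames(out) <- NULL
  out
}
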