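#' Hardy-Weinberg exact test
#'
#' Two-sided exact test of Hardy-Weinberg proportions from observed
#' genotype counts, by conditional enumeration of the heterozygote count
#' given the allele counts (the standard exact formulation used for array
#' QC). The p-value is the summed probability of all heterozygote counts
#' whose conditional probability does not exceed that of the observed
#' configuration (no mid-p correction), so p lies in (0, 1].
#'
#' @param n_aa,n_ab,n_bb non-negative genotype counts (homozygous for one
#'   allele, heterozygous, homozygous for the other). Which homozygote is
#'   first is immaterial.
#' @return exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)   # ~1: perfect HWE at p = 0.5
#' hwe_exact_test(50, 0, 50)    # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  counts <- c(n_aa, n_ab, n_bb)
  .assert(length(counts) == 3 && all(is.finite(counts)) && all(counts >= 0) &&
            all(counts == round(counts)), "genotype counts must be non-negative integers")
  n <- sum(counts)
  .assert(n > 0, "at least one observed genotype is required")
  n_a <- 2 * n_aa + n_ab           # copies of the first allele
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)         # monomorphic: HWE trivially exact
  # heterozygote counts sharing the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log conditional probability up to the normalizing constant:
  # P(h | n_a, n) proportional to n! 2^h / ((n_a-h)/2)! h! ((n_b-h)/2)!
  logw <- hets * log(2) - lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial((n_b - hets) / 2)
  prob <- exp(logw - max(logw))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_ab, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}
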