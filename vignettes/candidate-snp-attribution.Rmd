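---
title: "Ethnic-differentiation candidate SNPs: selection, association, and incidence-rate-ratio attribution"
author: "ethdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ethnic-differentiation candidate SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethdiff)
```

## The scientific problem

Several diseases — adult glioma is the motivating case — show large,
geographically stable incidence differences between ancestry groups that
are hard to ascribe to environment or access to care. If part of that
difference is genetic, alleles that protect against disease should be
systematically more frequent in the lower-incidence groups. This package
implements the candidate-SNP strategy built on that premise: rank SNPs by
the extremity of their allele-frequency differences between a
high-incidence group ("Whites" in the motivating design, pooled from
CEU-and-TSI-like panels) and two lower-incidence comparison groups (East
Asians, Africans), test only the extreme ones for association in a
case-control cohort of the high-incidence ancestry, and translate any
per-allele odds ratio into the share of the between-group incidence ratio
that the locus could explain.

## Candidate selection

For each SNP with reference-allele frequency $f_W$, $f_E$, $f_A$ in the
three groups, two signed differences are formed, $d_{WE} = f_W - f_E$ and
$d_{WA} = f_W - f_A$. When both differences share a sign (both strictly
nonzero), their mean absolute value $\bar d$ assigns the SNP to

* **Highest**: $\bar d \ge 0.70$,
* **High**: $0.60 \le \bar d < 0.70$,
* **Moderate**: $0.40 \le \bar d < 0.60$,

with closed lower and open upper bounds. Independently of direction
agreement, a SNP with one $|d| \ge 0.70$ and the other $|d| < 0.40$ falls
in the secondary-hypothesis **Highest/Low** stratum (differentiation in
one comparison only). Two interpretation choices were genuinely open and
are fixed here as follows: Highest/Low does *not* require direction
agreement, since the secondary hypothesis explicitly allows distinct
protective alleles per comparison group; and when a same-direction SNP
qualifies for both a mean-difference stratum and Highest/Low (possible
when $\bar d \ge 0.40$), the same-direction stratum wins, keeping the
primary-hypothesis strata intact. Zero difference carries no direction,
so a SNP with $d_{WE} = 0$ can never be "same direction". All assignments
are invariant to relabeling which allele is called "reference" (both
differences negate), which the test suite checks against a brute-force
grid oracle.

The study-wide level $\alpha = 0.05$ is split evenly over the four strata
(equal prior weight on each hypothesis stratum, $\alpha/4 = 0.0125$) and
Bonferroni-divided within: a stratum holding $n$ SNPs is tested at
$(\alpha/4)/n$. With strata of 38, 266, 2,883 and 774 SNPs this yields
$3.29\times10^{-4}$, $4.70\times10^{-5}$, $4.34\times10^{-6}$ and
$1.61\times10^{-5}$. Thresholds are carried at full precision and
reported at three significant figures.

## Panel and genotype quality control

Panel-level filters retain a SNP only if every pooled group has a defined
frequency, every group call rate is at least 95%, and the Hardy-Weinberg
exact p-value is at least $10^{-7}$ in every source population. Filters
apply in that order and each exclusion is attributed to its first failing
filter, so the QC report partitions the input — the combined count is
what matters scientifically; the order is a reporting convention.
Pooling source populations into groups (e.g., CEU + TSI into Whites) is
by allele-count weighting: summed reference-allele counts over summed
totals. Unweighted frequency averaging is a defensible alternative; the
count-weighted form was chosen because it equals the frequency that
would be computed from the concatenated genotype data. Case-control
matrices get the stricter array-QC analogue: samples below 98% call rate
are dropped first, then SNPs failing control-group HWE at $10^{-5}$ or
exceeding 5% missingness in any subject group.

The HWE test is the conditional exact test (enumeration of the
heterozygote count given allele counts), two-sided by the
probability-ordering rule, without mid-p correction — the convention of
array release QC. No installed package provides it, so it is implemented
here and validated against an independent enumeration oracle for every
genotype table with up to 20 subjects.

## Association model

Association uses unconditional logistic regression under an additive
model (0, 1, or 2 copies of the minor allele, coded in the combined
case-control sample; frequency ties at 0.5 break lexicographically by
allele label). Fitting is by iteratively reweighted least squares through
`stats::glm`; quasi-separation is flagged, not fatal, when the estimate
diverges ($|\hat\beta| > 15$) or the fit fails to converge. Population
stratification is adjusted by including the top principal components of
the standardized genotype matrix (each SNP centered by $2\hat p$ and
scaled by $\sqrt{2\hat p(1-\hat p)}$, missing dosages mean-imputed for
the PCA only; in regression, samples missing a SNP's genotype are dropped
for that SNP). Two components are the default — enough to capture the
dominant axes of a three-group design — and the count is configurable;
component signs are fixed so the largest-magnitude loading is positive,
making reruns reproducible.

Because the hypothesis is directional (the comparison-enriched allele is
protective), reported p-values are one-sided: half the two-sided Wald p
when the estimated sign matches the hypothesized direction, and one minus
that otherwise, which is exactly the Wald-z tail probability. The
direction attached to each SNP comes from its difference profile and
flips automatically with any minor-allele re-coding, so the one-sided p
is the same scientific statement under either allele labeling.

Supporting analyses mirror the discovery workflow of such a study:
conditional tests add the conditioning SNP's dosage as a covariate, and
linkage disequilibrium between two SNPs is estimated from unphased
genotypes by EM over the two-locus haplotype frequencies (only the double
heterozygote is phase-ambiguous; convergence at $10^{-10}$ on the
frequencies, cap of 1,000 iterations), reporting $D' = |D|/D_{max}$ and
$r^2$.

## Meta-analysis

Replication evidence pools by the generic inverse-variance method under a
fixed-effects model on the log-OR scale, with Cochran's $Q$ on $k-1$
degrees of freedom for heterogeneity. Published per-study rows can enter
via the reconstructed standard error $(\ln U - \ln L)/(2 \times 1.96)$.
Pooled values printed from rounded per-study confidence intervals do not
round-trip to rounded published meta-analysis rows, so tests pin this
module to hand-computed toys and to an independent fixed-effects
implementation instead.

## The incidence-rate-ratio attribution model

Under HWE, a group with risk-allele frequency $p$ has genotype
proportions $q^2, 2pq, p^2$. Weighting them by genotypic relative risks
$(g_0, g_1, g_2) = (1, g_1, g_2)$ gives the *normalized incidence rate*

$$ R(p) = q^2 + 2pq\,g_1 + p^2 g_2, $$

proportional to population disease incidence under a single-locus model;
the ratio $R(p_1)/R(p_2)$ between two groups is the incidence rate ratio
(IRR) attributable to the locus. In the canonical worked example
($g_1 = 2$, $g_2 = 3$, risk-allele frequencies 0.80 vs 0.20) the rates
are 2.60 and 1.40 and the IRR is 1.86.

Mapping a per-allele odds ratio to $(g_1, g_2)$ is underdetermined. The
default here is the *additive-risk* scale, $g_1 = \mathrm{OR}$ and
$g_2 = 1 + 2(\mathrm{OR} - 1)$, applied after orienting inputs to the
risk allele (frequencies complemented and the OR inverted whenever
OR < 1). This combination reproduces the reported per-locus IRR
contributions of the established glioma susceptibility loci to their
printed two decimals (e.g., rs6010620: White/East-Asian 1.34,
White/African 0.90; rs1412829: 1.22 and 1.30), which is why it is the
default; the multiplicative scale $g_2 = g_1^2$ is available as an
option. Orientation is mandatory under the additive-risk scale because
that scale is not invariant to allele relabeling; with orientation, the
computed IRR is allele-label-free. Note a precision limit: published
input frequencies rounded to two decimals can move a computed IRR by up
to about one unit in its own second decimal, so agreement beyond that is
not attainable from printed inputs.

## The synthetic-data generator

Because the original cohorts are external, the package ships a simulator
whose defaults define the study conditions the tests run under:

* **Panel**: each SNP draws an ancestral frequency uniformly on
  (0.05, 0.95), then one frequency per group from a Beta distribution
  with mean $p$ and variance $F p(1-p)$ (Balding-Nichols). Default group
  sizes (215, 250, 257 diploid samples) mirror the pooled
  HapMap-III-style panels the design uses. Default $F$ values (0.05,
  0.12, 0.15) are in the range of observed European/East-Asian/African
  differentiation; analyses that need a visible supply of extreme
  candidates raise all three to 0.2, which the drivers state explicitly.
* **Genotypes**: HWE within group, dosage $\sim$ Binomial(2, $p$), with
  missingness injected completely at random (default 2%, typical of
  array data after calling).
* **Disease model**: a subject's disease probability is a baseline risk
  (default 0.005, a rare disease) multiplied by the GRR of their genotype
  at each planted locus; risks multiply across loci (independence).
  Case-control sampling draws subjects until the configured quotas
  (defaults 692 cases, 3,992 controls) are met. Genotypes at null loci
  are drawn only for retained subjects — valid because loci are
  independent and null loci do not enter the risk model.
* **Seeding**: one integer seed; each operation derives a fixed
  sub-stream, so stages are independently reproducible.

What the simulator deliberately omits: linkage disequilibrium between
loci (independent sites only), admixed individuals, genotyping error
beyond MCAR missingness, and any subtype structure. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to LD, admixture or differential
missingness in real cohorts.

## Numerical choices and degenerate inputs

* HWE exact p returns 1 for monomorphic sites; all-zero genotype tables
  are an error.
* Logistic fits require at least one case and one control with
  non-missing genotype and a non-constant dosage; anything else errors
  per SNP and is flagged, not fatal, inside the scan.
* PCA excludes zero-variance SNPs before standardizing and rejects
  component counts above the numerical rank.
* EM for haplotype frequencies initializes at linkage equilibrium; a
  degenerate double-heterozygote split (both phase products zero) falls
  back to 0.5.
* Thresholds, IRRs and pooled estimates are kept at full precision
  internally; rounding (three significant figures for thresholds, two
  decimals for IRRs) happens only at the reporting surface.

## Problem sizes in the test suite

The suite favors sizes that make Monte-Carlo bounds tight but cheap: the
null type-I-error check runs 1,000 single-SNP fits at $n = 800$;
planted-OR confidence-interval coverage uses 100 cohorts of 2,000 cases
and 2,000 controls; the family-wise-error check runs the full pipeline on
100 seeded null panels of 150 SNPs (about 15 candidates each); the
simulator-versus-analytic IRR comparison uses 400,000 subjects per group.
Binomial acceptance bounds are fixed in advance at the one-sided 99%
envelope of the claimed rate.

## Known limitations

Single-locus attribution only (no joint multi-locus IRR), no
random-effects meta-analysis, no X-chromosome or imputation handling, no
strand disambiguation of A/T and C/G SNPs, and no power calculations.
The gene-region follow-up operationalizes "direction-inconsistent gene"
as: any follow-up SNP significant two-sided at the discovery cut whose
comparison-enriched allele is estimated risk-increasing; the exclusion
threshold is configurable since reasonable analysts could set it
differently.
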