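.categories <- c("HIGHEST", "HIGH", "MODERATE", "HIGHEST_LOW", "NONE")

#' Categorize inter-group allele-frequency differences
#'
#' Assigns each SNP to one of the candidate categories from its two signed
#' reference-allele frequency differences, d_we (White minus East Asian)
#' and d_wa (White minus African). When the two differences share a sign
#' (both strictly nonzero), their mean absolute difference places the SNP
#' in `HIGHEST` (>= 0.70), `HIGH` (0.60 to < 0.70) or `MODERATE` (0.40 to
#' < 0.60); lower bounds are closed, upper bounds open. Independently of
#' direction agreement, a SNP with exactly one absolute difference >= 0.70
#' and the other < 0.40 is `HIGHEST_LOW` (the one-comparison-only
#' hypothesis). When both a same-direction category and `HIGHEST_LOW`
#' apply, the same-direction category wins for same-direction SNPs and
#' `HIGHEST_LOW` wins otherwise. Everything else is `NONE`. Assignments
#' are invariant to which allele is labelled "reference", since relabeling
#' negates both differences.
#'
#' @param d_we,d_wa signed frequency differences in `[-1, 1]` (vectorized).
#' @return character vector of category labels.
#' @export
categorize <- function(d_we, d_wa) {
  .assert(length(d_we) == length(d_wa), "d_we and d_wa must align")
  ok <- !is.na(d_we) & !is.na(d_wa)
  .assert(all(abs(c(d_we[ok], d_wa[ok])) <= 1), "differences must lie in [-1, 1]")
  dw <- ifelse(ok, d_we, 0)  # unusable rows computed as NONE below
  da <- ifelse(ok, d_wa, 0)
  same_dir <- (dw > 0 & da > 0) | (dw < 0 & da < 0)
  mean_abs <- (abs(dw) + abs(da)) / 2
  hl <- (abs(dw) >= 0.70 & abs(da) < 0.40) |
    (abs(da) >= 0.70 & abs(dw) < 0.40)
  out <- rep("NONE", length(dw))
  out[hl] <- "HIGHEST_LOW"
  sd_cat <- ifelse(mean_abs >= 0.70, "HIGHEST",
                   ifelse(mean_abs >= 0.60, "HIGH",
                          ifelse(mean_abs >= 0.40, "MODERATE", NA)))
  use_sd <- same_dir & !is.na(sd_cat)
  out[use_sd] <- sd_cat[use_sd]
  out[!ok] <- "NONE"
  out
}

#' Difference profiles for every SNP in a panel
#'
#' Computes the two pairwise signed reference-allele frequency differences
#' (White vs. East Asian, White vs. African), the direction-agreement
#' flag, the mean absolute difference (defined only when the differences
#' share a sign), and the candidate category per [categorize()]. SNPs with
#' a missing group frequency are flagged unusable and categorized `NONE`.
#'
#' @param panel a pooled `pop_panel` containing the three role groups.
#' @param groups named character vector mapping roles `white`,
#'   `east_asian`, `african` to panel columns.
#' @return data.frame: `snp_id`, `d_we`, `d_wa`, `same_direction`,
#'   `mean_abs_diff`, `usable`, `category`.
#' @export
difference_profiles <- function(panel,
                                groups = c(white = "White",
                                           east_asian = "EastAsian",
                                           african = "African")) {
  .assert(inherits(panel, "pop_panel"), "panel must be a pop_panel")
  .assert(all(groups %in% panel_populations(panel)),
          "panel lacks required groups: %s",
          paste(setdiff(groups, panel_populations(panel)), collapse = ","))
  fw <- panel$freq[, groups[["white"]]]
  fe <- panel$freq[, groups[["east_asian"]]]
  fa <- panel$freq[, groups[["african"]]]
  d_we <- fw - fe
  d_wa <- fw - fa
  usable <- !is.na(d_we) & !is.na(d_wa)
  if (any(!usable)) {
    warning(sprintf("%d SNP(s) with missing group frequencies are unusable",
                    sum(!usable)))
  }
  same_dir <- usable & ((d_we > 0 & d_wa > 0) | (d_we < 0 & d_wa < 0))
  mean_abs <- ifelse(same_dir, (abs(d_we) + abs(d_wa)) / 2, NA_real_)
  data.frame(snp_id = panel$snps$snp_id,
             d_we = d_we, d_wa = d_wa,
             same_direction = same_dir,
             mean_abs_diff = mean_abs,
             usable = usable,
             category = categorize(d_we, d_wa),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select categorized candidate SNPs
#'
#' Filters the difference profiles of a (QC'd) panel to SNPs falling in
#' any candidate category, attaching the per-category counts as the
#' `"category_counts"` attribute.
#'
#' @inheritParams difference_profiles
#' @return data.frame of profiles with `category != "NONE"`.
#' @export
select_candidates <- function(panel,
                              groups = c(white = "White",
                                         east_asian = "EastAsian",
                                         african = "African")) {
  prof <- difference_profiles(panel, groups)
  sel <- prof[prof$category != "NONE", , drop = FALSE]
  rownames(sel) <- NULL
  counts <- table(factor(sel$category, levels = setdiff(.categories, "NONE")))
  attr(sel, "category_counts") <- setNames(as.integer(counts), names(counts))
  sel
}

#' Category-allocated Bonferroni significance thresholds
#'
#' Splits a study-wide alpha evenly over the four candidate categories
#' (alpha / 4 per subgroup, reflecting equal prior weight on each
#' hypothesis stratum) and Bonferroni-divides each subgroup allowance by
#' its SNP count: threshold = (alpha / 4) / n. Categories with zero SNPs
#' get no threshold. Thresholds are kept at full precision; the `signif_3`
#' column gives the conventional 3-significant-figure presentation.
#'
#' @param counts named vector of SNP counts per category (names from
#'   `HIGHEST`, `HIGH`, `MODERATE`, `HIGHEST_LOW`).
#' @param study_alpha study-wide significance level (default 0.05).
#' @return A `category_thresholds` object: list with `study_alpha`,
#'   `per_subgroup_alpha`, and a `table` data.frame (`category`, `n_snps`,
#'   `threshold`, `signif_3`).
#' @examples
#' category_thresholds(c(HIGHEST = 38, HIGH = 266, MODERATE = 2883,
#'                       HIGHEST_LOW = 774))
#' @export
category_thresholds <- function(counts, study_alpha = 0.05) {
  .assert(study_alpha > 0 && study_alpha < 1, "study_alpha must be in (0,1)")
  .assert(!is.null(names(counts)) &&
            all(names(counts) %in% setdiff(.categories, "NONE")),
          "counts must be named by candidate category")
  .assert(all(counts >= 0) && all(counts == round(counts)),
          "counts must be non-negative integers")
  per_subgroup <- study_alpha / 4
  thr <- ifelse(counts > 0, per_subgroup / counts, NA_real_)
  structure(list(study_alpha = study_alpha,
                 per_subgroup_alpha = per_subgroup,
                 table = data.frame(category = names(counts),
                                    n_snps = as.integer(counts),
                                    threshold = unname(thr),
                                    signif_3 = signif(unname(thr), 3),
                                    stringsAsFactors = FALSE)),
            class = "category_thresholds")
}

#' @export
print.category_thresholds <- function(x, ...) {
  cat(sprintf("category thresholds (study alpha %.3g, %.4g per subgroup)\n",
              x$study_alpha, x$per_subgroup_alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}
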