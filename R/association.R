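#' Additive-model logistic association test for one SNP
#'
#' Unconditional logistic regression of case status on allele dosage
#' (0, 1, or 2 copies of the coded allele) plus optional covariates,
#' fitted by iteratively reweighted least squares via `stats::glm`.
#' Samples with missing dosage are dropped for this SNP. Reports the Wald
#' per-allele log-odds estimate, standard error, odds ratio with 95\% CI,
#' the two-sided p, and a one-sided p for a prespecified direction: the
#' one-sided p equals half the two-sided p when the estimated sign matches
#' the hypothesized direction, and one minus half the two-sided p
#' otherwise (the Wald-z tail convention).
#'
#' @param dosage numeric vector of 0/1/2/NA dosages.
#' @param status binary vector (1 = case), aligned with `dosage`.
#' @param covariates optional numeric matrix/data.frame of adjustment
#'   covariates (e.g., principal components), aligned with `dosage`.
#' @param alternative direction of the one-sided hypothesis on the dosage
#'   coefficient: `"less"` (coded allele protective), `"greater"`, or
#'   `"two.sided"` (one-sided p reported as NA).
#' @param snp_id optional label copied into the result.
#' @return one-row data.frame: `snp_id`, `n_used`, `beta`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p_two_sided`, `p_one_sided`, `converged`.
#' @export
fit_additive_logistic <- function(dosage, status, covariates = NULL,
                                  alternative = c("two.sided", "less", "greater"),
                                  snp_id = NA_character_) {
  alternative <- match.arg(alternative)
  .assert(length(dosage) == length(status), "dosage and status must align")
  .assert(all(status %in% 0:1), "status must be binary 0/1")
  df <- data.frame(y = status, g = dosage)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    .assert(nrow(covariates) == length(dosage),
            "covariates must align with dosage")
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  .assert(sum(df$y == 1) >= 1 && sum(df$y == 0) >= 1,
          "need at least one case and one control with non-missing data")
  .assert(stats::var(df$g) > 0, "dosage is constant among usable samples")

  fit <- suppressWarnings(glm(y ~ ., family = binomial(), data = df))
  sm <- suppressWarnings(summary(fit))$coefficients
  beta <- sm["g", "Estimate"]
  se <- sm["g", "Std. Error"]
  # quasi-separation shows up as a diverging estimate with a huge SE
  converged <- isTRUE(fit$converged) && is.finite(beta) && is.finite(se) &&
    abs(beta) < 15
  z <- beta / se
  p_two <- 2 * pnorm(-abs(z))
  p_one <- switch(alternative,
                  two.sided = NA_real_,
                  less = pnorm(z),
                  greater = pnorm(-z))
  crit <- qnorm(0.975)
  data.frame(snp_id = snp_id, n_used = nrow(df),
             beta = beta, se = se, or = exp(beta),
             ci_low = exp(beta - crit * se), ci_high = exp(beta + crit * se),
             p_two_sided = p_two, p_one_sided = p_one,
             converged = converged, stringsAsFactors = FALSE)
}

#' Association scan over a genotype matrix
#'
#' Runs [fit_additive_logistic()] for every SNP. By default each SNP is
#' re-coded to count its minor allele in the combined case-control sample
#' (the additive-model convention); ties at frequency 0.5 keep the
#' lexicographically smaller allele label. A per-SNP `alternative` vector
#' carries the one-sided hypothesis direction, expressed for the coded
#' allele after any re-coding.
#'
#' @param geno a [geno_matrix()].
#' @param phenotypes data.frame with `sample_id` and `status` covering the
#'   genotype samples.
#' @param covariates optional matrix/data.frame of per-sample covariates
#'   (rows aligned with the genotype samples).
#' @param code `"minor"` (default) re-codes to the minor allele;
#'   `"as_is"` keeps the stored coding.
#' @param alternative single value or per-SNP vector of one-sided
#'   directions interpreted for the allele coding *before* re-coding; the
#'   direction flips with the dosage when a SNP is re-coded.
#' @return data.frame of per-SNP results with `coded_allele` and
#'   `flipped` columns.
#' @export
association_scan <- function(geno, phenotypes, covariates = NULL,
                             code = c("minor", "as_is"),
                             alternative = "two.sided") {
  code <- match.arg(code)
  .assert(inherits(geno, "geno_matrix"), "geno must be a geno_matrix")
  .assert(all(colnames(geno$dosage) %in% phenotypes$sample_id),
          "phenotypes must cover every genotype sample")
  status <- phenotypes$status[match(colnames(geno$dosage),
                                    phenotypes$sample_id)]
  nsnp <- nrow(geno$dosage)
  alternative <- rep(alternative, length.out = nsnp)
  flip_alt <- c(two.sided = "two.sided", less = "greater", greater = "less")
  rows <- vector("list", nsnp)
  for (i in seq_len(nsnp)) {
    d <- geno$dosage[i, ]
    alt <- alternative[i]
    flipped <- FALSE
    coded <- geno$coded_allele[i] %||% "A"
    other <- if (identical(coded, "A")) "B" else "A"
    if (code == "minor") {
      f <- mean(d, na.rm = TRUE) / 2
      if (!is.nan(f) && (f > 0.5 || (f == 0.5 && other < coded))) {
        d <- 2 - d
        alt <- flip_alt[[alt]]
        flipped <- TRUE
        tmp <- coded; coded <- other; other <- tmp
      }
    }
    res <- tryCatch(
      fit_additive_logistic(d, status, covariates, alternative = alt,
                            snp_id = rownames(geno$dosage)[i]),
      error = function(e) data.frame(snp_id = rownames(geno$dosage)[i],
                                     n_used = sum(!is.na(d)), beta = NA_real_,
                                     se = NA_real_, or = NA_real_,
                                     ci_low = NA_real_, ci_high = NA_real_,
                                     p_two_sided = NA_real_,
                                     p_one_sided = NA_real_,
                                     converged = FALSE,
                                     stringsAsFactors = FALSE))
    res$coded_allele <- coded
    res$flipped <- flipped
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Principal components for population-stratification adjustment
#'
#' EIGENSTRAT-style sample principal components from a genotype dosage
#' matrix: SNPs with zero variance are excluded, missing dosages are
#' mean-imputed per SNP, each SNP row is centered by twice its allele
#' frequency estimate and scaled by `sqrt(2 p (1 - p))`, and the top-k
#' right singular vectors (sample loadings) of the standardized matrix are
#' returned. Singular-vector sign is fixed so each component's
#' largest-magnitude loading is positive, making results reproducible.
#'
#' @param geno a [geno_matrix()].
#' @param k number of components (must not exceed the numerical rank).
#' @return samples x k matrix with columns `PC1..PCk`.
#' @export
compute_stratification_pcs <- function(geno, k = 2) {
  .assert(inherits(geno, "geno_matrix"), "geno must be a geno_matrix")
  .assert(k >= 1, "k must be positive")
  x <- geno$dosage
  .assert(ncol(x) >= k + 1, "need at least k + 1 samples")
  rowm <- rowMeans(x, na.rm = TRUE)
  for (i in seq_len(nrow(x))) x[i, is.na(x[i, ])] <- rowm[i]
  v <- apply(x, 1, stats::var)
  x <- x[v > 0, , drop = FALSE]
  p <- rowMeans(x) / 2
  xs <- (x - 2 * p) / sqrt(2 * p * (1 - p))
  sv <- svd(xs)
  rank <- sum(sv$d > max(dim(xs)) * .Machine$double.eps * sv$d[1])
  .assert(k <= rank, "k = %d exceeds the rank (%d) of the genotype matrix", k, rank)
  pcs <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (pcs[which.max(abs(pcs[, j])), j] < 0) pcs[, j] <- -pcs[, j]
  }
  dimnames(pcs) <- list(colnames(geno$dosage), paste0("PC", seq_len(k)))
  pcs
}

#' Conditional association test
#'
#' Tests a target SNP for association after adjusting for a conditioning
#' SNP: the conditioning SNP's dosage enters the logistic model as an
#' extra covariate and the target SNP's coefficient is reported. A target
#' signal that merely tags the conditioning SNP is absorbed by the
#' covariate and loses significance. Identical dosage columns are flagged
#' as collinear.
#'
#' @param geno a [geno_matrix()] containing both SNPs.
#' @param target_snp,conditioning_snp SNP ids.
#' @param phenotypes data.frame with `sample_id`, `status`.
#' @param covariates optional further covariates.
#' @param alternative one-sided direction for the target coefficient.
#' @return one-row data.frame as [fit_additive_logistic()], plus
#'   `collinear`.
#' @export
conditional_test <- function(geno, target_snp, conditioning_snp, phenotypes,
                             covariates = NULL, alternative = "two.sided") {
  .assert(all(c(target_snp, conditioning_snp) %in% rownames(geno$dosage)),
          "both SNPs must be present in the genotype matrix")
  tg <- geno$dosage[target_snp, ]
  cg <- geno$dosage[conditioning_snp, ]
  ok <- !is.na(tg) & !is.na(cg)
  collinear <- isTRUE(all(tg[ok] == cg[ok])) ||
    isTRUE(abs(suppressWarnings(stats::cor(tg[ok], cg[ok]))) > 1 - 1e-12)
  covs <- data.frame(cond = cg)
  if (!is.null(covariates)) covs <- cbind(covs, as.data.frame(covariates))
  status <- phenotypes$status[match(colnames(geno$dosage),
                                    phenotypes$sample_id)]
  res <- fit_additive_logistic(tg, status, covs, alternative = alternative,
                               snp_id = target_snp)
  res$collinear <- collinear
  if (collinear) res$converged <- FALSE
  res
}

#' Linkage disequilibrium between two SNPs from unphased genotypes
#'
#' Estimates two-locus haplotype frequencies by the EM algorithm (the only
#' ambiguous configuration, the double heterozygote, is split between the
#' cis and trans phases in proportion to their current likelihood), then
#' reports D' = |D| / Dmax and r^2 = D^2 / (p1 q1 p2 q2). Estimates are
#' invariant to allele relabeling at either locus.
#'
#' @param dosage1,dosage2 aligned 0/1/2/NA dosage vectors; both loci must
#'   be polymorphic among complete pairs.
#' @param tol EM convergence tolerance on haplotype frequencies.
#' @param max_iter iteration cap.
#' @return list with `d_prime`, `r_squared`, `D`, and `hap_freqs` (named
#'   `h11`, `h10`, `h01`, `h00`, where 1 denotes the counted allele).
#' @export
estimate_ld <- function(dosage1, dosage2, tol = 1e-10, max_iter = 1000) {
  .assert(length(dosage1) == length(dosage2), "dosage vectors must align")
  ok <- !is.na(dosage1) & !is.na(dosage2)
  g1 <- dosage1[ok]; g2 <- dosage2[ok]
  n <- length(g1)
  .assert(n >= 2, "need at least two complete genotype pairs")
  .assert(var(g1) > 0 && var(g2) > 0, "monomorphic locus: LD undefined")
  # 3x3 genotype counts, indices are dosage + 1
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[g1[i] + 1, g2[i] + 1] <- tab[g1[i] + 1, g2[i] + 1] + 1

  p1 <- mean(g1) / 2; p2 <- mean(g2) / 2
  h <- c(h11 = p1 * p2, h10 = p1 * (1 - p2), h01 = (1 - p1) * p2,
         h00 = (1 - p1) * (1 - p2))
  n_dh <- tab[2, 2]  # double heterozygotes: phase-ambiguous
  for (iter in seq_len(max_iter)) {
    cis <- h["h11"] * h["h00"]
    trans <- h["h10"] * h["h01"]
    f_cis <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    # expected haplotype counts; unambiguous cells contribute fixed counts
    c11 <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + n_dh * f_cis
    c10 <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1] + n_dh * (1 - f_cis)
    c01 <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3] + n_dh * (1 - f_cis)
    c00 <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1] + n_dh * f_cis
    h_new <- c(c11, c10, c01, c00) / (2 * n)
    names(h_new) <- names(h)
    if (max(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  p1 <- h[["h11"]] + h[["h10"]]
  p2 <- h[["h11"]] + h[["h01"]]
  D <- h[["h11"]] - p1 * p2
  d_max <- if (D >= 0) min(p1 * (1 - p2), (1 - p1) * p2) else
    min(p1 * p2, (1 - p1) * (1 - p2))
  d_prime <- if (d_max > 0) abs(D) / d_max else 0
  r2 <- D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
  list(d_prime = d_prime, r_squared = r2, D = D, hap_freqs = h)
}
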