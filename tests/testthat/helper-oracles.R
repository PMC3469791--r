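# Independent oracles used to validate package implementations.
# Each deliberately takes a different computational route than the package.

# Exact HWE p-value by direct enumeration of the conditional heterozygote
# distribution, with probabilities built from choose() products rather than
# the log-factorial weights the package uses.
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # P(h) proportional to choose(n, (n_a-h)/2) * choose(n-(n_a-h)/2, h) * 2^h
  # (pick hom-A subjects, then het subjects; remaining are hom-B) -- the
  # genotype-multinomial route
  w <- vapply(hets, function(h) {
    choose(n, (n_a - h) / 2) * choose(n - (n_a - h) / 2, h) * 2^h
  }, numeric(1))
  prob <- w / sum(w)
  p_obs <- prob[match(n_ab, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

# Scalar re-implementation of the category rules, written as a literal
# decision list (no vectorization, explicit branches).
categorize_oracle <- function(d_we, d_wa) {
  if (is.na(d_we) || is.na(d_wa)) return("NONE")
  one_high <- (abs(d_we) >= 0.70 && abs(d_wa) < 0.40) ||
    (abs(d_wa) >= 0.70 && abs(d_we) < 0.40)
  same <- (d_we > 0 && d_wa > 0) || (d_we < 0 && d_wa < 0)
  if (same) {
    m <- (abs(d_we) + abs(d_wa)) / 2
    if (m >= 0.70) return("HIGHEST")
    if (m >= 0.60) return("HIGH")
    if (m >= 0.40) return("MODERATE")
    if (one_high) return("HIGHEST_LOW")
    return("NONE")
  }
  if (one_high) return("HIGHEST_LOW")
  "NONE"
}

# Per-allele logistic fit by direct likelihood maximization on the
# collapsed 2 x 3 case/control-by-dosage table (Nelder-Mead on the exact
# log-likelihood, no IRLS).
logistic_oracle_beta <- function(dosage, status) {
  tab <- table(factor(status, levels = 0:1), factor(dosage, levels = 0:2))
  nll <- function(par) {
    eta <- par[1] + par[2] * (0:2)
    -sum(tab[2, ] * eta - (tab[1, ] + tab[2, ]) * log1p(exp(eta)))
  }
  stats::optim(c(0, 0), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$par[2]
}

# Two-locus haplotype frequency by exhaustive 1-D likelihood grid: with the
# allele frequencies fixed at their sample values, the genotype-table
# likelihood depends only on the coupling haplotype frequency h11, which is
# scanned on a coarse grid and refined twice.
ld_hap_oracle <- function(dosage1, dosage2) {
  ok <- !is.na(dosage1) & !is.na(dosage2)
  g1 <- dosage1[ok]; g2 <- dosage2[ok]
  n <- length(g1)
  p1 <- mean(g1) / 2; p2 <- mean(g2) / 2
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[g1[i] + 1, g2[i] + 1] <- tab[g1[i] + 1, g2[i] + 1] + 1
  loglik <- function(h11) {
    h <- c(h11, p1 - h11, p2 - h11, 1 - p1 - p2 + h11)  # h11,h10,h01,h00
    if (any(h < 0)) return(-Inf)
    # P(genotype pair) as products of haplotype probabilities
    gp <- function(i, j) {
      switch(paste(i, j),
             "0 0" = h[4]^2,          "0 1" = 2 * h[4] * h[3],
             "0 2" = h[3]^2,          "1 0" = 2 * h[4] * h[2],
             "1 1" = 2 * (h[1] * h[4] + h[2] * h[3]),
             "1 2" = 2 * h[1] * h[3], "2 0" = h[2]^2,
             "2 1" = 2 * h[1] * h[2], "2 2" = h[1]^2)
    }
    ll <- 0
    for (i in 0:2) for (j in 0:2) {
      if (tab[i + 1, j + 1] > 0) {
        p <- gp(i, j)
        if (p <= 0) return(-Inf)
        ll <- ll + tab[i + 1, j + 1] * log(p)
      }
    }
    ll
  }
  lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
  grid <- seq(lo, hi, length.out = 2001)
  best <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  step <- (hi - lo) / 2000
  for (refine in 1:3) {
    grid <- seq(max(lo, best - step), min(hi, best + step), length.out = 2001)
    best <- grid[which.max(vapply(grid, loglik, numeric(1)))]
    step <- step / 1000
  }
  c(h11 = best, h10 = p1 - best, h01 = p2 - best, h00 = 1 - p1 - p2 + best)
}

# small hand-built source-population panel used across panel/QC tests
toy_source_panel <- function() {
  snps <- data.frame(snp_id = paste0("rs", 1:4), chrom = "1",
                     pos = c(100L, 200L, 300L, 400L),
                     reference_allele = "A", other_allele = "G",
                     stringsAsFactors = FALSE)
  pops <- c("CEU", "TSI", "CHB", "JPT", "YRI", "LWK")
  ref_count <- matrix(c(30, 70, 10, 12, 50, 52,
                        20, 20, 80, 82, 30, 28,
                        50, 48, 40, 44, 60, 58,
                        10, 12, 90, 88, 70, 72),
                      nrow = 4, byrow = TRUE, dimnames = list(NULL, pops))
  n_alleles <- matrix(100, 4, 6, dimnames = list(NULL, pops))
  pop_panel(snps, ref_count / n_alleles, ref_count = ref_count,
            n_alleles = n_alleles,
            call_rate = matrix(1, 4, 6, dimnames = list(NULL, pops)),
            group_definitions = list(White = c("CEU", "TSI"),
                                     EastAsian = c("CHB", "JPT"),
                                     African = c("YRI", "LWK")))
}

# panel with explicit group-level frequencies (already pooled)
group_panel <- function(freq_white, freq_ea, freq_afr,
                        snp_id = sprintf("snp%03d", seq_along(freq_white))) {
  snps <- data.frame(snp_id = snp_id, chrom = "1",
                     pos = seq_along(freq_white) * 1000L,
                     reference_allele = "A", other_allele = "B",
                     stringsAsFactors = FALSE)
  freq <- cbind(White = freq_white, EastAsian = freq_ea, African = freq_afr)
  pop_panel(snps, freq)
}
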