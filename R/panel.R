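#' Multi-population allele-frequency panel
#'
#' Container for per-SNP, per-population reference-allele frequencies with
#' the QC metadata the selection workflow needs. All per-population values
#' are stored as SNP-by-population matrices sharing column order; any of
#' the count/QC matrices may be absent (`NULL`) when the source data do not
#' provide them (e.g., a frequency-only panel).
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `reference_allele`, `other_allele`; `snp_id` must be unique.
#' @param freq matrix of reference-allele frequencies (SNPs x populations).
#' @param ref_count,n_alleles optional allele-count matrices
#'   (`freq = ref_count / n_alleles` where counts are present).
#' @param call_rate optional per-SNP, per-population call-rate matrix.
#' @param hwe_p optional Hardy-Weinberg exact-test p-value matrix.
#' @param group_definitions optional named list mapping pooled group labels
#'   to their source population columns (e.g.,
#'   `list(White = c("CEU", "TSI"))`).
#' @return A `pop_panel` object.
#' @export
pop_panel <- function(snps, freq, ref_count = NULL, n_alleles = NULL,
                      call_rate = NULL, hwe_p = NULL,
                      group_definitions = NULL) {
  .assert(is.data.frame(snps) &&
            all(c("snp_id", "chrom", "pos", "reference_allele", "other_allele")
                %in% names(snps)),
          "snps must have snp_id, chrom, pos, reference_allele, other_allele")
  .assert(!anyDuplicated(snps$snp_id), "duplicate snp_id in panel")
  .assert(is.matrix(freq) && nrow(freq) == nrow(snps) && !is.null(colnames(freq)),
          "freq must be a SNP x population matrix with population names")
  ok <- freq[is.finite(freq)]
  .assert(all(ok >= 0 & ok <= 1), "frequencies must lie in [0, 1]")
  for (m in list(ref_count, n_alleles, call_rate, hwe_p)) {
    if (!is.null(m)) {
      .assert(identical(dim(m), dim(freq)) &&
                identical(colnames(m), colnames(freq)),
              "all panel matrices must share dimensions and population order")
    }
  }
  if (!is.null(group_definitions)) {
    .assert(is.list(group_definitions) && !is.null(names(group_definitions)),
            "group_definitions must be a named list")
    .assert(all(unlist(group_definitions) %in% colnames(freq)),
            "group_definitions reference unknown populations")
  }
  rownames(freq) <- snps$snp_id
  structure(list(snps = snps, freq = freq, ref_count = ref_count,
                 n_alleles = n_alleles, call_rate = call_rate, hwe_p = hwe_p,
                 group_definitions = group_definitions),
            class = "pop_panel")
}

#' @export
print.pop_panel <- function(x, ...) {
  cat(sprintf("pop_panel: %d SNPs x %d populations (%s)\n",
              nrow(x$snps), ncol(x$freq),
              paste(colnames(x$freq), collapse = ", ")))
  if (!is.null(x$group_definitions)) {
    cat("pooled groups:",
        paste(sprintf("%s={%s}", names(x$group_definitions),
                      vapply(x$group_definitions, paste, "", collapse = ",")),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of SNPs in a panel
#' @param panel a `pop_panel`.
#' @return integer count.
#' @export
n_snps <- function(panel) nrow(panel$snps)

#' Population (column) labels of a panel
#' @param panel a `pop_panel`.
#' @return character vector.
#' @export
panel_populations <- function(panel) colnames(panel$freq)

# genotype-matrix container --------------------------------------------------

#' Genotype dosage matrix
#'
#' SNP-by-sample matrix of allele-dosage codes 0/1/2/NA counting copies of
#' the per-SNP coded allele, plus per-sample metadata.
#'
#' @param dosage numeric matrix (SNPs x samples) with values in
#'   `{0, 1, 2, NA}`; rownames are SNP ids, colnames sample ids.
#' @param sample_info data.frame with a `sample_id` column matching the
#'   dosage columns (extra columns such as `group` are carried along).
#' @param coded_allele optional character vector naming the counted allele
#'   per SNP.
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(dosage, sample_info = NULL, coded_allele = NULL) {
  .assert(is.matrix(dosage) && !is.null(rownames(dosage)) &&
            !is.null(colnames(dosage)),
          "dosage must be a matrix with SNP rownames and sample colnames")
  vals <- dosage[!is.na(dosage)]
  .assert(all(vals %in% 0:2), "dosage values must be 0, 1, 2 or NA")
  if (is.null(sample_info)) {
    sample_info <- data.frame(sample_id = colnames(dosage))
  }
  .assert(identical(sample_info$sample_id, colnames(dosage)),
          "sample_info$sample_id must match dosage column order")
  if (!is.null(coded_allele)) {
    .assert(length(coded_allele) == nrow(dosage),
            "coded_allele must have one entry per SNP")
  }
  structure(list(dosage = dosage, sample_info = sample_info,
                 coded_allele = coded_allele),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d SNPs x %d samples, %.1f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

# loading --------------------------------------------------------------------

#' Load a population frequency panel
#'
#' Reads one of three dialects into a [pop_panel()]:
#' \describe{
#'   \item{`freq_tsv`}{header `snp_id chrom pos reference_allele
#'     other_allele` followed by `<pop>_ref_count` and `<pop>_total` column
#'     pairs; frequencies are computed as ref_count / total. Supplying
#'     `pop_sizes` (diploid sample counts) additionally yields call rates
#'     as total / (2 x size).}
#'   \item{`genotype_tsv`}{`snp_id` column then one 0/1/2/NA dosage column
#'     per sample (copies of the reference allele); `sample_populations`
#'     assigns samples to populations, over which frequencies, call rates
#'     and Hardy-Weinberg exact p-values are computed by allele counting
#'     over non-missing calls.}
#'   \item{`vcf`}{a VCF v4.x with GT genotypes, read via the vcfR package;
#'     multi-allelic sites are dropped with a warning. Frequencies refer to
#'     the REF allele.}
#' }
#'
#' @param path input file path.
#' @param dialect one of `"freq_tsv"`, `"genotype_tsv"`, `"vcf"`.
#' @param pop_sizes optional named diploid sample sizes (freq_tsv only).
#' @param sample_populations named character vector sample_id -> population
#'   (genotype dialects); unnamed samples form population `"ALL"`.
#' @param group_definitions optional pooled-group map stored on the panel.
#' @return A `pop_panel`.
#' @export
load_panel <- function(path, dialect = c("freq_tsv", "genotype_tsv", "vcf"),
                       pop_sizes = NULL, sample_populations = NULL,
                       group_definitions = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
         freq_tsv = .load_freq_tsv(path, pop_sizes, group_definitions),
         genotype_tsv = .load_genotype_tsv(path, sample_populations,
                                           group_definitions),
         vcf = .load_vcf(path, sample_populations, group_definitions))
}

.meta_cols <- c("snp_id", "chrom", "pos", "reference_allele", "other_allele")

.load_freq_tsv <- function(path, pop_sizes, group_definitions) {
  lines <- readLines(path)
  .assert(length(lines) >= 1, "empty frequency file: %s", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  .assert(identical(header[1:5], .meta_cols),
          "freq_tsv header must start with: %s", paste(.meta_cols, collapse = " "))
  popcols <- header[-(1:5)]
  refc <- grepl("_ref_count$", popcols)
  totc <- grepl("_total$", popcols)
  pops <- sub("_ref_count$", "", popcols[refc])
  .assert(length(pops) >= 1 &&
            identical(popcols, as.vector(rbind(paste0(pops, "_ref_count"),
                                               paste0(pops, "_total")))),
          "freq_tsv columns must alternate <pop>_ref_count, <pop>_total")
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  .assert(length(bad) == 0,
          "malformed line %d in %s: expected %d fields",
          if (length(bad)) bad[1] + 1L else 0L, path, length(header))
  m <- do.call(rbind, fields)
  snps <- data.frame(snp_id = m[, 1], chrom = m[, 2],
                     pos = as.integer(m[, 3]),
                     reference_allele = m[, 4], other_allele = m[, 5],
                     stringsAsFactors = FALSE)
  .assert(!anyDuplicated(snps$snp_id), "duplicate snp_id in %s", path)
  num <- matrix(as.numeric(m[, -(1:5), drop = FALSE]), nrow = nrow(m))
  ref_count <- num[, which(refc), drop = FALSE]
  n_alleles <- num[, which(totc), drop = FALSE]
  colnames(ref_count) <- colnames(n_alleles) <- pops
  freq <- ref_count / n_alleles
  freq[!is.finite(freq)] <- NA_real_
  call_rate <- NULL
  if (!is.null(pop_sizes)) {
    .assert(all(pops %in% names(pop_sizes)),
            "pop_sizes must name every population in the file")
    call_rate <- sweep(n_alleles, 2, 2 * pop_sizes[pops], `/`)
  }
  pop_panel(snps, freq, ref_count = ref_count, n_alleles = n_alleles,
            call_rate = call_rate, group_definitions = group_definitions)
}

.load_genotype_tsv <- function(path, sample_populations, group_definitions) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert(names(tab)[1] == "snp_id", "genotype_tsv must start with snp_id")
  .assert(!anyDuplicated(tab$snp_id), "duplicate snp_id in %s", path)
  dosage <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dosage) <- "numeric"
  rownames(dosage) <- tab$snp_id
  snps <- data.frame(snp_id = tab$snp_id, chrom = NA_character_,
                     pos = NA_integer_, reference_allele = "A",
                     other_allele = "B", stringsAsFactors = FALSE)
  .panel_from_dosage(dosage, snps, sample_populations, group_definitions)
}

.load_vcf <- function(path, sample_populations, group_definitions) {
  .assert(requireNamespace("vcfR", quietly = TRUE),
          "the vcfR package is required for the vcf dialect")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("dropping %d multi-allelic site(s)", sum(multi)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  # dosage of the REF allele from unphased or phased GT strings
  count_ref <- function(s) {
    ifelse(is.na(s), NA_real_,
           vapply(strsplit(s, "[/|]"), function(a) sum(a == "0"), numeric(1)))
  }
  dosage <- apply(gt, 2, count_ref)
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = nrow(gt),
                                             dimnames = dimnames(gt))
  rownames(dosage) <- fix$ID
  snps <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     reference_allele = fix$REF, other_allele = fix$ALT,
                     stringsAsFactors = FALSE)
  .assert(!anyDuplicated(snps$snp_id), "duplicate snp_id in %s", path)
  .panel_from_dosage(dosage, snps, sample_populations, group_definitions)
}

# shared path: per-population allele counting over a dosage matrix
.panel_from_dosage <- function(dosage, snps, sample_populations,
                               group_definitions) {
  samples <- colnames(dosage)
  if (is.null(sample_populations)) {
    sample_populations <- setNames(rep("ALL", length(samples)), samples)
  }
  .assert(all(samples %in% names(sample_populations)),
          "sample_populations must cover every sample column")
  pops <- unique(unname(sample_populations[samples]))
  nsnp <- nrow(dosage)
  freq <- ref_count <- n_alleles <- call_rate <- hwe_p <-
    matrix(NA_real_, nsnp, length(pops), dimnames = list(snps$snp_id, pops))
  for (p in pops) {
    cols <- samples[sample_populations[samples] == p]
    d <- dosage[, cols, drop = FALSE]
    nonmiss <- rowSums(!is.na(d))
    ref_count[, p] <- rowSums(d, na.rm = TRUE)
    n_alleles[, p] <- 2 * nonmiss
    freq[, p] <- ifelse(nonmiss > 0, ref_count[, p] / (2 * nonmiss), NA_real_)
    call_rate[, p] <- nonmiss / ncol(d)
    n2 <- rowSums(d == 2, na.rm = TRUE)  # hom reference
    n1 <- rowSums(d == 1, na.rm = TRUE)
    n0 <- rowSums(d == 0, na.rm = TRUE)
    hwe_p[, p] <- vapply(seq_len(nsnp), function(i) {
      if (nonmiss[i] == 0) return(NA_real_)
      hwe_exact_test(n2[i], n1[i], n0[i])
    }, numeric(1))
  }
  pop_panel(snps, freq, ref_count = ref_count, n_alleles = n_alleles,
            call_rate = call_rate, hwe_p = hwe_p,
            group_definitions = group_definitions)
}

# pooling --------------------------------------------------------------------

#' Pool source populations into analysis groups
#'
#' Collapses source-population columns into pooled groups (e.g.,
#' CEU + TSI -> Whites) by allele-count weighting: the pooled frequency is
#' the summed reference-allele count divided by the summed total allele
#' count, and the pooled call rate is total observed alleles over total
#' attempted alleles. A SNP missing data in any source population of a
#' group gets a missing pooled value for that group.
#'
#' @param panel a `pop_panel` whose columns are source populations.
#' @param group_definitions named list group -> source populations;
#'   defaults to the panel's stored `group_definitions`.
#' @return A `pop_panel` whose columns are the pooled groups. Per-source
#'   Hardy-Weinberg p-values do not pool and are dropped; run
#'   [apply_panel_qc()] on the source-level panel first.
#' @export
pool_groups <- function(panel, group_definitions = panel$group_definitions) {
  .assert(inherits(panel, "pop_panel"), "panel must be a pop_panel")
  .assert(!is.null(group_definitions), "group_definitions required")
  .assert(all(unlist(group_definitions) %in% panel_populations(panel)),
          "group_definitions reference unknown populations")
  .assert(!is.null(panel$ref_count) && !is.null(panel$n_alleles),
          "count-weighted pooling requires allele counts on the panel")
  groups <- names(group_definitions)
  nsnp <- n_snps(panel)
  dimn <- list(panel$snps$snp_id, groups)
  freq <- ref_count <- n_alleles <- matrix(NA_real_, nsnp, length(groups),
                                           dimnames = dimn)
  call_rate <- if (is.null(panel$call_rate)) NULL else
    matrix(NA_real_, nsnp, length(groups), dimnames = dimn)
  for (g in groups) {
    src <- group_definitions[[g]]
    rc <- panel$ref_count[, src, drop = FALSE]
    na <- panel$n_alleles[, src, drop = FALSE]
    any_missing <- rowSums(is.na(rc) | is.na(na)) > 0
    ref_count[, g] <- ifelse(any_missing, NA_real_, rowSums(rc))
    n_alleles[, g] <- ifelse(any_missing, NA_real_, rowSums(na))
    freq[, g] <- ref_count[, g] / n_alleles[, g]
    if (!is.null(call_rate)) {
      cr <- panel$call_rate[, src, drop = FALSE]
      attempted <- na / cr  # observed alleles / call rate = attempted alleles
      call_rate[, g] <- rowSums(na) / rowSums(attempted)
    }
  }
  freq[!is.finite(freq)] <- NA_real_
  pop_panel(panel$snps, freq, ref_count = ref_count, n_alleles = n_alleles,
            call_rate = call_rate)
}

# writers --------------------------------------------------------------------

#' Write a panel in the freq_tsv dialect
#' @param panel a `pop_panel` carrying allele counts.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_freq_tsv <- function(panel, path) {
  .assert(!is.null(panel$ref_count) && !is.null(panel$n_alleles),
          "freq_tsv requires allele counts")
  pops <- panel_populations(panel)
  out <- panel$snps[, .meta_cols]
  for (p in pops) {
    out[[paste0(p, "_ref_count")]] <- panel$ref_count[, p]
    out[[paste0(p, "_total")]] <- panel$n_alleles[, p]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as TSV (rows = SNPs, columns = samples)
#' @param geno a `geno_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(geno, path) {
  out <- data.frame(snp_id = rownames(geno$dosage),
                    geno$dosage, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phenotype table as TSV
#' @param phenotypes data.frame with `sample_id`, `status`, covariates.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_tsv <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a minimal GT-only VCF for a genotype matrix
#'
#' Emits an uncompressed VCF v4.2 with unphased GT genotypes, where dosage
#' counts copies of the REF allele (2 -> 0/0, 1 -> 0/1, 0 -> 1/1,
#' NA -> ./.).
#'
#' @param geno a `geno_matrix`.
#' @param snps data.frame with `snp_id`, `chrom`, `pos`,
#'   `reference_allele`, `other_allele` covering the matrix rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, snps, path) {
  .assert(all(rownames(geno$dosage) %in% snps$snp_id),
          "snps must cover every genotype row")
  snps <- snps[match(rownames(geno$dosage), snps$snp_id), ]
  gt <- matrix("./.", nrow(geno$dosage), ncol(geno$dosage))
  gt[which(geno$dosage == 2)] <- "0/0"
  gt[which(geno$dosage == 1)] <- "0/1"
  gt[which(geno$dosage == 0)] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(geno$dosage)),
                    collapse = "\t"))
  chrom <- ifelse(is.na(snps$chrom), "1", snps$chrom)
  pos <- ifelse(is.na(snps$pos), seq_len(nrow(snps)) * 1000L, snps$pos)
  body <- paste(chrom, pos, snps$snp_id, snps$reference_allele,
                snps$other_allele, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
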