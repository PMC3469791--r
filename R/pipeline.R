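#' Gene regions for the follow-up expansion
#'
#' Builds a validated gene-region table (1-based inclusive coordinates)
#' either from a data.frame or from a BED file. BED input (0-based,
#' half-open) is read via the rtracklayer package, which performs the
#' coordinate conversion to 1-based inclusive intervals.
#'
#' @param x data.frame with columns `gene_label`, `chrom`, `start`, `end`
#'   (1-based inclusive), or a path to a BED file whose name column holds
#'   the gene labels.
#' @return data.frame of class `gene_regions`.
#' @export
gene_regions <- function(x) {
  if (is.character(x) && length(x) == 1) {
    .assert(requireNamespace("rtracklayer", quietly = TRUE),
            "the rtracklayer package is required to read BED files")
    gr <- as.data.frame(rtracklayer::import(x, format = "BED"))
    x <- data.frame(gene_label = gr$name,
                    chrom = as.character(gr$seqnames),
                    start = gr$start, end = gr$end,
                    stringsAsFactors = FALSE)
  }
  .assert(is.data.frame(x) &&
            all(c("gene_label", "chrom", "start", "end") %in% names(x)),
          "gene regions need gene_label, chrom, start, end")
  .assert(all(x$start <= x$end), "region start must not exceed end")
  class(x) <- c("gene_regions", "data.frame")
  x
}

#' Expand sub-threshold hits to all SNPs in their gene regions
#'
#' For every gene whose (flank-extended) interval contains at least one
#' hit SNP, returns all panel SNPs lying within `[start - flank,
#' end + flank]` on the same chromosome - including SNPs that failed the
#' allele-frequency-difference criteria, which is the point of the
#' follow-up stage. Hit SNPs falling in no annotated gene are skipped
#' with a warning.
#'
#' @param hits character vector of hit SNP ids.
#' @param regions a [gene_regions()] table.
#' @param panel a `pop_panel` providing SNP positions.
#' @param flank bases added on each side of the gene body (default 5000).
#' @return named list gene_label -> character vector of SNP ids.
#' @export
expand_gene_regions <- function(hits, regions, panel, flank = 5000) {
  .assert(inherits(regions, "gene_regions"), "regions must be gene_regions")
  .assert(flank >= 0, "flank must be non-negative")
  snps <- panel$snps
  lo <- regions$start - flank
  hi <- regions$end + flank
  in_region <- function(snp_row, r) {
    !is.na(snp_row$pos) && snp_row$chrom == regions$chrom[r] &&
      snp_row$pos >= lo[r] && snp_row$pos <= hi[r]
  }
  hit_rows <- match(hits, snps$snp_id)
  .assert(!anyNA(hit_rows), "hit SNPs missing from the panel")
  covered <- logical(nrow(regions))
  for (h in hit_rows) {
    found <- FALSE
    for (r in seq_len(nrow(regions))) {
      if (in_region(snps[h, ], r)) { covered[r] <- TRUE; found <- TRUE }
    }
    if (!found) {
      warning(sprintf("hit SNP %s lies in no annotated gene; skipped",
                      snps$snp_id[h]))
    }
  }
  out <- list()
  for (r in which(covered)) {
    sel <- !is.na(snps$pos) & snps$chrom == regions$chrom[r] &
      snps$pos >= lo[r] & snps$pos <= hi[r]
    out[[regions$gene_label[r]]] <- snps$snp_id[sel]
  }
  out
}

#' Direction-consistency filter over follow-up genes
#'
#' Retains a gene only if none of its follow-up SNPs contradicts the
#' study's directional hypothesis: the allele enriched in the comparison
#' (East Asian / African) groups should be protective. A contradiction is
#' a follow-up SNP that is significant two-sided at `p_cut` and whose
#' comparison-enriched allele is estimated risk-increasing. Genes with no
#' significant follow-up SNPs pass through unchanged.
#'
#' The comparison-enrichment of each SNP's coded allele is derived from
#' its difference profile: with profiles expressed for the reference
#' allele, the coded allele's mean (White minus comparison) difference is
#' `(d_we + d_wa) / 2`, negated when the coded allele is the other allele.
#'
#' @param gene_snps named list gene -> SNP ids (from
#'   [expand_gene_regions()]).
#' @param assoc association results covering those SNPs (needs `snp_id`,
#'   `beta`, `p_two_sided`, `flipped`).
#' @param profiles difference profiles for the reference allele (needs
#'   `snp_id`, `d_we`, `d_wa`).
#' @param p_cut significance bound for calling a contradiction
#'   (default 0.01).
#' @return character vector of retained gene labels.
#' @export
direction_consistency_filter <- function(gene_snps, assoc, profiles,
                                         p_cut = 0.01) {
  .assert(p_cut > 0 && p_cut < 1, "p_cut must be in (0, 1)")
  retained <- character(0)
  for (g in names(gene_snps)) {
    ids <- gene_snps[[g]]
    rows <- assoc[assoc$snp_id %in% ids & !is.na(assoc$beta), , drop = FALSE]
    prof <- profiles[match(rows$snp_id, profiles$snp_id), , drop = FALSE]
    # signed White-minus-comparison enrichment of each row's coded allele
    d_ref <- (prof$d_we + prof$d_wa) / 2
    d_coded <- ifelse(rows$flipped %||% FALSE, -d_ref, d_ref)
    # hypothesis: comparison-enriched coded allele (d_coded < 0) protective
    # (beta < 0); White-enriched coded allele risk-increasing (beta > 0)
    contradiction <- !is.na(rows$p_two_sided) & rows$p_two_sided < p_cut &
      !is.na(d_coded) & d_coded != 0 & (sign(rows$beta) != sign(d_coded))
    if (!any(contradiction)) retained <- c(retained, g)
  }
  retained
}

#' Pipeline configuration
#'
#' Bundles inputs and tuning parameters for [run_discovery_pipeline()].
#' Inputs may be in-memory objects or file paths (paths are loaded with
#' the corresponding reader).
#'
#' @param panel a `pop_panel` (source or pooled) or path to a freq_tsv.
#' @param genotypes a `geno_matrix` or path to a genotype TSV.
#' @param phenotypes a data.frame or path to a phenotype TSV.
#' @param regions optional [gene_regions()] table or BED path.
#' @param group_definitions optional pooling map for the panel.
#' @param groups role map passed to [difference_profiles()].
#' @param study_alpha study-wide significance level (default 0.05).
#' @param discovery_p_cut gene-follow-up hit threshold (default 0.01).
#' @param replication_alpha nominal replication level (default 0.05),
#'   carried into the exported rows.
#' @param k_pcs number of stratification PCs (0 disables adjustment).
#' @param flank gene flank in bases (default 5000).
#' @param callrate_min,hwe_alpha panel QC settings.
#' @param seed integer seed controlling any stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(panel, genotypes, phenotypes, regions = NULL,
                            group_definitions = NULL,
                            groups = c(white = "White",
                                       east_asian = "EastAsian",
                                       african = "African"),
                            study_alpha = 0.05, discovery_p_cut = 0.01,
                            replication_alpha = 0.05, k_pcs = 2,
                            flank = 5000, callrate_min = 0.95,
                            hwe_alpha = 1e-7, seed = 1L) {
  .assert(discovery_p_cut > 0 && discovery_p_cut < 1,
          "discovery_p_cut must be in (0, 1)")
  .assert(study_alpha > 0 && study_alpha < 1, "study_alpha must be in (0, 1)")
  structure(list(panel = panel, genotypes = genotypes,
                 phenotypes = phenotypes, regions = regions,
                 group_definitions = group_definitions, groups = groups,
                 study_alpha = study_alpha,
                 discovery_p_cut = discovery_p_cut,
                 replication_alpha = replication_alpha,
                 k_pcs = k_pcs, flank = flank,
                 callrate_min = callrate_min, hwe_alpha = hwe_alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the discovery workflow end to end
#'
#' Executes the full discovery sequence: panel QC, candidate selection by
#' allele-frequency-difference category, category-allocated Bonferroni
#' thresholds, one-sided additive logistic association with
#' principal-component adjustment, comparison of each candidate's
#' one-sided p against its category threshold, optional gene-region
#' follow-up with the direction-consistency filter, and a
#' replication-format export of retained SNPs. Every stage is a pure
#' function of the inputs and the seed.
#'
#' Each candidate's one-sided direction encodes the primary hypothesis:
#' the allele enriched in the comparison (East Asian / African) groups is
#' protective. The per-SNP provenance column records whether a reported
#' SNP entered by category selection or by gene-region expansion.
#'
#' @param config a [pipeline_config()].
#' @return list with `qc_report`, `profiles`, `candidates`, `thresholds`,
#'   `pcs`, `assoc` (candidate associations with `significant` flag),
#'   `top_hit`, `followup` (gene lists, follow-up associations, retained
#'   genes) and `replication_export`.
#' @export
run_discovery_pipeline <- function(config) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  set.seed(config$seed)

  panel <- config$panel
  if (is.character(panel)) panel <- load_panel(panel, "freq_tsv")
  geno <- config$genotypes
  if (is.character(geno)) geno <- load_panel_genotypes(geno)
  phen <- config$phenotypes
  if (is.character(phen)) phen <- read.delim(phen, stringsAsFactors = FALSE)

  # stage 1: panel QC (availability -> call rate -> HWE), then pooling
  qc <- apply_panel_qc(panel, callrate_min = config$callrate_min,
                       hwe_alpha = config$hwe_alpha,
                       group_definitions = config$group_definitions)
  pooled <- if (is.null(config$group_definitions)) qc$panel else
    pool_groups(qc$panel, config$group_definitions)

  # stage 2: difference profiles, candidate categories, thresholds
  profiles <- difference_profiles(pooled, config$groups)
  candidates <- profiles[profiles$category != "NONE", , drop = FALSE]
  counts <- table(factor(candidates$category,
                         levels = setdiff(.categories, "NONE")))
  thresholds <- category_thresholds(setNames(as.integer(counts), names(counts)),
                                    config$study_alpha)

  # stage 3: stratification PCs and one-sided association on candidates
  pcs <- if (config$k_pcs > 0) compute_stratification_pcs(geno, config$k_pcs)
         else NULL
  cand_ids <- intersect(candidates$snp_id, rownames(geno$dosage))
  cand_geno <- geno_matrix(geno$dosage[cand_ids, , drop = FALSE],
                           sample_info = geno$sample_info,
                           coded_allele = geno$coded_allele[
                             match(cand_ids, rownames(geno$dosage))])
  # hypothesized direction for the stored (reference-allele) coding:
  # White-enriched reference allele => risk-increasing => "greater";
  # comparison-enriched => protective => "less"
  prof_idx <- match(cand_ids, profiles$snp_id)
  d_ref <- (profiles$d_we[prof_idx] + profiles$d_wa[prof_idx]) / 2
  alt <- ifelse(d_ref > 0, "greater", "less")
  assoc <- association_scan(cand_geno, phen, covariates = pcs,
                            code = "minor", alternative = alt)
  assoc$category <- candidates$category[match(assoc$snp_id, candidates$snp_id)]
  thr_map <- setNames(thresholds$table$threshold, thresholds$table$category)
  assoc$threshold <- unname(thr_map[assoc$category])
  assoc$significant <- !is.na(assoc$p_one_sided) &
    assoc$p_one_sided < assoc$threshold
  assoc$provenance <- "category_selection"
  top_hit <- if (nrow(assoc) > 0 && any(!is.na(assoc$p_one_sided)))
    assoc[which.min(assoc$p_one_sided), , drop = FALSE] else NULL

  # stage 4: gene-region follow-up and direction-consistency exclusion
  followup <- NULL
  replication_export <- NULL
  if (!is.null(config$regions)) {
    regions <- gene_regions(config$regions)
    hit_ids <- assoc$snp_id[!is.na(assoc$p_one_sided) &
                              assoc$p_one_sided < config$discovery_p_cut]
    gene_snps <- expand_gene_regions(hit_ids, regions, pooled,
                                     flank = config$flank)
    extra_ids <- setdiff(intersect(unlist(gene_snps), rownames(geno$dosage)),
                         assoc$snp_id)
    fu_assoc <- assoc
    if (length(extra_ids) > 0) {
      extra_geno <- geno_matrix(geno$dosage[extra_ids, , drop = FALSE],
                                sample_info = geno$sample_info,
                                coded_allele = geno$coded_allele[
                                  match(extra_ids, rownames(geno$dosage))])
      prof_idx2 <- match(extra_ids, profiles$snp_id)
      d_ref2 <- (profiles$d_we[prof_idx2] + profiles$d_wa[prof_idx2]) / 2
      alt2 <- ifelse(!is.na(d_ref2) & d_ref2 > 0, "greater", "less")
      extra <- association_scan(extra_geno, phen, covariates = pcs,
                                code = "minor", alternative = alt2)
      extra$category <- "NONE"
      extra$threshold <- NA_real_
      extra$significant <- NA
      extra$provenance <- "gene_expansion"
      fu_assoc <- rbind(assoc, extra)
    }
    retained <- direction_consistency_filter(gene_snps, fu_assoc, profiles,
                                             p_cut = config$discovery_p_cut)
    followup <- list(gene_snps = gene_snps, assoc = fu_assoc,
                     retained_genes = retained)
    # replication export: every SNP with p < cut in a retained gene
    rep_ids <- unique(unlist(gene_snps[retained]))
    rep_rows <- fu_assoc[fu_assoc$snp_id %in% rep_ids &
                           !is.na(fu_assoc$p_two_sided) &
                           (pmin(fu_assoc$p_one_sided, fu_assoc$p_two_sided,
                                 na.rm = TRUE) < config$discovery_p_cut), ,
                         drop = FALSE]
    if (nrow(rep_rows) > 0) {
      replication_export <- data.frame(
        study = "discovery", snp_id = rep_rows$snp_id,
        coded_allele = rep_rows$coded_allele,
        beta = rep_rows$beta, se = rep_rows$se, or = rep_rows$or,
        ci_low = rep_rows$ci_low, ci_high = rep_rows$ci_high,
        p_one_sided = rep_rows$p_one_sided,
        provenance = rep_rows$provenance,
        replication_alpha = config$replication_alpha,
        stringsAsFactors = FALSE)
    }
  }

  list(qc_report = qc$report, profiles = profiles, candidates = candidates,
       thresholds = thresholds, pcs = pcs, assoc = assoc, top_hit = top_hit,
       followup = followup, replication_export = replication_export)
}

#' Read a genotype TSV into a geno_matrix
#'
#' Companion reader for the genotype dialect written by
#' [write_genotype_tsv()] (`snp_id` column, then one 0/1/2/NA column per
#' sample).
#'
#' @param path input file.
#' @return a [geno_matrix()].
#' @export
load_panel_genotypes <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert(names(tab)[1] == "snp_id", "genotype TSV must start with snp_id")
  dosage <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dosage) <- "numeric"
  rownames(dosage) <- tab$snp_id
  geno_matrix(dosage)
}

#' Write the pipeline report bundle as TSV tables
#'
#' Emits deterministic, byte-stable TSV tables (fixed column order,
#' full-precision numbers via `format(..., digits = 15)`) for the main
#' stages of a pipeline run.
#'
#' @param bundle result of [run_discovery_pipeline()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_pipeline_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stable <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stable(bundle$profiles, file.path(dir, "difference_profiles.tsv"))
  stable(bundle$thresholds$table, file.path(dir, "category_thresholds.tsv"))
  stable(bundle$assoc, file.path(dir, "candidate_associations.tsv"))
  if (!is.null(bundle$followup)) {
    stable(bundle$followup$assoc, file.path(dir, "followup_associations.tsv"))
    writeLines(bundle$followup$retained_genes,
               file.path(dir, "retained_genes.txt"))
  }
  if (!is.null(bundle$replication_export)) {
    stable(bundle$replication_export, file.path(dir, "replication_export.tsv"))
  }
  invisible(dir)
}
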