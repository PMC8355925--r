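#' Run the full analysis pipeline on a synthetic study
#'
#' End-to-end orchestration of every stage on generated inputs:
#' consensus peaks from per-sample H3K27ac and H3K4me1 calls, dual-mark
#' enhancer identification, paired differential H3K27ac and gene
#' expression, regulated/non-regulated set selection, enhancer-gene
#' link integration (promoter groups, ECDF shifts, concordance), and
#' the GWAS enrichment: catalog filtering, LD clumping, 1:2 matched
#' controls, per-category de-duplication, tag expansion with
#' block-collapsed overlap, and logistic-regression odds ratios against
#' both the regulated and the non-regulated enhancer sets.
#'
#' Deterministic for a fixed `config$seed`: rerunning yields
#' byte-identical outputs.
#'
#' @param config a [simulation_config()]
#' @param fdr FDR cutoff for regulated calls (default 0.1)
#' @param outdir optional directory; when given, result tables are
#'   written as TSV/BED
#' @return list with the study, per-stage tables, and the enrichment
#'   results
#' @export
run_pipeline <- function(config = simulation_config(), fdr = 0.1,
                         outdir = NULL) {
  study <- simulate_study(config)

  # --- enhancer identification from per-sample peak calls
  k27_cons <- consensus_peaks(study$k27_peaks)
  k4_cons <- consensus_peaks(study$k4_peaks)
  enhancers <- identify_enhancers(k27_cons, k4_cons)
  # consensus intervals inherit the generator's region ids by overlap
  hits <- overlap_pairs(enhancers, study$regions)
  enhancers$name <- NA_character_
  enhancers$name[hits$query] <- study$regions$name[hits$subject]
  enhancers <- enhancers[!is.na(enhancers$name) &
                           !duplicated(enhancers$name), , drop = FALSE]

  # --- paired differential H3K27ac on dual-mark regions
  chip_cm <- study$chip_counts
  keep <- rownames(chip_cm$counts) %in% enhancers$name
  chip_sub <- count_matrix(chip_cm$counts[keep, , drop = FALSE],
                           chip_cm$design$participant,
                           chip_cm$design$training,
                           chip_cm$design$library_size)
  enh_res <- differential_activity(chip_sub)
  reg <- classify_regulated(enh_res, fdr = fdr)
  n_reg <- length(reg$up) + length(reg$down)
  nonreg_ids <- if (n_reg > 0 && n_reg <= nrow(enh_res))
    select_nonregulated(enh_res, n_reg) else character(0)
  reg_enh <- enhancers[enhancers$name %in% c(reg$up, reg$down), ,
                       drop = FALSE]
  nonreg_enh <- enhancers[enhancers$name %in% nonreg_ids, , drop = FALSE]

  # --- paired differential expression
  gene_res <- differential_expression(study$rna_counts)
  gene_reg <- classify_regulated(gene_res, fdr = fdr)

  # --- enhancer-gene links
  attached <- attach_links(enhancers, study$links)
  groups <- promoter_groups(attached, reg$up, reg$down)
  conc <- activity_expression_concordance(enh_res, gene_res, attached,
                                          fdr = fdr)
  ecdf_tests <- list()
  none_fc <- gene_res$logFC[match(groups$gene_id[groups$group == "None"],
                                  gene_res$feature_id)]
  for (g in c("Up", "Down", "Both")) {
    gv <- gene_res$logFC[match(groups$gene_id[groups$group == g],
                               gene_res$feature_id)]
    gv <- gv[!is.na(gv)]
    if (length(gv) > 0 && length(none_fc) > 0)
      ecdf_tests[[g]] <- ecdf_shift(gv, none_fc[!is.na(none_fc)])
  }

  # --- GWAS enrichment
  catalog <- filter_catalog(study$snp_table)
  clumped <- ld_clump(catalog, study$ld)
  pool <- study$snp_table[study$snp_table$trait == "control", ,
                          drop = FALSE]
  controls <- match_controls_all(clumped, pool,
                                 k = config$control_ratio,
                                 rng_seed = derive_seed(config$seed, 71L))
  controls <- dedup_controls(controls)
  enrichment <- run_enrichment(
    clumped, controls, reg_enh, study$ld, study$snp_table,
    nonregulated = if (nrow(nonreg_enh) > 0) nonreg_enh else NULL,
    min_category_n = 0)

  res <- list(study = study, k27_consensus = k27_cons,
              k4_consensus = k4_cons, enhancers = enhancers,
              enhancer_results = enh_res, regulated = reg,
              nonregulated_ids = nonreg_ids, gene_results = gene_res,
              gene_regulated = gene_reg, attached = attached,
              promoter_groups = groups, ecdf_tests = ecdf_tests,
              concordance = conc, clumped = clumped,
              controls = controls, enrichment = enrichment)
  if (!is.null(outdir)) write_pipeline(res, outdir)
  res
}

# Write the user-facing pipeline tables.
write_pipeline <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f)
    utils::write.table(x, file.path(outdir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_bed(res$enhancers, file.path(outdir, "enhancers.bed"))
  tsv(res$enhancer_results, "enhancer_differential.tsv")
  up_bed <- res$enhancers[res$enhancers$name %in% res$regulated$up, ]
  down_bed <- res$enhancers[res$enhancers$name %in% res$regulated$down, ]
  nr_bed <- res$enhancers[res$enhancers$name %in% res$nonregulated_ids, ]
  write_bed(up_bed, file.path(outdir, "enhancers_up.bed"))
  write_bed(down_bed, file.path(outdir, "enhancers_down.bed"))
  write_bed(nr_bed, file.path(outdir, "enhancers_nonregulated.bed"))
  tsv(res$gene_results, "gene_differential.tsv")
  tsv(res$promoter_groups, "promoter_groups.tsv")
  tsv(res$concordance$pairs, "concordance_pairs.tsv")
  tsv(res$concordance$concordant_significant, "concordant_significant.tsv")
  tsv(data.frame(r = res$concordance$r,
                 n_pairs = res$concordance$n_pairs),
      "concordance_summary.tsv")
  tsv(res$enrichment, "enrichment.tsv")
  invisible(outdir)
}
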