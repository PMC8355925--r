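#' Read a scored enhancer-gene link table
#'
#' TSV with header columns `chrom`, `start`, `end`, `gene_id`, `score`
#' and optionally `distance` (bp between enhancer midpoint and TSS).
#' Coordinates are BED 0-based half-open.
#'
#' @param path path to link TSV
#' @return link data.frame
#' @export
read_links <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "gene_id", "score")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("link table lacks column(s): ", paste(missing_cols, collapse = ", "))
  validate_intervals(df)
  df
}

#' Attach scored links to enhancers by single-nucleotide overlap
#'
#' An enhancer is connected to a gene whenever its interval overlaps the
#' link-side geometry by at least one base. All overlapping links are
#' retained, including multiple links to the same gene (deduplication is
#' a downstream concern). Enhancers without any overlapping link carry no
#' rows in the result.
#'
#' @param enhancers interval data.frame; a `name` column is used as the
#'   enhancer id (default `chrom:start-end`)
#' @param links link data.frame (`chrom`, `start`, `end`, `gene_id`,
#'   `score`, optional `distance`)
#' @return data.frame with one row per attached (enhancer, link) pair:
#'   `enhancer_id`, `gene_id`, `score`, `distance`, link geometry; the
#'   full enhancer id set is kept in attribute `"enhancer_ids"`
#' @export
attach_links <- function(enhancers, links) {
  validate_intervals(enhancers)
  ids <- enhancer_ids(enhancers)
  hits <- overlap_pairs(enhancers, links)
  out <- data.frame(
    enhancer_id = ids[hits$query],
    gene_id = links$gene_id[hits$subject],
    score = links$score[hits$subject],
    distance = if (!is.null(links$distance)) links$distance[hits$subject]
               else link_midpoint_distance(enhancers[hits$query, , drop = FALSE],
                                           links[hits$subject, , drop = FALSE]),
    chrom = links$chrom[hits$subject],
    start = links$start[hits$subject],
    end = links$end[hits$subject],
    stringsAsFactors = FALSE)
  attr(out, "enhancer_ids") <- ids
  out
}

enhancer_ids <- function(enhancers) {
  if (!is.null(enhancers$name)) as.character(enhancers$name)
  else sprintf("%s:%d-%d", enhancers$chrom, enhancers$start, enhancers$end)
}

link_midpoint_distance <- function(enh, links) {
  if (nrow(enh) == 0) return(integer(0))
  abs(floor((enh$start + enh$end) / 2) - floor((links$start + links$end) / 2))
}

#' Summary statistics of an attached link map
#'
#' Duplicate (enhancer, gene) pairs are collapsed before counting.
#' Returns the mean number of enhancers per linked gene, mean genes per
#' linked enhancer, and mean link distance in bp over all attached links.
#'
#' @param attached output of [attach_links()]
#' @return list `mean_enhancers_per_gene`, `mean_genes_per_enhancer`,
#'   `mean_distance_bp`
#' @export
link_statistics <- function(attached) {
  if (nrow(attached) == 0) stop("no attached links")
  pairs <- unique(attached[, c("enhancer_id", "gene_id")])
  list(mean_enhancers_per_gene = mean(table(pairs$gene_id)),
       mean_genes_per_enhancer = mean(table(pairs$enhancer_id)),
       mean_distance_bp = mean(attached$distance))
}

#' Strongest-scoring linked gene per enhancer
#'
#' For each enhancer with at least one link, the gene of its
#' maximum-interaction-score link; score ties break to the
#' lexicographically smallest gene id.
#'
#' @param attached output of [attach_links()]
#' @return data.frame `enhancer_id`, `gene_id`, `score`
#' @export
strongest_gene <- function(attached) {
  if (nrow(attached) == 0)
    return(data.frame(enhancer_id = character(), gene_id = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  ord <- order(attached$enhancer_id, -attached$score, attached$gene_id)
  srt <- attached[ord, , drop = FALSE]
  keep <- !duplicated(srt$enhancer_id)
  out <- srt[keep, c("enhancer_id", "gene_id", "score"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Promoter groups from linked-enhancer regulation
#'
#' Classifies each linked gene by the regulation of its connected
#' enhancers: `Both` if linked to at least one up- and one down-regulated
#' enhancer; `Up` / `Down` if linked to at least one regulated enhancer
#' of only that sign (regulated links dominate unregulated ones); `None`
#' if linked only to unregulated enhancers. Genes without links are
#' excluded.
#'
#' @param attached output of [attach_links()]
#' @param up,down disjoint character vectors of regulated enhancer ids
#' @return data.frame `gene_id`, `group` (factor None/Up/Down/Both)
#' @export
promoter_groups <- function(attached, up, down) {
  if (length(intersect(up, down)) > 0)
    stop("up and down enhancer sets must be disjoint")
  if (nrow(attached) == 0)
    return(data.frame(gene_id = character(),
                      group = factor(character(),
                                     levels = c("None", "Up", "Down", "Both"))))
  pairs <- unique(attached[, c("enhancer_id", "gene_id")])
  pairs$is_up <- pairs$enhancer_id %in% up
  pairs$is_down <- pairs$enhancer_id %in% down
  agg <- stats::aggregate(cbind(is_up, is_down) ~ gene_id, data = pairs, FUN = any)
  grp <- ifelse(agg$is_up & agg$is_down, "Both",
         ifelse(agg$is_up, "Up",
         ifelse(agg$is_down, "Down", "None")))
  data.frame(gene_id = agg$gene_id,
             group = factor(grp, levels = c("None", "Up", "Down", "Both")),
             stringsAsFactors = FALSE)
}

#' ECDF shift between two groups of fold changes
#'
#' Two-sample Kolmogorov-Smirnov comparison of lnFC distributions with
#' asymptotic p-value, plus the direction of the shift (sign of the
#' difference in medians).
#'
#' @param group_values,reference_values nonempty numeric vectors
#' @return list `ks_D`, `p`, `direction` (-1, 0, +1)
#' @export
ecdf_shift <- function(group_values, reference_values) {
  if (length(group_values) == 0 || length(reference_values) == 0)
    stop("both vectors must be nonempty")
  kt <- suppressWarnings(stats::ks.test(group_values, reference_values,
                                        exact = FALSE))
  list(ks_D = unname(kt$statistic), p = kt$p.value,
       direction = sign(stats::median(group_values) -
                        stats::median(reference_values)))
}

#' Enhancer-activity / gene-expression concordance
#'
#' Correlates per-enhancer H3K27ac log fold change with the log fold
#' change of the linked gene, and lists concordant significant pairs:
#' both members at q < `fdr` with the same fold-change sign. By default
#' each enhancer is reduced to its strongest-scoring gene; `mode =
#' "all"` keeps every attached (enhancer, gene) pair.
#'
#' @param enh_results,gene_results differential result data.frames
#' @param attached output of [attach_links()]
#' @param mode `"strongest"` (default) or `"all"`
#' @param method correlation coefficient (`"pearson"` default)
#' @param fdr significance cutoff for the concordant-pair list
#' @return list `r`, `n_pairs`, `pairs` (the correlated table), and
#'   `concordant_significant` data.frame
#' @export
activity_expression_concordance <- function(enh_results, gene_results,
                                            attached,
                                            mode = c("strongest", "all"),
                                            method = c("pearson", "spearman"),
                                            fdr = 0.1) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  pair_tab <- if (mode == "strongest") strongest_gene(attached)
              else unique(attached[, c("enhancer_id", "gene_id")])
  ei <- match(pair_tab$enhancer_id, enh_results$feature_id)
  gi <- match(pair_tab$gene_id, gene_results$feature_id)
  keep <- !is.na(ei) & !is.na(gi)
  pairs <- data.frame(
    enhancer_id = pair_tab$enhancer_id[keep],
    gene_id = pair_tab$gene_id[keep],
    enh_logFC = enh_results$logFC[ei[keep]],
    gene_logFC = gene_results$logFC[gi[keep]],
    enh_q = enh_results$q[ei[keep]],
    gene_q = gene_results$q[gi[keep]],
    stringsAsFactors = FALSE)
  ok <- stats::complete.cases(pairs[, c("enh_logFC", "gene_logFC")])
  pairs <- pairs[ok, , drop = FALSE]
  r <- if (nrow(pairs) < 3) NA_real_
       else stats::cor(pairs$enh_logFC, pairs$gene_logFC, method = method)
  conc <- pairs[!is.na(pairs$enh_q) & !is.na(pairs$gene_q) &
                pairs$enh_q < fdr & pairs$gene_q < fdr &
                sign(pairs$enh_logFC) == sign(pairs$gene_logFC) &
                pairs$enh_logFC != 0, , drop = FALSE]
  rownames(conc) <- NULL
  list(r = r, n_pairs = nrow(pairs), pairs = pairs,
       concordant_significant = conc)
}
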