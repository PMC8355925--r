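#' Paired differential gene expression
#'
#' Per-gene NB likelihood-ratio test comparing `~ participant` against
#' `~ participant + training` on paired pre/post counts, with the fitted
#' training coefficient as the natural-log fold change. Adjustment is BH
#' by default; Bonferroni is available because family-wise corrected
#' q-values are sometimes preferred for gene-level reporting. Outlier
#' samples are expected to be excluded by the caller before testing.
#'
#' @inheritParams nb_paired_test
#' @return differential result data.frame
#' @export
differential_expression <- function(cm, adjust_method = c("BH", "bonferroni"),
                                    dispersion_floor = 1e-4, log2_fc = FALSE) {
  nb_paired_test(cm, adjust_method = adjust_method,
                 dispersion_floor = dispersion_floor, log2_fc = log2_fc)
}

#' Secreted-factor enrichment (Pearson chi-square)
#'
#' Tests whether an annotation set (e.g. genes encoding secreted
#' proteins) is over-represented among regulated genes, against the full
#' expressed-gene universe. The 2x2 table is
#' \{regulated, universe \\ regulated\} x \{annotated, not annotated\},
#' tested by the Pearson chi-square without continuity correction, 1 df.
#'
#' @param regulated character vector of regulated gene ids (subset of
#'   `universe`)
#' @param universe character vector of all tested gene ids
#' @param annotation character vector of annotated gene ids
#' @return list with `table` (2x2 integer matrix), `chi2`, `p`; a
#'   `warning` element is attached when any expected cell is < 1
#' @export
secreted_enrichment <- function(regulated, universe, annotation) {
  if (!all(regulated %in% universe))
    stop("regulated genes must be a subset of the universe")
  regulated <- unique(regulated)
  universe <- unique(universe)
  annotation <- intersect(unique(annotation), universe)
  nonreg <- setdiff(universe, regulated)
  tab <- matrix(c(sum(regulated %in% annotation),
                  sum(!(regulated %in% annotation)),
                  sum(nonreg %in% annotation),
                  sum(!(nonreg %in% annotation))),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("regulated", "not_regulated"),
                                c("annotated", "not_annotated")))
  chisq_2x2(tab)
}

# Pearson chi-square on a 2x2 table, no Yates correction.
chisq_2x2 <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(tab == 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    res <- list(table = tab, chi2 = NA_real_, p = NA_real_)
    res$warning <- "degenerate margin"
    return(res)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  res <- list(table = tab, chi2 = unname(ct$statistic), p = ct$p.value)
  if (any(expected < 1)) res$warning <- "expected cell count < 1"
  res
}

#' MDS embedding of samples after participant-effect removal
#'
#' Computes log2-CPM (prior count 0.5), subtracts each participant's mean
#' profile (removing the paired-design batch structure), and embeds the
#' samples by classical MDS on leading-log-fold-change distances: the
#' distance between two samples is the root mean square of the `top`
#' largest absolute per-gene log differences for that pair.
#'
#' @param cm a [count_matrix()] with >= 3 samples
#' @param dims number of MDS dimensions (< number of samples)
#' @param top number of top genes per pair entering the distance
#' @param remove_participant subtract participant mean profiles first
#' @return matrix (samples x dims) of coordinates
#' @export
mds_embedding <- function(cm, dims = 2, top = 500,
                          remove_participant = TRUE) {
  n <- ncol(cm$counts)
  if (n < 3) stop("need at least 3 samples")
  if (dims >= n) stop("dims must be smaller than the number of samples")
  lcpm <- cpm(cm, log = TRUE)
  if (remove_participant) {
    part <- factor(cm$design$participant)
    for (lev in levels(part)) {
      idx <- which(part == lev)
      lcpm[, idx] <- lcpm[, idx] - rowMeans(lcpm[, idx, drop = FALSE])
    }
  }
  top <- min(top, nrow(lcpm))
  d <- matrix(0, n, n, dimnames = list(colnames(cm$counts),
                                       colnames(cm$counts)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffs <- sort((lcpm[, i] - lcpm[, j])^2, decreasing = TRUE)[seq_len(top)]
      d[i, j] <- d[j, i] <- sqrt(mean(diffs))
    }
  }
  coords <- stats::cmdscale(stats::as.dist(d), k = dims)
  colnames(coords) <- paste0("dim", seq_len(dims))
  coords
}
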