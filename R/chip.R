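#' Coverage-based consensus peaks
#'
#' Builds a reproducible consensus region set from per-sample peak calls:
#' the genome is partitioned by the union of all peaks, and maximal runs
#' of bases covered by at least `min_support` samples are kept,
#' intersected back to the union-peak extents. This deterministic
#' coverage rule plays the role of a reproducibility filter over
#' replicate peak calls. The default support is a majority of samples.
#'
#' @param per_sample_peaks list (>= 2 elements) of interval data.frames
#' @param min_support minimum number of samples covering a base
#'   (default `ceiling(n_samples / 2)`)
#' @return interval data.frame sorted by (chrom, start)
#' @export
consensus_peaks <- function(per_sample_peaks,
                            min_support = ceiling(length(per_sample_peaks) / 2)) {
  if (length(per_sample_peaks) < 2)
    stop("need peak calls from at least 2 samples")
  if (min_support < 1) stop("min_support must be >= 1")
  if (min_support > length(per_sample_peaks))
    stop("min_support exceeds the number of samples")
  grl <- lapply(unname(per_sample_peaks), as_granges)
  all_gr <- do.call(c, grl)
  if (length(all_gr) == 0)
    return(genomic_intervals(character(), numeric(), numeric()))
  cov <- GenomicRanges::coverage(all_gr)
  supported <- methods::as(IRanges::slice(cov, lower = min_support,
                                          rangesOnly = TRUE), "GRanges")
  union_ext <- GenomicRanges::reduce(all_gr)
  out <- GenomicRanges::intersect(supported, union_ext)
  out <- GenomicRanges::sort(out)
  genomic_intervals(as.character(GenomicRanges::seqnames(out)),
                    GenomicRanges::start(out) - 1,
                    GenomicRanges::end(out))
}

#' Identify enhancers as dual-mark consensus peaks
#'
#' An enhancer is an H3K27ac consensus peak that overlaps at least one
#' H3K4me1 consensus peak by a single nucleotide. The H3K27ac peak is the
#' enhancer unit: returned coordinates are the K27 peaks, unchanged.
#'
#' @param k27_consensus,k4_consensus interval data.frames
#' @return subset of `k27_consensus` (row order preserved)
#' @export
identify_enhancers <- function(k27_consensus, k4_consensus) {
  validate_intervals(k27_consensus)
  validate_intervals(k4_consensus)
  if (nrow(k27_consensus) == 0) return(k27_consensus)
  hits <- overlap_pairs(k27_consensus, k4_consensus)
  k27_consensus[sort(unique(hits$query)), , drop = FALSE]
}

#' Paired differential H3K27ac activity
#'
#' Per-region paired NB likelihood-ratio test of the training effect on
#' H3K27ac counts; see [nb_paired_test()] for the model. Normalisation is
#' by library-size offset only; `mean_cpm` is reported for plotting.
#'
#' @inheritParams nb_paired_test
#' @return differential result data.frame
#' @export
differential_activity <- function(cm, adjust_method = c("BH", "bonferroni"),
                                  dispersion_floor = 1e-4, log2_fc = FALSE) {
  nb_paired_test(cm, adjust_method = adjust_method,
                 dispersion_floor = dispersion_floor, log2_fc = log2_fc)
}

#' Classify regulated enhancers
#'
#' Splits features into up- (q < fdr, logFC > 0) and down-regulated
#' (q < fdr, logFC < 0) sets; the sets are disjoint by construction.
#'
#' @param results differential result data.frame
#' @param fdr FDR cutoff (default 0.1)
#' @return list with character vectors `up` and `down`
#' @export
classify_regulated <- function(results, fdr = 0.1) {
  sig <- !is.na(results$q) & results$q < fdr
  list(up = results$feature_id[sig & results$logFC > 0],
       down = results$feature_id[sig & results$logFC < 0])
}

#' Select non-regulated enhancers
#'
#' The `n` features least responsive to training: largest q, ties broken
#' by larger p, then lexicographically smaller feature id. Used as the
#' contrast enhancer set in the GWAS enrichment analysis.
#'
#' @param results differential result data.frame
#' @param n number of features to select
#' @return character vector of feature ids
#' @export
select_nonregulated <- function(results, n) {
  if (n > nrow(results)) stop("n exceeds the number of tested features")
  ord <- order(-results$q, -results$p, results$feature_id)
  results$feature_id[ord][seq_len(n)]
}
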