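#' Count matrix with paired pre/post design
#'
#' Container for feature x sample integer counts together with the
#' per-sample design: participant id, training status (0 = untrained,
#' 1 = trained), and library size (total sequencing depth, used as a
#' normalisation offset; it need not bound the column sums).
#'
#' @param counts non-negative integer matrix, features in rows; rownames
#'   are feature ids, colnames sample ids
#' @param participant per-sample participant ids (length `ncol(counts)`)
#' @param training per-sample 0/1 training status
#' @param library_size per-sample positive library sizes
#' @return object of class `count_matrix`
#' @export
count_matrix <- function(counts, participant, training, library_size) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("feature_%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample_%02d", seq_len(ncol(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- ncol(counts)
  if (length(participant) != n || length(training) != n ||
      length(library_size) != n)
    stop("design vectors must have one entry per sample")
  if (!all(training %in% c(0, 1)))
    stop("training status must be coded 0 (untrained) / 1 (trained)")
  if (any(library_size <= 0)) stop("library sizes must be positive")
  design <- data.frame(sample_id = colnames(counts),
                       participant = as.character(participant),
                       training = as.integer(training),
                       library_size = as.numeric(library_size),
                       stringsAsFactors = FALSE)
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples, %d participants\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$design$participant))))
  invisible(x)
}

# Require each participant to appear in both training states.
check_paired_design <- function(cm) {
  tab <- table(cm$design$participant, cm$design$training)
  bad <- rownames(tab)[tab[, "0"] == 0 | tab[, "1"] == 0]
  if (length(bad) > 0)
    stop("unpaired participant(s): ", paste(bad, collapse = ", "))
  invisible(cm)
}

#' Counts per million
#'
#' @param cm a [count_matrix()]
#' @param log return log2-CPM with the given prior count
#' @param prior_count prior added (scaled by library size) before logging
#' @return numeric matrix of CPM values
#' @export
cpm <- function(cm, log = FALSE, prior_count = 0.5) {
  lib <- cm$design$library_size
  if (!log)
    return(t(t(cm$counts) / lib) * 1e6)
  # library-size-scaled prior, as in standard log-CPM practice
  prior <- prior_count * lib / mean(lib)
  adj_lib <- lib + 2 * prior
  log2(t((t(cm$counts) + prior) / adj_lib) * 1e6)
}
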