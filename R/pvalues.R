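#' Multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()] exposing the two adjustments the
#' pipeline uses: Benjamini-Hochberg FDR (the default for all
#' feature-level tests, discoveries called at q < 0.1) and Bonferroni.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @param method `"BH"` (default) or `"bonferroni"`
#' @return list with elements `p`, `q`, `method`
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04))$q  # all 0.04
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = method)
  list(p = p, q = q, method = method)
}
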