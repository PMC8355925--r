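#' Block-structured LD reference
#'
#' Pairwise R-squared lookup over a panel of SNPs partitioned into
#' disjoint LD blocks. R-squared is symmetric, `r2(x, x) = 1`, and SNPs
#' in different blocks have `r2 = 0`; only within-block pairs need to be
#' listed. This block model is sufficient for the two thresholds the
#' pipeline consumes (clumping at 0.5, tag expansion at 1.0).
#'
#' @param blocks data.frame `snp_id`, `block_id`
#' @param pairs data.frame `snp_a`, `snp_b`, `r2` (within-block pairs;
#'   either orientation)
#' @return object of class `ld_reference`
#' @export
ld_reference <- function(blocks, pairs) {
  stopifnot(all(c("snp_id", "block_id") %in% names(blocks)),
            all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
  if (anyDuplicated(blocks$snp_id))
    stop("duplicate snp_id in block map")
  if (any(pairs$r2 < 0 | pairs$r2 > 1))
    stop("r2 values must lie in [0, 1]")
  block_of <- stats::setNames(as.character(blocks$block_id), blocks$snp_id)
  sym <- data.table::data.table(
    a = c(pairs$snp_a, pairs$snp_b),
    b = c(pairs$snp_b, pairs$snp_a),
    r2 = c(pairs$r2, pairs$r2))
  sym <- unique(sym, by = c("a", "b"))
  data.table::setkeyv(sym, c("a", "b"))
  structure(list(block_of = block_of, pairs = sym), class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("ld_reference: %d SNPs in %d blocks, %d listed pairs\n",
              length(x$block_of), length(unique(x$block_of)),
              nrow(x$pairs) / 2))
  invisible(x)
}

#' Pairwise R-squared lookup
#'
#' @param ld an [ld_reference()]
#' @param a,b equal-length vectors of snp ids
#' @return numeric vector of R-squared values (1 on the diagonal, 0
#'   across blocks or for unlisted within-block pairs)
#' @export
ld_r2 <- function(ld, a, b) {
  a <- as.character(a); b <- as.character(b)
  unknown <- c(a[!(a %in% names(ld$block_of))],
               b[!(b %in% names(ld$block_of))])
  if (length(unknown) > 0)
    stop("SNP(s) missing from LD reference: ",
         paste(utils::head(unique(unknown), 5), collapse = ", "))
  out <- numeric(length(a))
  same <- a == b
  out[same] <- 1
  cross <- !same & ld$block_of[a] != ld$block_of[b]
  idx <- which(!same & !cross)
  if (length(idx) > 0) {
    itab <- data.table::data.table(qa = a[idx], qb = b[idx])
    m <- ld$pairs[itab, on = c(a = "qa", b = "qb")]
    out[idx] <- ifelse(is.na(m$r2), 0, m$r2)
  }
  out
}

# All (lead, partner) pairs with r2 >= threshold, partner restricted to
# `universe` ids; used by tag expansion and clumping.
ld_partners <- function(ld, leads, r2_threshold, universe = NULL) {
  p <- ld$pairs[ld$pairs$a %in% leads & ld$pairs$r2 >= r2_threshold, ]
  if (!is.null(universe)) p <- p[p$b %in% universe, ]
  p
}
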