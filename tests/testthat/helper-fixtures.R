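# Shared fixtures and independent oracles for the test suite.

# Tiny paired count matrix: one row per feature, explicit counts.
tiny_cm <- function(counts, participants = NULL, lib = NULL) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  np <- n / 2
  if (is.null(participants))
    participants <- rep(sprintf("P%d", seq_len(np)), 2)
  if (is.null(lib)) lib <- rep(1e6, n)
  count_matrix(counts, participants, rep(c(0, 1), each = np), lib)
}

# Random LD panel of <= 12 SNPs with a randomised symmetric R^2 matrix,
# for exercising ld_clump against the brute-force oracle. Block
# structure: random partition; within-block r2 drawn U(0, 1).
random_ld_panel <- function(seed, n_max = 12) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  block <- sort(sample(seq_len(max(1, n %/% 2)), n, replace = TRUE))
  ids <- sprintf("s%02d", seq_len(n))
  snps <- data.frame(snp_id = ids, chrom = "chr1",
                     pos = sample.int(1e6, n),
                     p_assoc = 10^(-runif(n, 8, 20)),
                     trait = "t", maf = runif(n, 0.05, 0.5),
                     gene_density = 1, dist_nearest_gene = 1000,
                     ld_buddies = 0, block_id = paste0("b", block),
                     stringsAsFactors = FALSE)
  pairs <- NULL
  for (b in unique(block)) {
    m <- which(block == b)
    if (length(m) < 2) next
    cmb <- utils::combn(m, 2)
    pairs <- rbind(pairs, data.frame(snp_a = ids[cmb[1, ]],
                                     snp_b = ids[cmb[2, ]],
                                     r2 = runif(ncol(cmb))))
  }
  if (is.null(pairs))
    pairs <- data.frame(snp_a = character(), snp_b = character(),
                        r2 = numeric())
  list(snps = snps,
       ld = ld_reference(snps[, c("snp_id", "block_id")], pairs))
}

# Brute-force clumping validity oracle: the kept set is valid iff
# (a) every removed SNP has r2 >= threshold to some kept SNP with a
#     stronger (or tie-broken stronger) p, and
# (b) no kept SNP has r2 >= threshold to a stronger kept SNP.
clump_is_valid <- function(kept_ids, snps, ld, thr = 0.5) {
  rank_key <- order(snps$p_assoc, snps$pos, snps$snp_id)
  rk <- match(snps$snp_id, snps$snp_id[rank_key])
  names(rk) <- snps$snp_id
  removed <- setdiff(snps$snp_id, kept_ids)
  for (r in removed) {
    buddies <- kept_ids[ld_r2(ld, rep(r, length(kept_ids)), kept_ids) >= thr]
    if (!any(rk[buddies] < rk[r])) return(FALSE)
  }
  for (k in kept_ids) {
    others <- setdiff(kept_ids, k)
    if (length(others) == 0) next
    strong <- others[rk[others] < rk[k]]
    if (length(strong) > 0 &&
        any(ld_r2(ld, rep(k, length(strong)), strong) >= thr))
      return(FALSE)
  }
  TRUE
}

# Enhancer fixture: named intervals on one chromosome.
toy_enhancers <- function() {
  genomic_intervals(rep("chr1", 3), c(100, 1000, 5000),
                    c(400, 1600, 5200),
                    name = c("enhA", "enhB", "enhC"))
}
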