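#' Read a SNP table
#'
#' TSV with header columns `snp_id`, `chrom`, `pos` (1-based, converted
#' to 0-based on read), `p_assoc`, `trait`, `maf`, `gene_density`,
#' `dist_nearest_gene`, `ld_buddies`, `block_id`, and optionally
#' `is_haplotype` (0/1).
#'
#' @param path path to SNP TSV
#' @return SNP data.frame with 0-based `pos`
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("snp_id", "chrom", "pos", "p_assoc", "trait", "maf",
           "gene_density", "dist_nearest_gene", "ld_buddies", "block_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("SNP table lacks column(s): ", paste(missing_cols, collapse = ", "))
  df$pos <- df$pos - 1
  if (is.null(df$is_haplotype)) df$is_haplotype <- 0L
  df
}

#' Filter a GWAS-catalog-like SNP table
#'
#' Keeps single-variant records with a defined genome position reaching
#' genome-wide significance (`p_assoc < p_threshold`, strict).
#' Haplotype/multi-variant records are dropped. Duplicates by
#' `(snp_id, trait)` collapse to the record with the smallest
#' association p-value.
#'
#' @param raw SNP data.frame (see [read_snp_table()])
#' @param p_threshold genome-wide significance cutoff (default 5e-8)
#' @return filtered SNP data.frame
#' @export
filter_catalog <- function(raw, p_threshold = 5e-8) {
  keep <- !is.na(raw$pos) & !is.na(raw$p_assoc) &
    raw$p_assoc < p_threshold
  if (!is.null(raw$is_haplotype)) keep <- keep & !(raw$is_haplotype %in% 1)
  out <- raw[keep, , drop = FALSE]
  if (nrow(out) == 0) return(out)
  ord <- order(out$snp_id, out$trait, out$p_assoc)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out[, c("snp_id", "trait")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining SNP with the smallest association
#' p-value (ties broken by smaller position, then snp id) as a clump
#' index and removes every remaining SNP with `r2 >= r2_threshold` to
#' it. Deterministic and invariant to input order. No distance window is
#' applied: correlation is bounded by the block structure of the LD
#' reference.
#'
#' @param snps SNP data.frame; all ids must be present in `ld`
#' @param ld an [ld_reference()]
#' @param r2_threshold clumping threshold (default 0.5)
#' @return the index SNPs, sorted by (chrom, pos)
#' @export
ld_clump <- function(snps, ld, r2_threshold = 0.5) {
  if (nrow(snps) == 0) return(snps)
  missing_ids <- snps$snp_id[!(snps$snp_id %in% names(ld$block_of))]
  if (length(missing_ids) > 0)
    stop("SNP(s) missing from LD reference: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  ord <- order(snps$p_assoc, snps$pos, snps$snp_id)
  s <- snps[ord, , drop = FALSE]
  n <- nrow(s)
  # integer adjacency restricted to pairs at/above the threshold
  adj_tab <- ld_partners(ld, s$snp_id, r2_threshold, universe = s$snp_id)
  adj <- vector("list", n)
  if (nrow(adj_tab) > 0) {
    ai <- match(adj_tab$a, s$snp_id)
    bi <- match(adj_tab$b, s$snp_id)
    sp <- split(bi, ai)
    adj[as.integer(names(sp))] <- sp
  }
  removed <- logical(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (removed[i]) next
    keep[i] <- TRUE
    nb <- adj[[i]]
    if (!is.null(nb)) removed[nb] <- TRUE
  }
  out <- s[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Covariate windows for control-SNP matching
#'
#' Defaults mirror standard matched-SNP practice: minor allele frequency
#' within +/- 0.05 absolute, and gene density, distance to nearest gene,
#' and LD-buddy count within +/- 50% of the index SNP's value.
#'
#' @param maf_abs absolute MAF half-window
#' @param rel relative half-window for the three remaining covariates
#' @return list of window settings
#' @export
matching_windows <- function(maf_abs = 0.05, rel = 0.5) {
  list(maf_abs = maf_abs, rel = rel)
}

# Eligibility of pool rows for one index SNP.
matching_eligible <- function(index, pool, windows) {
  abs(pool$maf - index$maf) <= windows$maf_abs &
    pool$gene_density >= (1 - windows$rel) * index$gene_density &
    pool$gene_density <= (1 + windows$rel) * index$gene_density &
    pool$dist_nearest_gene >= (1 - windows$rel) * index$dist_nearest_gene &
    pool$dist_nearest_gene <= (1 + windows$rel) * index$dist_nearest_gene &
    pool$ld_buddies >= (1 - windows$rel) * index$ld_buddies &
    pool$ld_buddies <= (1 + windows$rel) * index$ld_buddies
}

#' Matched control SNPs for one index SNP
#'
#' Draws `k` control SNPs without replacement from the pool members
#' lying inside all covariate windows of the index SNP. When fewer than
#' `k` are eligible, all eligible controls are returned and the result
#' carries `attr(, "shortfall") = TRUE`.
#'
#' @param index single-row SNP data.frame
#' @param pool control SNP data.frame (disjoint from the GWAS set)
#' @param k controls per index (default 2, i.e. 1:2 matching)
#' @param windows a [matching_windows()] list
#' @param rng_seed integer seed for the (restored-afterwards) draw
#' @return data.frame of matched controls
#' @export
match_controls <- function(index, pool, k = 2,
                           windows = matching_windows(), rng_seed = 1) {
  if (nrow(pool) == 0) stop("control pool is empty")
  elig <- which(matching_eligible(index, pool, windows))
  shortfall <- length(elig) < k
  take <- if (shortfall) elig
          else with_seed(rng_seed, sample(elig, k))
  out <- pool[take, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "shortfall") <- shortfall
  out
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Matched controls for a whole index set
#'
#' Batch driver over [match_controls()] semantics: for every index SNP,
#' `k` controls drawn from its covariate windows. Sampling is by seeded
#' rejection rounds over a MAF-sorted pool (fast at tens of thousands of
#' indices); indices whose windows contain fewer than `k` pool members
#' return what exists and are flagged.
#'
#' @param indices SNP data.frame of clumped index SNPs
#' @param pool control SNP data.frame
#' @param k controls per index
#' @param windows a [matching_windows()] list
#' @param rng_seed integer seed
#' @return data.frame: control rows plus `index_snp`, `index_pos`,
#'   `category` columns copied from the matched index; shortfall ids in
#'   attribute `"shortfall_ids"`
#' @export
match_controls_all <- function(indices, pool, k = 2,
                               windows = matching_windows(), rng_seed = 1) {
  if (nrow(pool) == 0) stop("control pool is empty")
  n <- nrow(indices)
  if (n == 0) {
    out <- pool[0, , drop = FALSE]
    out$index_snp <- character(0)
    return(out)
  }
  ord <- order(pool$maf)
  pool_s <- pool[ord, , drop = FALSE]
  maf_s <- pool_s$maf
  lo <- findInterval(indices$maf - windows$maf_abs, maf_s,
                     left.open = TRUE) + 1L
  hi <- findInterval(indices$maf + windows$maf_abs, maf_s)
  chosen <- matrix(NA_integer_, nrow = n, ncol = k)
  with_seed(rng_seed, {
    for (slot in seq_len(k)) {
      active <- which(hi >= lo)
      for (round in seq_len(60)) {
        if (length(active) == 0) break
        cand <- lo[active] +
          floor(stats::runif(length(active)) * (hi[active] - lo[active] + 1L))
        ok <- eligible_rows(indices, active, pool_s, cand, windows)
        if (slot > 1) { # without replacement within an index
          dup <- rowSums(chosen[active, seq_len(slot - 1), drop = FALSE] ==
                           cand, na.rm = TRUE) > 0
          ok <- ok & !dup
        }
        chosen[active[ok], slot] <- cand[ok]
        active <- active[!ok]
      }
      # exhaustive fallback for stragglers (rare small windows)
      for (i in active) {
        cand_rows <- seq(lo[i], hi[i])
        ok <- eligible_rows(indices, rep(i, length(cand_rows)), pool_s,
                            cand_rows, windows)
        cand_rows <- setdiff(cand_rows[ok],
                             chosen[i, seq_len(slot - 1)][!is.na(chosen[i, ])])
        if (length(cand_rows) > 0)
          chosen[i, slot] <- cand_rows[sample.int(length(cand_rows), 1)]
      }
    }
  })
  idx_rep <- rep(seq_len(n), k)
  sel <- as.vector(chosen)
  keep <- !is.na(sel)
  out <- pool_s[sel[keep], , drop = FALSE]
  out$index_snp <- indices$snp_id[idx_rep[keep]]
  out$index_pos <- indices$pos[idx_rep[keep]]
  if (!is.null(indices$category))
    out$category <- indices$category[idx_rep[keep]]
  rownames(out) <- NULL
  got <- rowSums(!is.na(chosen))
  attr(out, "shortfall_ids") <- indices$snp_id[got < k]
  out
}

eligible_rows <- function(indices, idx, pool_s, rows, windows) {
  rel <- windows$rel
  abs(pool_s$maf[rows] - indices$maf[idx]) <= windows$maf_abs &
    pool_s$gene_density[rows] >= (1 - rel) * indices$gene_density[idx] &
    pool_s$gene_density[rows] <= (1 + rel) * indices$gene_density[idx] &
    pool_s$dist_nearest_gene[rows] >=
      (1 - rel) * indices$dist_nearest_gene[idx] &
    pool_s$dist_nearest_gene[rows] <=
      (1 + rel) * indices$dist_nearest_gene[idx] &
    pool_s$ld_buddies[rows] >= (1 - rel) * indices$ld_buddies[idx] &
    pool_s$ld_buddies[rows] <= (1 + rel) * indices$ld_buddies[idx]
}

#' De-duplicate control SNPs within categories
#'
#' Within each disease/trait category, a control snp id may appear only
#' once; the first occurrence in index-SNP position order is kept. The
#' same control may still serve different categories.
#'
#' @param controls data.frame with `snp_id`, `category`, `index_pos`
#' @return de-duplicated data.frame
#' @export
dedup_controls <- function(controls) {
  if (nrow(controls) == 0) return(controls)
  ord <- order(controls$category, controls$index_pos, controls$snp_id)
  out <- controls[ord, , drop = FALSE]
  out <- out[!duplicated(out[, c("category", "snp_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tag-SNP expansion at perfect LD
#'
#' The lead SNP plus every universe SNP in LD with it at
#' `r2 >= r2_threshold` (default 1: perfect proxies only).
#'
#' @param lead single-row SNP data.frame (must be in `universe`)
#' @param ld an [ld_reference()]
#' @param universe SNP data.frame of candidate tags
#' @param r2_threshold tag threshold (default 1.0)
#' @return SNP data.frame: lead plus its tags
#' @export
expand_tags <- function(lead, ld, universe, r2_threshold = 1.0) {
  partners <- ld_partners(ld, lead$snp_id, r2_threshold,
                          universe = universe$snp_id)$b
  ids <- unique(c(lead$snp_id, partners))
  out <- universe[match(ids, universe$snp_id), , drop = FALSE]
  out <- out[!is.na(out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Block-collapsed enhancer overlap for one lead
#'
#' 1 when any of the lead's tag SNPs (the lead included) falls inside an
#' enhancer interval, else 0. However many SNPs of the LD block overlap,
#' the contribution is a single overlap per lead.
#'
#' @param lead single-row SNP data.frame
#' @param tags SNP data.frame including the lead (see [expand_tags()])
#' @param enhancers interval data.frame
#' @return integer 0 or 1
#' @export
block_overlap <- function(lead, tags, enhancers) {
  if (!lead$snp_id %in% tags$snp_id)
    stop("tags must include the lead SNP")
  as.integer(any(positions_in_intervals(tags$chrom, tags$pos, enhancers)))
}

# Batch block-collapsed overlap flags: one 0/1 flag per lead after tag
# expansion at r2 >= r2_threshold within `universe`.
overlap_flags <- function(leads, ld, universe, enhancers,
                          r2_threshold = 1.0) {
  if (nrow(leads) == 0) return(integer(0))
  partners <- ld_partners(ld, leads$snp_id, r2_threshold,
                          universe = universe$snp_id)
  tag_tab <- data.frame(lead = c(leads$snp_id, partners$a),
                        tag = c(leads$snp_id, partners$b),
                        stringsAsFactors = FALSE)
  uidx <- match(tag_tab$tag, universe$snp_id)
  ok <- !is.na(uidx)
  tag_tab <- tag_tab[ok, , drop = FALSE]
  inside <- positions_in_intervals(universe$chrom[uidx[ok]],
                                   universe$pos[uidx[ok]], enhancers)
  hit_leads <- unique(tag_tab$lead[inside])
  as.integer(leads$snp_id %in% hit_leads)
}

#' Logistic-regression enrichment test on overlap flags
#'
#' Tests whether case (GWAS) SNPs have higher odds of overlapping an
#' enhancer than control SNPs: `logit P(flag = 1) = b0 + b1 is_case`,
#' fit by IRLS ([stats::glm()] binomial). The odds ratio is `exp(b1)`
#' with a 95% Wald interval from the observed information; for this
#' saturated binary predictor it equals the 2x2 cross-product ratio. A
#' zero margin (no cases, no controls, no overlaps anywhere, or
#' all-overlap) makes the OR unidentifiable: the result is flagged
#' degenerate with a sentinel `NA` OR.
#'
#' @param case_flags,control_flags 0/1 overlap vectors
#' @return one-row data.frame: `n_case`, `n_case_overlap`, `n_control`,
#'   `n_control_overlap`, `or_estimate`, `ci_low`, `ci_high`, `p`,
#'   `degenerate`
#' @export
enrichment_test <- function(case_flags, control_flags) {
  if (length(case_flags) == 0 || length(control_flags) == 0)
    stop("both flag vectors must be nonempty")
  stopifnot(all(case_flags %in% 0:1), all(control_flags %in% 0:1))
  a <- sum(case_flags); n1 <- length(case_flags)
  b <- sum(control_flags); n0 <- length(control_flags)
  cells <- c(a, n1 - a, b, n0 - b)
  out <- data.frame(n_case = n1, n_case_overlap = a,
                    n_control = n0, n_control_overlap = b,
                    or_estimate = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_, degenerate = FALSE)
  if (a + b == 0 || (n1 - a) + (n0 - b) == 0) {
    out$degenerate <- TRUE
    return(out)
  }
  if (any(cells == 0)) {
    # zero cell, nonzero margins: OR degenerates to 0 or Inf
    out$or_estimate <- (a * (n0 - b)) / (b * (n1 - a))
    out$degenerate <- TRUE
    return(out)
  }
  dat <- data.frame(flag = c(1, 0, 1, 0), is_case = c(1, 1, 0, 0),
                    w = cells)
  fit <- stats::glm(flag ~ is_case, family = stats::binomial(),
                    data = dat, weights = w,
                    control = list(epsilon = 1e-12, maxit = 50))
  est <- summary(fit)$coefficients["is_case", ]
  out$or_estimate <- exp(est["Estimate"])
  out$ci_low <- exp(est["Estimate"] - 1.96 * est["Std. Error"])
  out$ci_high <- exp(est["Estimate"] + 1.96 * est["Std. Error"])
  out$p <- 2 * stats::pnorm(-abs(est["Estimate"] / est["Std. Error"]))
  out
}

#' Per-category GWAS enrichment over enhancer sets
#'
#' For the combined SNP set and for each disease/trait category: expand
#' tag SNPs for every case and control lead (perfect proxies,
#' `r2 >= 1`), compute block-collapsed overlap flags against the
#' enhancer intervals, and run the logistic enrichment test. When a
#' non-regulated enhancer set is supplied the analysis is repeated
#' against it; rows are tagged by `enhancer_set`. The combined analysis
#' pools all categories and de-duplicates leads and controls by snp id.
#'
#' @param gwas clumped GWAS SNP data.frame with a `category` column
#' @param controls matched, de-duplicated control data.frame with
#'   `category`
#' @param enhancers regulated-enhancer interval data.frame
#' @param ld an [ld_reference()]
#' @param universe SNP data.frame used for tag lookups
#' @param nonregulated optional contrast enhancer interval data.frame
#' @param min_category_n warn below this many category SNPs (default
#'   150)
#' @return data.frame of [enrichment_test()] rows with `category` and
#'   `enhancer_set` columns
#' @export
run_enrichment <- function(gwas, controls, enhancers, ld, universe,
                           nonregulated = NULL, min_category_n = 150) {
  stopifnot(!is.null(gwas$category), !is.null(controls$category))
  sets <- list(regulated = enhancers)
  if (!is.null(nonregulated)) sets$nonregulated <- nonregulated
  res <- list()
  for (set_name in names(sets)) {
    enh <- sets[[set_name]]
    case_flags <- overlap_flags(gwas, ld, universe, enh)
    ctrl_flags <- overlap_flags(controls, ld, universe, enh)
    comb_case <- !duplicated(gwas$snp_id)
    comb_ctrl <- !duplicated(controls$snp_id)
    row <- enrichment_test(case_flags[comb_case], ctrl_flags[comb_ctrl])
    row$category <- "combined"; row$enhancer_set <- set_name
    res[[length(res) + 1]] <- row
    for (cat in sort(unique(gwas$category))) {
      ci <- gwas$category == cat
      if (sum(ci) == 0) {
        message("skipping category with no SNPs: ", cat)
        next
      }
      if (sum(ci) < min_category_n)
        warning("category '", cat, "' has fewer than ", min_category_n,
                " SNPs (", sum(ci), ")", call. = FALSE)
      wi <- controls$category == cat
      if (sum(wi) == 0) {
        message("skipping category with no controls: ", cat)
        next
      }
      row <- enrichment_test(case_flags[ci], ctrl_flags[wi])
      row$category <- cat; row$enhancer_set <- set_name
      res[[length(res) + 1]] <- row
    }
  }
  out <- do.call(rbind, res)
  out[, c("category", "enhancer_set", "n_case", "n_case_overlap",
          "n_control", "n_control_overlap", "or_estimate", "ci_low",
          "ci_high", "p", "degenerate")]
}
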