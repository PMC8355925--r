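#' Simulation configuration
#'
#' Parameters of the seeded synthetic study. Defaults mirror the study
#' design the pipeline targets: 8 participants sampled pre and post
#' training, dual-mark enhancers as ~75% of H3K27ac regions, a minority
#' of regions regulated with mostly decreasing acetylation, negative
#' binomial counts with dispersion 0.1, 19 disease/trait categories,
#' and 1:2 GWAS:control matching with a baseline enhancer-overlap rate
#' of 1.8%.
#'
#' @param seed integer RNG seed fixing every output bit
#' @param n_participants paired participants (>= 2)
#' @param n_regions candidate H3K27ac consensus regions
#' @param n_genes genes with detectable expression
#' @param frac_dual_mark fraction of regions also covered by H3K4me1
#' @param frac_regulated fraction of dual-mark regions carrying a
#'   planted training effect
#' @param frac_up_among_regulated fraction of planted effects that are
#'   positive (the rest decrease)
#' @param effect_logfc_mean,effect_logfc_sd natural-log effect-size
#'   magnitude distribution (`abs(rnorm)`)
#' @param nb_dispersion negative binomial dispersion of the counts
#' @param library_size_range integer pair: uniform range of per-sample
#'   library sizes
#' @param participant_sd standard deviation of per-participant
#'   log-abundance effects (shared between ChIP and RNA counts)
#' @param coupling enhancer-to-gene effect transmission coefficient
#' @param gene_noise_sd independent noise on planted gene effects
#' @param n_snps independent GWAS lead SNPs
#' @param n_blocks upper bound hint for LD blocks (blocks are built per
#'   lead; kept for interface compatibility)
#' @param n_categories disease/trait categories (default 19)
#' @param planted_category_or per-category planted odds ratio of
#'   enhancer placement (single value recycled, or named vector by
#'   category); 1 = null
#' @param control_ratio matched controls requested per index SNP
#' @param baseline_overlap control SNP probability of lying inside an
#'   enhancer interval
#' @param frac_multi_lead fraction of GWAS leads sharing an LD block
#'   with a second, weaker catalog SNP (exercises clumping)
#' @return validated list of class `simulation_config`
#' @export
simulation_config <- function(seed = 1,
                              n_participants = 8,
                              n_regions = 2000,
                              n_genes = 1000,
                              frac_dual_mark = 0.75,
                              frac_regulated = 0.10,
                              frac_up_among_regulated = 0.21,
                              effect_logfc_mean = 1.5,
                              effect_logfc_sd = 0.25,
                              nb_dispersion = 0.1,
                              library_size_range = c(2e5, 5e5),
                              participant_sd = 0.2,
                              coupling = 0.8,
                              gene_noise_sd = 0.1,
                              n_snps = 4000,
                              n_blocks = NULL,
                              n_categories = 19,
                              planted_category_or = 1.0,
                              control_ratio = 2,
                              baseline_overlap = 0.018,
                              frac_multi_lead = 0.05) {
  cfg <- as.list(environment())
  fracs <- c(frac_dual_mark, frac_regulated, frac_up_among_regulated)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (n_participants < 2) stop("need at least 2 participants")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (any(planted_category_or <= 0)) stop("planted ORs must be positive")
  if (frac_dual_mark * n_regions < 1)
    stop("frac_dual_mark * n_regions must be at least 1")
  class(cfg) <- "simulation_config"
  cfg
}

# Deterministic sub-seed so successive generator stages draw from
# independent streams of the one user-facing seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

#' Canonical disease/trait category labels
#'
#' @param n number of categories
#' @return character vector of labels
#' @export
trait_categories <- function(n = 19) {
  base <- c("anthropometric", "autoimmune", "bone_mineral_density",
            "cancer", "cardiovascular", "cognitive", "coagulation",
            "inflammatory_bowel_disease", "inflammatory_response",
            "lipid_levels", "lung_related", "diabetes_glucose",
            "neuropsychiatric", "obesity_related", "ophthalmological",
            "oxygen_carriers", "renal_function", "female_reproductive",
            "others")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("category_%02d", seq_len(n - length(base))))
}

# Lay n_regions regions across 4 chromosomes with random widths/gaps.
layout_regions <- function(n_regions) {
  chroms <- paste0("chr", 1:4)
  per <- diff(round(seq(0, n_regions, length.out = 5)))
  out <- vector("list", 4)
  for (ci in seq_len(4)) {
    m <- per[ci]
    if (m == 0) next
    w <- round(stats::runif(m, 500, 3000))
    g <- round(stats::runif(m, 5000, 20000))
    start <- cumsum(g) + cumsum(c(0, utils::head(w, -1)))
    out[[ci]] <- data.frame(chrom = chroms[ci], start = start,
                            end = start + w, stringsAsFactors = FALSE)
  }
  reg <- do.call(rbind, out)
  reg$name <- sprintf("region_%05d", seq_len(nrow(reg)))
  rownames(reg) <- NULL
  reg
}

#' Simulate ChIP-seq inputs: peaks, counts, and planted truth
#'
#' Generates candidate H3K27ac consensus regions, marks a
#' `frac_dual_mark` subset as covered by H3K4me1, plants training
#' effects (natural-log fold changes, sign split by
#' `frac_up_among_regulated`) on exactly
#' `round(frac_regulated * n_dual)` dual-mark regions, and draws paired
#' negative binomial counts with mean
#' `library_size * region_weight * exp(participant_effect + training *
#' planted_logfc)` and dispersion `nb_dispersion`. Per-sample peak lists
#' are the consensus regions with each edge jittered by at most 10% of
#' the region width.
#'
#' @param config a [simulation_config()]
#' @param participant_effects optional named per-participant
#'   log-abundance effects (drawn when `NULL`; pass to share with
#'   [simulate_rna()])
#' @return list: `regions` (interval table with `name`), `k27_peaks`,
#'   `k4_peaks` (per-sample interval lists), `chip_counts`
#'   ([count_matrix()]), `truth` (data.frame `region_id`, `dual`,
#'   `regulated`, `planted_logfc`), `participant_effects`
#' @export
simulate_chip <- function(config, participant_effects = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 11L))
  regions <- layout_regions(config$n_regions)
  n <- nrow(regions)
  dual <- rep(FALSE, n)
  dual[sample.int(n, round(config$frac_dual_mark * n))] <- TRUE
  n_reg <- round(config$frac_regulated * sum(dual))
  regulated <- rep(FALSE, n)
  if (n_reg > 0)
    regulated[sample(which(dual), n_reg)] <- TRUE
  delta <- numeric(n)
  if (n_reg > 0) {
    mag <- abs(stats::rnorm(n_reg, config$effect_logfc_mean,
                            config$effect_logfc_sd))
    sgn <- ifelse(stats::runif(n_reg) < config$frac_up_among_regulated,
                  1, -1)
    delta[regulated] <- mag * sgn
  }
  np <- config$n_participants
  participants <- sprintf("P%d", seq_len(np))
  if (is.null(participant_effects)) {
    participant_effects <- stats::setNames(
      stats::rnorm(np, 0, config$participant_sd), participants)
  }
  design <- data.frame(
    participant = rep(participants, 2),
    training = rep(c(0L, 1L), each = np),
    stringsAsFactors = FALSE)
  design$sample_id <- paste0(design$participant,
                             ifelse(design$training == 0, "_pre", "_post"))
  lib <- round(stats::runif(nrow(design), config$library_size_range[1],
                            config$library_size_range[2]))
  w <- stats::rlnorm(n, 0, 0.7)
  w <- w / sum(w)
  mu <- outer(w, lib) *
    exp(outer(delta, design$training) +
          matrix(participant_effects[design$participant], n,
                 nrow(design), byrow = TRUE))
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = n, dimnames = list(regions$name, design$sample_id))
  cm <- count_matrix(counts, design$participant, design$training, lib)
  k27_peaks <- lapply(seq_len(nrow(design)),
                      function(i) jitter_peaks(regions))
  names(k27_peaks) <- design$sample_id
  k4_regions <- regions[dual, , drop = FALSE]
  width4 <- k4_regions$end - k4_regions$start
  k4_regions$start <- pmax(0, k4_regions$start - round(0.2 * width4))
  k4_regions$end <- k4_regions$end + round(0.2 * width4)
  k4_peaks <- lapply(seq_len(nrow(design)),
                     function(i) jitter_peaks(k4_regions))
  names(k4_peaks) <- design$sample_id
  truth <- data.frame(region_id = regions$name, dual = dual,
                      regulated = regulated, planted_logfc = delta,
                      stringsAsFactors = FALSE)
  list(regions = regions, k27_peaks = k27_peaks, k4_peaks = k4_peaks,
       chip_counts = cm, truth = truth,
       participant_effects = participant_effects)
}

# Jitter each peak edge by at most 10% of its width.
jitter_peaks <- function(regions) {
  w <- regions$end - regions$start
  s <- regions$start + round(stats::runif(nrow(regions), -0.1, 0.1) * w)
  e <- regions$end + round(stats::runif(nrow(regions), -0.1, 0.1) * w)
  out <- data.frame(chrom = regions$chrom, start = pmax(0, s),
                    end = pmax(pmax(0, s) + 50, e),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate an EpiMap-like scored link table
#'
#' Places `n_genes` transcription start sites across the simulated
#' genome and connects every dual-mark region to its 1-3 nearest genes
#' with interaction scores in (0.2, 1) and slightly jittered link-side
#' geometry (so link intervals resemble an external enhancer atlas
#' rather than the exact consensus coordinates).
#'
#' @param config a [simulation_config()]
#' @param regions region table from [simulate_chip()]
#' @param truth truth table from [simulate_chip()]
#' @return list: `links` (data.frame `chrom`, `start`, `end`,
#'   `gene_id`, `score`, `distance`, `enhancer_id`), `gene_tss`
#'   (data.frame `gene_id`, `chrom`, `tss`)
#' @export
simulate_links <- function(config, regions, truth) {
  set.seed(derive_seed(config$seed, 23L))
  chrom_len <- tapply(regions$end, regions$chrom, max) + 50000
  chroms <- names(chrom_len)
  gene_chrom <- sample(chroms, config$n_genes, replace = TRUE,
                       prob = as.numeric(chrom_len) / sum(chrom_len))
  tss <- floor(stats::runif(config$n_genes) *
                 as.numeric(chrom_len[gene_chrom]))
  gene_tss <- data.frame(gene_id = sprintf("gene_%05d",
                                           seq_len(config$n_genes)),
                         chrom = gene_chrom, tss = tss,
                         stringsAsFactors = FALSE)
  dual_regions <- regions[truth$dual, , drop = FALSE]
  out <- vector("list", nrow(dual_regions))
  for (i in seq_len(nrow(dual_regions))) {
    r <- dual_regions[i, ]
    cand <- gene_tss[gene_tss$chrom == r$chrom, , drop = FALSE]
    if (nrow(cand) == 0) next
    mid <- floor((r$start + r$end) / 2)
    d <- abs(cand$tss - mid)
    k <- min(sample(1:3, 1), nrow(cand))
    pick <- cand[order(d)[seq_len(k)], , drop = FALSE]
    shift <- round(stats::runif(k, -150, 150))
    out[[i]] <- data.frame(
      chrom = r$chrom, start = pmax(0, r$start + shift),
      end = r$end + shift, gene_id = pick$gene_id,
      score = stats::runif(k, 0.2, 1),
      distance = abs(pick$tss - mid),
      enhancer_id = r$name, stringsAsFactors = FALSE)
  }
  links <- do.call(rbind, out)
  rownames(links) <- NULL
  list(links = links, gene_tss = gene_tss)
}

#' Simulate RNA-seq counts coupled to enhancer truth
#'
#' A gene's planted natural-log fold change is
#' `coupling * weighted.mean(planted logFC of its linked enhancers,
#' weights = interaction scores)` plus independent Gaussian noise
#' (`gene_noise_sd`); genes without links receive noise only. Counts
#' are paired negative binomial draws with the same participant
#' effects, library-size model, and dispersion as the ChIP counts.
#'
#' @param config a [simulation_config()]
#' @param truth ChIP truth table from [simulate_chip()]
#' @param links link table from [simulate_links()] (needs
#'   `enhancer_id`, `gene_id`, `score`)
#' @param participant_effects optional shared per-participant effects
#' @return list: `rna_counts` ([count_matrix()]), `gene_truth`
#'   (data.frame `gene_id`, `planted_logfc`, `coupled_logfc`,
#'   `n_links`)
#' @export
simulate_rna <- function(config, truth, links, participant_effects = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 37L))
  gene_ids <- sprintf("gene_%05d", seq_len(config$n_genes))
  coupled <- stats::setNames(numeric(config$n_genes), gene_ids)
  n_links <- stats::setNames(integer(config$n_genes), gene_ids)
  if (!is.null(links) && nrow(links) > 0) {
    enh_fc <- truth$planted_logfc[match(links$enhancer_id, truth$region_id)]
    wsum <- tapply(links$score * enh_fc, links$gene_id, sum)
    wtot <- tapply(links$score, links$gene_id, sum)
    coupled[names(wsum)] <- as.numeric(wsum) / as.numeric(wtot)
    cnt <- table(links$gene_id)
    n_links[names(cnt)] <- as.integer(cnt)
  }
  planted <- config$coupling * coupled +
    stats::rnorm(config$n_genes, 0, config$gene_noise_sd)
  np <- config$n_participants
  participants <- sprintf("P%d", seq_len(np))
  if (is.null(participant_effects))
    participant_effects <- stats::setNames(
      stats::rnorm(np, 0, config$participant_sd), participants)
  design <- data.frame(participant = rep(participants, 2),
                       training = rep(c(0L, 1L), each = np),
                       stringsAsFactors = FALSE)
  design$sample_id <- paste0(design$participant,
                             ifelse(design$training == 0, "_pre", "_post"))
  lib <- round(stats::runif(nrow(design), config$library_size_range[1],
                            config$library_size_range[2]))
  w <- stats::rlnorm(config$n_genes, 0, 0.7)
  w <- w / sum(w)
  mu <- outer(w, lib) *
    exp(outer(planted, design$training) +
          matrix(participant_effects[design$participant],
                 config$n_genes, nrow(design), byrow = TRUE))
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = config$n_genes,
                   dimnames = list(gene_ids, design$sample_id))
  cm <- count_matrix(counts, design$participant, design$training, lib)
  gene_truth <- data.frame(gene_id = gene_ids, planted_logfc = planted,
                           coupled_logfc = config$coupling * coupled,
                           n_links = as.integer(n_links),
                           stringsAsFactors = FALSE)
  list(rna_counts = cm, gene_truth = gene_truth)
}

#' Simulate a GWAS SNP panel with block LD and matched-control pool
#'
#' Builds, per GWAS lead SNP: an LD block containing the lead, 0-2
#' perfect proxies (R-squared exactly 1) and possibly a loose buddy
#' (R-squared in \[0.5, 0.95)); matching covariates (MAF, gene density,
#' distance to nearest gene, LD-buddy count = block size - 1); and a
#' genome position that falls inside the supplied enhancer intervals
#' with per-category odds `planted_category_or` times the control
#' placement odds (`baseline_overlap`). Perfect proxies share their
#' lead's enhancer-overlap status, so block-collapsed overlap flags
#' reflect the planted odds. For every lead, `control_ratio + 1`
#' control SNPs are created whose covariates are small within-window
#' perturbations of the lead's, guaranteeing matchability. A small
#' fraction of leads share a block with a second, weaker catalog SNP;
#' sub-threshold and haplotype-flagged rows are included so catalog
#' filtering has work to do.
#'
#' @param config a [simulation_config()]
#' @param enhancers interval data.frame used for overlap planting
#' @return list: `snp_table` (all panel SNPs; catalog rows have a
#'   non-`none` trait), `ld` ([ld_reference()]), `category_map`
#'   (data.frame `trait`, `category`), `truth` (list with the planted
#'   per-category ORs and baseline)
#' @export
simulate_snp_panel <- function(config, enhancers) {
  stopifnot(inherits(config, "simulation_config"))
  validate_intervals(enhancers)
  if (nrow(enhancers) == 0) stop("enhancers must be nonempty")
  set.seed(derive_seed(config$seed, 53L))
  n <- config$n_snps
  cats <- trait_categories(config$n_categories)
  or_map <- resolve_category_or(config$planted_category_or, cats)
  p0 <- config$baseline_overlap
  category <- rep_len(cats, n)
  trait <- paste0(category, "_trait", sample.int(3, n, replace = TRUE))
  odds <- or_map[category] * p0 / (1 - p0)
  p_in <- odds / (1 + odds)
  lead_inside <- stats::runif(n) < p_in
  n_perfect <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  n_loose <- stats::rbinom(n, 1, 0.3)
  second <- stats::runif(n) < config$frac_multi_lead
  block_size <- 1L + n_perfect + n_loose + as.integer(second)
  maf <- stats::runif(n, 0.05, 0.5)
  gene_density <- stats::rlnorm(n, log(5), 0.5)
  dist_gene <- round(stats::rlnorm(n, log(20000), 0.8))
  lead_pos <- draw_positions(lead_inside, enhancers)
  k <- config$control_ratio + 1L
  ctrl_inside <- stats::runif(n * k) < p0
  ctrl_pos <- draw_positions(ctrl_inside, enhancers)
  ctrl_n_perfect <- rep(n_perfect, k)
  ctrl_n_loose <- rep(n_loose + as.integer(second), k)
  ctrl_block_size <- rep(block_size, k)
  rows <- list()
  pair_rows <- list()
  # GWAS lead blocks -------------------------------------------------
  lead_ids <- sprintf("rs%07d", seq_len(n))
  lead_block <- sprintf("gb%06d", seq_len(n))
  rows$lead <- data.frame(
    snp_id = lead_ids, chrom = lead_pos$chrom, pos = lead_pos$pos,
    p_assoc = 10^(-stats::runif(n, 10, 30)), trait = trait,
    category = category, maf = maf, gene_density = gene_density,
    dist_nearest_gene = dist_gene, ld_buddies = block_size - 1L,
    block_id = lead_block, is_haplotype = 0L, stringsAsFactors = FALSE)
  prox <- make_proxies(lead_ids, lead_block, lead_pos, lead_inside,
                       n_perfect, n_loose, block_size, maf, gene_density,
                       dist_gene, enhancers, prefix = "gp")
  rows$lead_prox <- prox$rows
  pair_rows$lead <- prox$pairs
  # secondary catalog SNPs sharing a lead's block --------------------
  si <- which(second)
  if (length(si) > 0) {
    spos <- draw_positions(lead_inside[si], enhancers)
    sids <- sprintf("rs2nd%05d", seq_along(si))
    rows$second <- data.frame(
      snp_id = sids, chrom = spos$chrom, pos = spos$pos,
      p_assoc = 10^(-stats::runif(length(si), 7.4, 9.5)),
      trait = trait[si], category = category[si], maf = maf[si],
      gene_density = gene_density[si], dist_nearest_gene = dist_gene[si],
      ld_buddies = block_size[si] - 1L, block_id = lead_block[si],
      is_haplotype = 0L, stringsAsFactors = FALSE)
    pair_rows$second <- data.frame(
      snp_a = lead_ids[si], snp_b = sids,
      r2 = stats::runif(length(si), 0.5, 0.9), stringsAsFactors = FALSE)
  }
  # control blocks (covariates perturbed within matching windows) ----
  ctrl_ids <- sprintf("ctrl%07d", seq_len(n * k))
  ctrl_block <- sprintf("cb%07d", seq_len(n * k))
  ctrl_maf <- pmin(0.5, pmax(0.01, rep(maf, k) +
                               stats::runif(n * k, -0.02, 0.02)))
  ctrl_gd <- rep(gene_density, k) * stats::runif(n * k, 0.85, 1.17)
  ctrl_dist <- round(rep(dist_gene, k) * stats::runif(n * k, 0.85, 1.17))
  rows$ctrl <- data.frame(
    snp_id = ctrl_ids, chrom = ctrl_pos$chrom, pos = ctrl_pos$pos,
    p_assoc = stats::runif(n * k, 0.06, 1), trait = "control",
    category = "control", maf = ctrl_maf, gene_density = ctrl_gd,
    dist_nearest_gene = ctrl_dist, ld_buddies = ctrl_block_size - 1L,
    block_id = ctrl_block, is_haplotype = 0L, stringsAsFactors = FALSE)
  cprox <- make_proxies(ctrl_ids, ctrl_block, ctrl_pos, ctrl_inside,
                        ctrl_n_perfect, ctrl_n_loose, ctrl_block_size,
                        ctrl_maf, ctrl_gd, ctrl_dist, enhancers,
                        prefix = "cp")
  rows$ctrl_prox <- cprox$rows
  pair_rows$ctrl <- cprox$pairs
  # catalog noise: sub-threshold and haplotype rows ------------------
  n_sub <- max(1L, round(0.03 * n))
  sub_inside <- stats::runif(n_sub) < p0
  sub_pos <- draw_positions(sub_inside, enhancers)
  rows$sub <- data.frame(
    snp_id = sprintf("rssub%05d", seq_len(n_sub)), chrom = sub_pos$chrom,
    pos = sub_pos$pos, p_assoc = 10^(-stats::runif(n_sub, 4, 7.2)),
    trait = paste0(rep_len(cats, n_sub), "_trait1"),
    category = rep_len(cats, n_sub), maf = stats::runif(n_sub, 0.05, 0.5),
    gene_density = stats::rlnorm(n_sub, log(5), 0.5),
    dist_nearest_gene = round(stats::rlnorm(n_sub, log(20000), 0.8)),
    ld_buddies = 0L, block_id = sprintf("sb%06d", seq_len(n_sub)),
    is_haplotype = 0L, stringsAsFactors = FALSE)
  n_hap <- max(1L, round(0.02 * n))
  hap_pos <- draw_positions(rep(FALSE, n_hap), enhancers)
  rows$hap <- data.frame(
    snp_id = sprintf("hap%05d", seq_len(n_hap)), chrom = hap_pos$chrom,
    pos = hap_pos$pos, p_assoc = 10^(-stats::runif(n_hap, 8, 12)),
    trait = paste0(rep_len(cats, n_hap), "_trait1"),
    category = rep_len(cats, n_hap), maf = stats::runif(n_hap, 0.05, 0.5),
    gene_density = stats::rlnorm(n_hap, log(5), 0.5),
    dist_nearest_gene = round(stats::rlnorm(n_hap, log(20000), 0.8)),
    ld_buddies = 0L, block_id = sprintf("hb%06d", seq_len(n_hap)),
    is_haplotype = 1L, stringsAsFactors = FALSE)
  snp_table <- do.call(rbind, rows)
  rownames(snp_table) <- NULL
  pairs <- do.call(rbind, pair_rows)
  if (is.null(pairs))
    pairs <- data.frame(snp_a = character(), snp_b = character(),
                        r2 = numeric())
  ld <- ld_reference(blocks = data.frame(snp_id = snp_table$snp_id,
                                         block_id = snp_table$block_id,
                                         stringsAsFactors = FALSE),
                     pairs = pairs)
  category_map <- unique(data.frame(trait = snp_table$trait,
                                    category = snp_table$category,
                                    stringsAsFactors = FALSE))
  list(snp_table = snp_table, ld = ld, category_map = category_map,
       truth = list(planted_category_or = or_map,
                    baseline_overlap = p0))
}

resolve_category_or <- function(planted, cats) {
  if (is.null(names(planted)))
    return(stats::setNames(rep_len(planted, length(cats)), cats))
  out <- stats::setNames(rep(1.0, length(cats)), cats)
  known <- intersect(names(planted), cats)
  out[known] <- planted[known]
  out
}

# Positions inside (weighted by width) or outside the enhancer set.
draw_positions <- function(inside, enhancers) {
  n <- length(inside)
  chrom <- character(n)
  pos <- numeric(n)
  wid <- enhancers$end - enhancers$start
  chrom_len <- tapply(enhancers$end, enhancers$chrom, max) + 1e6
  chroms <- names(chrom_len)
  n_in <- sum(inside)
  if (n_in > 0) {
    ei <- sample.int(nrow(enhancers), n_in, replace = TRUE,
                     prob = wid / sum(wid))
    chrom[inside] <- enhancers$chrom[ei]
    pos[inside] <- enhancers$start[ei] +
      floor(stats::runif(n_in) * wid[ei])
  }
  n_out <- n - n_in
  if (n_out > 0) {
    oc <- sample(chroms, n_out, replace = TRUE,
                 prob = as.numeric(chrom_len) / sum(chrom_len))
    op <- floor(stats::runif(n_out) * as.numeric(chrom_len[oc]))
    bad <- positions_in_intervals(oc, op, enhancers)
    while (any(bad)) {
      oc[bad] <- sample(chroms, sum(bad), replace = TRUE,
                        prob = as.numeric(chrom_len) / sum(chrom_len))
      op[bad] <- floor(stats::runif(sum(bad)) *
                         as.numeric(chrom_len[oc[bad]]))
      bad <- positions_in_intervals(oc, op, enhancers)
    }
    chrom[!inside] <- oc
    pos[!inside] <- op
  }
  list(chrom = chrom, pos = pos)
}

# Build proxy SNP rows and LD pair rows for a set of lead blocks.
# Perfect proxies (r2 = 1) inherit the lead's enhancer-overlap status;
# loose buddies (0.5 <= r2 < 0.95) are placed independently outside.
make_proxies <- function(lead_ids, lead_block, lead_pos, lead_inside,
                         n_perfect, n_loose, block_size, maf,
                         gene_density, dist_gene, enhancers, prefix) {
  li_perf <- rep(seq_along(lead_ids), n_perfect)
  li_loose <- rep(seq_along(lead_ids), n_loose)
  rows_list <- list()
  pairs_list <- list()
  if (length(li_perf) > 0) {
    ppos <- draw_positions(lead_inside[li_perf], enhancers)
    ids <- sprintf("%s_perf%07d", prefix, seq_along(li_perf))
    rows_list$perf <- data.frame(
      snp_id = ids, chrom = ppos$chrom, pos = ppos$pos,
      p_assoc = stats::runif(length(li_perf), 0.1, 1), trait = "none",
      category = "none", maf = maf[li_perf],
      gene_density = gene_density[li_perf],
      dist_nearest_gene = dist_gene[li_perf],
      ld_buddies = block_size[li_perf] - 1L,
      block_id = lead_block[li_perf], is_haplotype = 0L,
      stringsAsFactors = FALSE)
    pairs_list$perf <- data.frame(snp_a = lead_ids[li_perf], snp_b = ids,
                                  r2 = 1, stringsAsFactors = FALSE)
    # perfect proxies of the same lead are mutual perfect proxies
    dup <- which(n_perfect == 2)
    if (length(dup) > 0) {
      first <- match(dup, li_perf)
      pairs_list$perf2 <- data.frame(snp_a = ids[first],
                                     snp_b = ids[first + 1L], r2 = 1,
                                     stringsAsFactors = FALSE)
    }
  }
  if (length(li_loose) > 0) {
    lpos <- draw_positions(rep(FALSE, length(li_loose)), enhancers)
    ids <- sprintf("%s_loose%07d", prefix, seq_along(li_loose))
    rows_list$loose <- data.frame(
      snp_id = ids, chrom = lpos$chrom, pos = lpos$pos,
      p_assoc = stats::runif(length(li_loose), 0.1, 1), trait = "none",
      category = "none", maf = maf[li_loose],
      gene_density = gene_density[li_loose],
      dist_nearest_gene = dist_gene[li_loose],
      ld_buddies = block_size[li_loose] - 1L,
      block_id = lead_block[li_loose], is_haplotype = 0L,
      stringsAsFactors = FALSE)
    pairs_list$loose <- data.frame(
      snp_a = lead_ids[li_loose], snp_b = ids,
      r2 = stats::runif(length(li_loose), 0.5, 0.95),
      stringsAsFactors = FALSE)
  }
  list(rows = if (length(rows_list) > 0) do.call(rbind, rows_list) else NULL,
       pairs = if (length(pairs_list) > 0) do.call(rbind, pairs_list)
               else NULL)
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_chip()], [simulate_links()], [simulate_rna()] (with
#' shared participant effects), and [simulate_snp_panel()] planted
#' against the truth-regulated dual-mark regions. Fixing
#' `config$seed` fixes every output bit.
#'
#' @param config a [simulation_config()]
#' @return list of class `synthetic_study` with elements `config`,
#'   `regions`, `k27_peaks`, `k4_peaks`, `chip_counts`, `truth`,
#'   `links`, `gene_tss`, `rna_counts`, `gene_truth`, `snp_table`,
#'   `ld`, `category_map`, `snp_truth`
#' @export
simulate_study <- function(config = simulation_config()) {
  chip <- simulate_chip(config)
  lk <- simulate_links(config, chip$regions, chip$truth)
  rna <- simulate_rna(config, chip$truth, lk$links,
                      participant_effects = chip$participant_effects)
  planted_enh <- chip$regions[chip$truth$regulated, , drop = FALSE]
  if (nrow(planted_enh) == 0)
    planted_enh <- chip$regions[chip$truth$dual, , drop = FALSE]
  snp <- simulate_snp_panel(config, planted_enh)
  structure(list(config = config, regions = chip$regions,
                 k27_peaks = chip$k27_peaks, k4_peaks = chip$k4_peaks,
                 chip_counts = chip$chip_counts, truth = chip$truth,
                 links = lk$links, gene_tss = lk$gene_tss,
                 rna_counts = rna$rna_counts, gene_truth = rna$gene_truth,
                 snp_table = snp$snp_table, ld = snp$ld,
                 category_map = snp$category_map, snp_truth = snp$truth),
            class = "synthetic_study")
}

#' Write a synthetic study to a fixture directory
#'
#' Emits the same BED/TSV dialects the pipeline reads, plus a truth
#' manifest: per-sample peak BEDs, counts and design TSVs, link TSV,
#' SNP TSV (1-based positions on write), LD pair and block TSVs, a
#' trait-to-category map, and truth tables.
#'
#' @param study a [simulate_study()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("k27_peaks", "k4_peaks"))
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  for (s in names(study$k27_peaks))
    write_bed(study$k27_peaks[[s]], file.path(dir, "k27_peaks",
                                              paste0(s, ".bed")))
  for (s in names(study$k4_peaks))
    write_bed(study$k4_peaks[[s]], file.path(dir, "k4_peaks",
                                             paste0(s, ".bed")))
  write_tsv <- function(x, f)
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  write_counts <- function(cm, f, fd) {
    write_tsv(data.frame(feature_id = rownames(cm$counts), cm$counts,
                         check.names = FALSE), f)
    write_tsv(cm$design, fd)
  }
  write_counts(study$chip_counts, "chip_counts.tsv", "chip_design.tsv")
  write_counts(study$rna_counts, "rna_counts.tsv", "rna_design.tsv")
  write_tsv(study$links, "links.tsv")
  snp_out <- study$snp_table
  snp_out$pos <- snp_out$pos + 1  # external dialect is 1-based
  write_tsv(snp_out, "snps.tsv")
  write_tsv(as.data.frame(study$ld$pairs[study$ld$pairs$a <
                                           study$ld$pairs$b, ]),
            "ld_pairs.tsv")
  write_tsv(data.frame(snp_id = names(study$ld$block_of),
                       block_id = unname(study$ld$block_of)),
            "ld_blocks.tsv")
  write_tsv(study$category_map, "category_map.tsv")
  write_tsv(study$truth, "truth_regions.tsv")
  write_tsv(study$gene_truth, "truth_genes.tsv")
  write_bed(study$regions, file.path(dir, "regions.bed"))
  invisible(dir)
}
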