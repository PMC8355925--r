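test_that("fixing the seed fixes every output bit", {
  cfg <- simulation_config(seed = 17, n_regions = 120, n_genes = 80,
                           n_snps = 300)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$chip_counts$counts, s2$chip_counts$counts)
  expect_identical(s1$rna_counts$counts, s2$rna_counts$counts)
  expect_identical(s1$k27_peaks, s2$k27_peaks)
  expect_identical(s1$snp_table, s2$snp_table)
  expect_identical(s1$links, s2$links)
  # a different seed changes the data
  s3 <- simulate_study(simulation_config(seed = 18, n_regions = 120,
                                         n_genes = 80, n_snps = 300))
  expect_false(identical(s1$chip_counts$counts, s3$chip_counts$counts))
})

test_that("planted-effect bookkeeping follows the rounding rule", {
  cfg <- simulation_config(seed = 2, n_regions = 1000, frac_dual_mark = 1,
                           frac_regulated = 0.1)
  ch <- simulate_chip(cfg)
  expect_equal(sum(ch$truth$regulated), 100)
  expect_true(all(ch$truth$planted_logfc[!ch$truth$regulated] == 0))
  expect_true(all(ch$truth$planted_logfc[ch$truth$regulated] != 0))
  # null config: no regulated regions, zero planted effects
  ch0 <- simulate_chip(simulation_config(seed = 2, n_regions = 200,
                                         frac_regulated = 0))
  expect_equal(sum(ch0$truth$regulated), 0)
  expect_true(all(ch0$truth$planted_logfc == 0))
  expect_error(simulation_config(n_regions = 10, frac_dual_mark = 0.01),
               "at least 1")
})

test_that("NB counts match the analytic marginal mean within 2%", {
  cfg <- simulation_config(seed = 4, n_regions = 5000, n_participants = 2,
                           frac_regulated = 0, participant_sd = 0,
                           library_size_range = c(3e5, 3e5))
  ch <- simulate_chip(cfg)
  # with no effects, E[count_rs] = lib_s * w_r; summing over regions
  # gives E[colSums] = lib (weights sum to 1)
  expect_equal(unname(colSums(ch$chip_counts$counts)),
               ch$chip_counts$design$library_size, tolerance = 0.02)
})

test_that("per-sample peaks jitter consensus edges by at most 10% of width", {
  cfg <- simulation_config(seed = 6, n_regions = 150)
  ch <- simulate_chip(cfg)
  w <- ch$regions$end - ch$regions$start
  for (s in ch$k27_peaks[1:3]) {
    expect_true(all(abs(s$start - ch$regions$start) <= 0.1 * w + 1))
    expect_true(all(abs(s$end - ch$regions$end) <= 0.1 * w + 1))
  }
})

test_that("gene effects follow the score-weighted coupling formula", {
  cfg <- simulation_config(seed = 8, n_genes = 5, coupling = 0.5,
                           gene_noise_sd = 0)
  truth <- data.frame(region_id = c("r1", "r2"), dual = TRUE,
                      regulated = TRUE, planted_logfc = c(1.0, -2.0))
  links <- data.frame(chrom = "chr1", start = 0, end = 10,
                      gene_id = c("gene_00001", "gene_00002",
                                  "gene_00002"),
                      score = c(1, 3, 1),
                      distance = 0, enhancer_id = c("r1", "r1", "r2"))
  rna <- simulate_rna(cfg, truth, links)
  gt <- rna$gene_truth
  # single link: coupling * logFC
  expect_equal(gt$planted_logfc[1], 0.5 * 1.0)
  # two links: coupling * weighted mean (3*1 + 1*(-2)) / 4 = 0.125
  expect_equal(gt$planted_logfc[2], 0.5 * (3 * 1 - 2) / 4)
  # unlinked genes carry no effect when noise is off
  expect_true(all(gt$planted_logfc[3:5] == 0))
  # zero coupling decouples gene effects from enhancer truth
  cfgd <- simulation_config(seed = 12, n_regions = 600, n_genes = 600,
                            coupling = 0, gene_noise_sd = 0.3)
  chd <- simulate_chip(cfgd)
  lkd <- simulate_links(cfgd, chd$regions, chd$truth)
  rnad <- simulate_rna(cfgd, chd$truth, lkd$links)
  # recompute the raw link-weighted enhancer truth independently
  raw <- tapply(seq_len(nrow(lkd$links)), lkd$links$gene_id, function(i) {
    fc <- chd$truth$planted_logfc[match(lkd$links$enhancer_id[i],
                                        chd$truth$region_id)]
    sum(lkd$links$score[i] * fc) / sum(lkd$links$score[i])
  })
  gi <- match(names(raw), rnad$gene_truth$gene_id)
  expect_lt(abs(cor(rnad$gene_truth$planted_logfc[gi],
                    as.numeric(raw))), 0.1)
  # full coupling, zero noise: monotone map onto the coupled effect
  cfgm <- simulation_config(seed = 13, n_regions = 300, n_genes = 300,
                            coupling = 1, gene_noise_sd = 0)
  chm <- simulate_chip(cfgm)
  lkm <- simulate_links(cfgm, chm$regions, chm$truth)
  rnam <- simulate_rna(cfgm, chm$truth, lkm$links)
  expect_equal(cor(rnam$gene_truth$planted_logfc,
                   rnam$gene_truth$coupled_logfc, method = "spearman"), 1)
})

test_that("SNP panel bookkeeping is self-consistent and matchable", {
  cfg <- simulation_config(seed = 19, n_regions = 150, n_snps = 500)
  ch <- simulate_chip(cfg)
  sp <- simulate_snp_panel(cfg, ch$regions[ch$truth$dual, ])
  tab <- sp$snp_table
  # listed LD buddies equal the block bookkeeping count
  bs <- table(tab$block_id)
  expect_true(all(tab$ld_buddies == as.integer(bs[tab$block_id]) - 1L))
  # r2 lookups: symmetric, unit diagonal, zero across blocks
  two <- tab$snp_id[1:2]
  expect_equal(ld_r2(sp$ld, two[1], two[1]), 1)
  expect_equal(ld_r2(sp$ld, two[1], two[2]),
               ld_r2(sp$ld, two[2], two[1]))
  # every GWAS lead admits >= 2 in-window controls in the pool
  leads <- filter_catalog(tab)
  leads <- leads[grepl("^rs0", leads$snp_id), ]
  pool <- tab[tab$trait == "control", ]
  w <- matching_windows()
  n_elig <- vapply(seq_len(nrow(leads)), function(i)
    sum(enhancertrain:::matching_eligible(leads[i, ], pool, w)), 1L)
  expect_true(all(n_elig >= 2))
  expect_error(simulate_snp_panel(cfg, genomic_intervals(character(),
                                                         numeric(),
                                                         numeric())),
               "nonempty")
})

test_that("null planting yields near-unit odds ratios", {
  cfg <- simulation_config(seed = 23, n_regions = 400, n_snps = 6000,
                           n_categories = 1, planted_category_or = 1.0,
                           baseline_overlap = 0.05)
  ch <- simulate_chip(cfg)
  enh <- ch$regions[ch$truth$dual, ][1:80, ]
  sp <- simulate_snp_panel(cfg, enh)
  leads <- sp$snp_table[grepl("^rs0", sp$snp_table$snp_id), ]
  ctrls <- sp$snp_table[sp$snp_table$trait == "control", ]
  in_enh <- function(x) positions_in_intervals(x$chrom, x$pos, enh)
  r <- enrichment_test(as.integer(in_enh(leads)),
                       as.integer(in_enh(ctrls)))
  expect_gt(r$ci_high, 1.0)
  expect_lt(r$ci_low, 1.0)
})

test_that("write_study emits readable fixtures in the pipeline dialects", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 29, n_regions = 60, n_genes = 40,
                           n_snps = 150)
  st <- simulate_study(cfg)
  write_study(st, dir)
  peaks <- read_bed(file.path(dir, "k27_peaks", "P1_pre.bed"))
  expect_equal(nrow(peaks), 60)
  snps <- read_snp_table(file.path(dir, "snps.tsv"))
  expect_equal(snps$pos, st$snp_table$pos)  # 1-based on disk, restored
  links <- read_links(file.path(dir, "links.tsv"))
  expect_equal(nrow(links), nrow(st$links))
  counts <- utils::read.delim(file.path(dir, "chip_counts.tsv"),
                              check.names = FALSE)
  expect_equal(as.matrix(counts[, -1]),
               st$chip_counts$counts, ignore_attr = TRUE)
})
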