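snp_to_interval <- function(s) genomic_intervals(s$chrom, s$pos, s$pos + 1)

snp_row <- function(id, p, pos = 100, block = "b1", trait = "t",
                    maf = 0.3, gd = 5, dist = 1000, buddies = 0,
                    hap = 0L, chrom = "chr1") {
  data.frame(snp_id = id, chrom = chrom, pos = pos, p_assoc = p,
             trait = trait, maf = maf, gene_density = gd,
             dist_nearest_gene = dist, ld_buddies = buddies,
             block_id = block, is_haplotype = hap,
             stringsAsFactors = FALSE)
}

test_that("filter_catalog applies strict genome-wide significance and dedup rules", {
  raw <- rbind(snp_row("rs1", 4e-8), snp_row("rs2", 6e-8),
               snp_row("rs3", 1e-9), snp_row("rs3", 1e-12),
               snp_row("rs4", 1e-10, hap = 1L))
  out <- filter_catalog(raw)
  expect_setequal(out$snp_id, c("rs1", "rs3"))
  expect_equal(out$p_assoc[out$snp_id == "rs3"], 1e-12)
  # same snp under a different trait survives separately
  raw2 <- rbind(snp_row("rs9", 1e-9, trait = "a"),
                snp_row("rs9", 1e-10, trait = "b"))
  expect_equal(nrow(filter_catalog(raw2)), 2)
})

test_that("ld_clump reproduces the greedy hand example and degenerate cases", {
  snps <- rbind(snp_row("A", 1e-10, pos = 10, block = "b1"),
                snp_row("B", 1e-9, pos = 20, block = "b1"),
                snp_row("C", 1e-8, pos = 30, block = "b2"))
  ld <- ld_reference(snps[, c("snp_id", "block_id")],
                     data.frame(snp_a = "A", snp_b = "B", r2 = 0.6))
  out <- ld_clump(snps, ld)
  expect_setequal(out$snp_id, c("A", "C"))
  # all pairwise r2 = 0: input returned unchanged (sorted by position)
  ld0 <- ld_reference(snps[, c("snp_id", "block_id")],
                      data.frame(snp_a = "A", snp_b = "B", r2 = 0.1))
  expect_equal(nrow(ld_clump(snps, ld0)), 3)
  expect_equal(nrow(ld_clump(snps[1, ], ld)), 1)
  expect_error(ld_clump(rbind(snps, snp_row("Z", 1e-9, block = "zz")), ld),
               "missing from LD reference: Z")
})

test_that("ld_clump matches the brute-force oracle and is order-invariant", {
  for (seed in 1:30) {
    panel <- random_ld_panel(seed)
    kept <- ld_clump(panel$snps, panel$ld)
    expect_true(clump_is_valid(kept$snp_id, panel$snps, panel$ld))
    perm <- panel$snps[sample(nrow(panel$snps)), ]
    expect_identical(ld_clump(perm, panel$ld)$snp_id, kept$snp_id)
  }
})

test_that("match_controls enforces all covariate windows with shortfall fallback", {
  index <- snp_row("idx", 1e-9, maf = 0.30, gd = 10, dist = 10000,
                   buddies = 2)
  pool <- rbind(
    snp_row("c1", 0.5, maf = 0.34, gd = 10, dist = 10000, buddies = 2),
    snp_row("c2", 0.5, maf = 0.36, gd = 10, dist = 10000, buddies = 2),
    snp_row("c3", 0.5, maf = 0.30, gd = 16, dist = 10000, buddies = 2),
    snp_row("c4", 0.5, maf = 0.30, gd = 10, dist = 4000, buddies = 2),
    snp_row("c5", 0.5, maf = 0.30, gd = 10, dist = 10000, buddies = 4))
  m <- match_controls(index, pool, k = 2, rng_seed = 7)
  expect_equal(m$snp_id, "c1")  # only eligible candidate
  expect_true(attr(m, "shortfall"))
  pool2 <- rbind(pool, snp_row("c6", 0.5, maf = 0.26, gd = 14,
                               dist = 14000, buddies = 3))
  m2 <- match_controls(index, pool2, k = 2, rng_seed = 7)
  expect_setequal(m2$snp_id, c("c1", "c6"))
  expect_false(attr(m2, "shortfall"))
  expect_error(match_controls(index, pool[0, ]), "empty")
})

test_that("batch matching returns in-window controls for every index", {
  cfg <- simulation_config(seed = 21, n_regions = 100, n_snps = 400)
  ch <- simulate_chip(cfg)
  sp <- simulate_snp_panel(cfg, ch$regions[ch$truth$dual, ])
  clumped <- ld_clump(filter_catalog(sp$snp_table), sp$ld)
  pool <- sp$snp_table[sp$snp_table$trait == "control", ]
  ctrl <- match_controls_all(clumped, pool, k = 2, rng_seed = 3)
  expect_length(attr(ctrl, "shortfall_ids"), 0)
  expect_equal(nrow(ctrl), 2 * nrow(clumped))
  # verify every matched control against its index's windows
  w <- matching_windows()
  ii <- match(ctrl$index_snp, clumped$snp_id)
  expect_true(all(abs(ctrl$maf - clumped$maf[ii]) <= w$maf_abs))
  for (cov in c("gene_density", "dist_nearest_gene", "ld_buddies")) {
    expect_true(all(ctrl[[cov]] >= 0.5 * clumped[[cov]][ii] &
                      ctrl[[cov]] <= 1.5 * clumped[[cov]][ii]))
  }
  # per-index draws are without replacement
  expect_false(any(tapply(ctrl$snp_id, ctrl$index_snp,
                          function(x) anyDuplicated(x) > 0)))
})

test_that("dedup_controls removes duplicates within but not across categories", {
  ctrl <- data.frame(snp_id = c("c1", "c1", "c2", "c1"),
                     category = c("cat1", "cat1", "cat1", "cat2"),
                     index_pos = c(5, 10, 1, 3))
  out <- dedup_controls(ctrl)
  expect_equal(sum(out$snp_id == "c1" & out$category == "cat1"), 1)
  # first occurrence by index position order is kept
  expect_equal(out$index_pos[out$snp_id == "c1" & out$category == "cat1"], 5)
  expect_equal(sum(out$snp_id == "c1" & out$category == "cat2"), 1)
  expect_equal(nrow(dedup_controls(ctrl[c(1, 3), ])), 2)
})

test_that("expand_tags keeps only perfect proxies at threshold 1", {
  snps <- rbind(snp_row("L", 1e-9, block = "b1", pos = 10),
                snp_row("T1", 0.5, block = "b1", pos = 20),
                snp_row("T2", 0.5, block = "b1", pos = 30),
                snp_row("X", 0.5, block = "b2", pos = 40))
  ld <- ld_reference(snps[, c("snp_id", "block_id")],
                     data.frame(snp_a = c("L", "L"),
                                snp_b = c("T1", "T2"),
                                r2 = c(1.0, 0.99)))
  tags <- expand_tags(snps[1, ], ld, snps)
  expect_setequal(tags$snp_id, c("L", "T1"))
  # no partners: singleton
  tags2 <- expand_tags(snps[4, ], ld, snps)
  expect_equal(tags2$snp_id, "X")
})

test_that("block_overlap collapses any number of in-enhancer tags to one", {
  enh <- toy_enhancers()
  lead <- snp_row("L", 1e-9, pos = 50)    # outside
  tags <- rbind(lead,
                snp_row("T1", 0.5, pos = 150),
                snp_row("T2", 0.5, pos = 151),
                snp_row("T3", 0.5, pos = 152))
  expect_equal(block_overlap(lead, tags, enh), 1L)
  expect_equal(block_overlap(lead, lead, enh), 0L)
  expect_error(block_overlap(lead, tags[-1, ], enh), "include the lead")
  # monotone: adding intervals can only turn 0 into 1
  expect_equal(block_overlap(
    lead, lead,
    rbind(enh[, c("chrom", "start", "end")],
          snp_to_interval(lead))), 1L)
})

test_that("enrichment_test equals the 2x2 cross-product OR and behaves under swaps", {
  flags <- function(k, n) c(rep(1, k), rep(0, n - k))
  r <- enrichment_test(flags(10, 100), flags(20, 200))
  expect_equal(r$or_estimate, 1.0, tolerance = 1e-7)
  r2 <- enrichment_test(flags(5, 10), flags(2, 10))
  expect_equal(r2$or_estimate, 4.0, tolerance = 1e-7)
  # cross-product equality to >= 6 significant digits
  r3 <- enrichment_test(flags(33, 1295), flags(42, 2345))
  expect_equal(r3$or_estimate, (33 * (2345 - 42)) / (42 * (1295 - 33)),
               tolerance = 1e-7)
  # swapping case/control maps OR to 1/OR with unchanged p
  r3s <- enrichment_test(flags(42, 2345), flags(33, 1295))
  expect_equal(r3s$or_estimate, 1 / r3$or_estimate, tolerance = 1e-7)
  expect_equal(r3s$p, r3$p, tolerance = 1e-9)
  # degenerate margins are flagged
  expect_true(enrichment_test(flags(0, 10), flags(0, 10))$degenerate)
  expect_true(enrichment_test(flags(0, 10), flags(2, 10))$degenerate)
})

test_that("run_enrichment tags categories and contrasts enhancer sets", {
  cfg <- simulation_config(seed = 41, n_regions = 200, n_snps = 600,
                           n_categories = 3, planted_category_or = 3.0,
                           baseline_overlap = 0.05)
  ch <- simulate_chip(cfg)
  enh <- ch$regions[ch$truth$dual, ][1:50, ]
  sp <- simulate_snp_panel(cfg, enh)
  clumped <- ld_clump(filter_catalog(sp$snp_table), sp$ld)
  pool <- sp$snp_table[sp$snp_table$trait == "control", ]
  ctrl <- dedup_controls(match_controls_all(clumped, pool, k = 2,
                                            rng_seed = 5))
  far <- genomic_intervals("chr4", 9e6, 9.1e6)  # no SNPs land here
  er <- run_enrichment(clumped, ctrl, enh, sp$ld, sp$snp_table,
                       nonregulated = far, min_category_n = 0)
  expect_setequal(unique(er$enhancer_set), c("regulated", "nonregulated"))
  expect_setequal(unique(er$category), c("combined", trait_categories(3)))
  comb <- er[er$category == "combined" & er$enhancer_set == "regulated", ]
  expect_gt(comb$or_estimate, 1)  # planted enrichment shows up
  expect_true(all(er$n_case_overlap <= er$n_case))
  # empty contrast set has zero overlaps -> degenerate rows
  expect_true(all(er$degenerate[er$enhancer_set == "nonregulated"]))
})
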