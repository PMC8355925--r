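make_links <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), gene_id = r[[4]],
               score = as.numeric(r[[5]]),
               distance = as.numeric(r[[6]]), stringsAsFactors = FALSE)))
}

test_that("attach_links connects by single-nucleotide overlap, keeping duplicates", {
  enh <- genomic_intervals("chr1", 100, 200, name = "e1")
  lk <- make_links(list("chr1", 150, 160, "geneA", 0.9, 1000),
                   list("chr1", 200, 210, "geneB", 0.8, 2000),  # abuts
                   list("chr1", 120, 130, "geneA", 0.5, 1500))
  att <- attach_links(enh, lk)
  expect_equal(nrow(att), 2)  # both geneA links retained, geneB not
  expect_setequal(att$gene_id, c("geneA", "geneA"))
  expect_equal(attr(att, "enhancer_ids"), "e1")
})

test_that("link_statistics collapses duplicate pairs and averages correctly", {
  enh <- genomic_intervals("chr1", 100, 200, name = "e1")
  lk <- make_links(list("chr1", 150, 160, "geneA", 0.9, 1000),
                   list("chr1", 120, 130, "geneB", 0.5, 3000))
  st <- link_statistics(attach_links(enh, lk))
  expect_equal(st$mean_enhancers_per_gene, 1.0)
  expect_equal(st$mean_genes_per_enhancer, 2.0)
  expect_equal(st$mean_distance_bp, 2000)
  # duplicate (enhancer, gene) rows collapse before counting
  lk_dup <- rbind(lk, lk[1, ])
  st2 <- link_statistics(attach_links(enh, lk_dup))
  expect_equal(st2$mean_genes_per_enhancer, 2.0)
  empty <- attach_links(genomic_intervals("chr2", 1, 10), lk)
  expect_error(link_statistics(empty), "no attached links")
})

test_that("strongest_gene takes the max score with lexicographic tie-break", {
  enh <- genomic_intervals("chr1", 100, 200, name = "e1")
  att <- attach_links(enh, make_links(
    list("chr1", 150, 160, "A", 0.9, 1),
    list("chr1", 150, 160, "B", 0.5, 1)))
  expect_equal(strongest_gene(att)$gene_id, "A")
  att_tie <- attach_links(enh, make_links(
    list("chr1", 150, 160, "B", 0.7, 1),
    list("chr1", 150, 160, "A", 0.7, 1)))
  expect_equal(strongest_gene(att_tie)$gene_id, "A")
  att_one <- attach_links(enh, make_links(list("chr1", 150, 160, "Z", 0.1, 1)))
  expect_equal(strongest_gene(att_one)$gene_id, "Z")
  expect_equal(nrow(strongest_gene(att_one[0, ])), 0)
})

test_that("promoter_groups implements the four-group definition and partitions genes", {
  enh <- genomic_intervals(rep("chr1", 3), c(100, 300, 500),
                           c(200, 400, 600), name = c("up1", "dn1", "nr1"))
  lk <- make_links(list("chr1", 150, 160, "gUp", 1, 1),
                   list("chr1", 350, 360, "gDown", 1, 1),
                   list("chr1", 150, 160, "gBoth", 1, 1),
                   list("chr1", 350, 360, "gBoth", 1, 1),
                   list("chr1", 550, 560, "gNone", 1, 1),
                   list("chr1", 550, 560, "gUp2", 1, 1),
                   list("chr1", 150, 160, "gUp2", 1, 1))
  att <- attach_links(enh, lk)
  grp <- promoter_groups(att, up = "up1", down = "dn1")
  g <- setNames(as.character(grp$group), grp$gene_id)
  expect_equal(g[["gUp"]], "Up")
  expect_equal(g[["gDown"]], "Down")
  expect_equal(g[["gBoth"]], "Both")
  expect_equal(g[["gNone"]], "None")
  expect_equal(g[["gUp2"]], "Up")  # regulated link dominates unregulated
  # partition: one group per linked gene
  expect_equal(nrow(grp), length(unique(att$gene_id)))
  expect_error(promoter_groups(att, up = "up1", down = "up1"), "disjoint")
})

test_that("ecdf_shift matches the two-sample KS oracle", {
  same <- ecdf_shift(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$ks_D, 0)
  expect_equal(same$p, 1)
  expect_equal(same$direction, 0)
  sep <- ecdf_shift(c(1, 2), c(3, 4))
  expect_equal(sep$ks_D, 1)
  expect_equal(sep$direction, -1)
  set.seed(3)
  x <- rnorm(500)
  sh <- ecdf_shift(x + 0.5, x)
  expect_equal(sh$direction, 1)
  expect_lt(sh$p, 0.01)
  expect_error(ecdf_shift(numeric(0), 1), "nonempty")
})

test_that("concordance correlation matches hand-computed Pearson values", {
  mk_res <- function(ids, fc, q = 0.05)
    data.frame(feature_id = ids, logFC = fc, p = q, q = q)
  enh <- genomic_intervals(rep("chr1", 3), c(0, 1000, 2000),
                           c(500, 1500, 2500), name = c("e1", "e2", "e3"))
  lk <- make_links(list("chr1", 100, 110, "g1", 1, 1),
                   list("chr1", 1100, 1110, "g2", 1, 1),
                   list("chr1", 2100, 2110, "g3", 1, 1))
  att <- attach_links(enh, lk)
  # perfect concordance / anti-concordance
  er <- mk_res(c("e1", "e2", "e3"), c(1, 2, -1))
  expect_equal(activity_expression_concordance(
    er, mk_res(c("g1", "g2", "g3"), c(1, 2, -1)), att)$r, 1)
  expect_equal(activity_expression_concordance(
    er, mk_res(c("g1", "g2", "g3"), c(-1, -2, 1)), att)$r, -1)
  # frozen value from the sum formulas: 48 / sqrt(42 * 78)
  cc <- activity_expression_concordance(
    er, mk_res(c("g1", "g2", "g3"), c(2, 1, -2)), att)
  expect_equal(cc$r, 48 / sqrt(42 * 78), tolerance = 1e-10)
  expect_equal(cc$r, 0.8386, tolerance = 1e-4)
  expect_equal(cc$n_pairs, 3)
  # concordant pairs need both significant and same sign
  gr <- mk_res(c("g1", "g2", "g3"), c(2, -1, -2), q = c(0.05, 0.05, 0.5))
  cs <- activity_expression_concordance(er, gr, att)$concordant_significant
  expect_equal(cs$enhancer_id, "e1")
  # fewer than 3 pairs: undefined correlation sentinel
  small <- activity_expression_concordance(
    er, mk_res("g1", 1), att)
  expect_true(is.na(small$r))
})
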