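norm_from <- function(cpm_mat, sheet) {
  # NormalizedCounts with prescribed CPM, for correlation tests
  structure(list(cpm = cpm_mat, tmm_factors = rep(1, ncol(cpm_mat)),
                 lib_sizes = rep(1e6, ncol(cpm_mat)), samples = sheet),
            class = "NormalizedCounts")
}

test_that("CpG-gene correlation handles monotone, flat and anti-monotone profiles", {
  sheet <- make_sheet("3A/targeting", n_rep = 5)
  beta_vals <- rbind(seq(0.1, 0.5, length.out = 5),   # increasing
                     rep(0.4, 5),                      # constant
                     seq(0.5, 0.1, length.out = 5))    # decreasing
  b <- make_beta(beta_vals, c(100L, 200L, 300L), sheet)
  cpm <- matrix(c(1, 3, 7, 20, 60), 1)[rep(1, 2), ]
  rownames(cpm) <- c("geneA", "geneB")
  colnames(cpm) <- sheet$sample_id
  expr <- norm_from(cpm, sheet)
  pairs <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                      gene = c("geneA", "geneA", "geneB"))
  res <- cpg_gene_correlation(b, expr, pairs, method = "spearman")
  expect_equal(res$r[1], 1)                     # perfect monotone
  expect_true(res$skipped[2])
  expect_match(res$reason[2], "zero variance")
  expect_equal(res$r[3], -1)
  # exact permutation p for n = 5 perfect anti-correlation: enumerate 120 ranks
  x <- beta_vals[3, ]; y <- cpm[2, ]
  expect_equal(res$p[3], spearman_exact_p(x, y), tolerance = 1e-10)
  expect_true(res$significant[3])
})

test_that("correlation p-values use the exact permutation null for small n", {
  set.seed(5)
  sheet <- make_sheet("3A/targeting", n_rep = 6)
  for (i in 1:8) {
    bv <- matrix(runif(6), 1)
    cpm <- matrix(runif(6, 1, 100), 1, dimnames = list("g", sheet$sample_id))
    b <- make_beta(bv, 100L, sheet)
    res <- cpg_gene_correlation(b, norm_from(cpm, sheet),
                                data.frame(chrom = "chr1", pos = 100L, gene = "g"),
                                method = "spearman")
    expect_equal(res$p, spearman_exact_p(bv[1, ], cpm[1, ]), tolerance = 1e-10)
  }
})

test_that("Spearman correlation is invariant under monotone transforms", {
  set.seed(14)
  sheet <- make_sheet("3A/targeting", n_rep = 8)
  bv <- matrix(runif(8), 1)
  cpm <- matrix(runif(8, 1, 100), 1, dimnames = list("g", sheet$sample_id))
  pairs <- data.frame(chrom = "chr1", pos = 100L, gene = "g")
  r1 <- cpg_gene_correlation(make_beta(bv, 100L, sheet),
                             norm_from(cpm, sheet), pairs, "spearman")$r
  r2 <- cpg_gene_correlation(make_beta(bv^3, 100L, sheet),
                             norm_from(exp(cpm / 30), sheet), pairs, "spearman")$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("DMR-gene mapping uses promoter window and gene body, DEG gate applies", {
  genes <- region_annotation("chr1", c(10000L, 10150L, 40000L),
                             c(12000L, 13000L, 45000L),
                             c("gA", "gB", "gC"), "gene")
  dmr <- data.frame(chrom = "chr1", start = 9000L, end = 9300L, n_cpgs = 3L,
                    direction = "hyper", mean_delta = 0.2)
  dmr$cpg_positions <- list(c(9000L, 9100L, 9299L))
  degs <- data.frame(gene = c("gA", "gB", "gC"),
                     log2fc = c(-1.5, 0.5, 2), p = NA, p_adj = NA,
                     is_deg = c(TRUE, FALSE, TRUE))
  # DMR at 9000-9300 is inside gA's promoter (-1500/+500 of 10000) and gB's
  # (-1500 of 10150); only gA is a DEG
  hits <- intersect_dmr_deg(dmr, degs, genes)
  expect_equal(hits$gene, "gA")
  expect_equal(hits$mapping_rule, "promoter")
  expect_equal(hits$log2fc, -1.5)

  # with both genes as DEGs, both candidate mappings are reported
  degs$is_deg <- c(TRUE, TRUE, TRUE)
  hits2 <- intersect_dmr_deg(dmr, degs, genes)
  expect_equal(sort(hits2$gene), c("gA", "gB"))

  # a DMR inside a gene body maps by the body rule
  dmr_body <- dmr
  dmr_body$start <- 11000L; dmr_body$end <- 11200L
  dmr_body$cpg_positions <- list(c(11000L, 11100L))
  hits3 <- intersect_dmr_deg(dmr_body, degs, genes)
  expect_true("body" %in% hits3$mapping_rule[hits3$gene == "gA"])

  # count bound: DMR-DEGs never exceed mapped DMRs or DEGs
  expect_lte(nrow(hits2), sum(degs$is_deg) * nrow(dmr))
})

test_that("chromatin-state enrichment assigns by midpoint and matches the exact tail", {
  states <- region_annotation("chr1", c(0L, 1000L), c(1000L, 10000L),
                              c("Active TSS", "Quiescent"), "chromatin_state")
  dmr <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  res <- chromhmm_enrichment(dmr, states,
                             data.frame(chrom = "chr1", pos = c(50L, 1500L, 2500L)))
  expect_equal(res$n_in_query[res$state == "Active TSS"], 1)

  # worked 2x2: [[10, 90], [100, 9900]] -> OR 11, p equals the exact
  # hypergeometric tail sum
  q <- data.frame(chrom = "chr1",
                  start = c(rep(100L, 10), rep(2000L, 90)),
                  end = c(rep(200L, 10), rep(2100L, 90)))
  bg <- data.frame(chrom = "chr1", pos = c(rep(500L, 100), rep(5000L, 9900)))
  res2 <- chromhmm_enrichment(q, states, bg)
  row <- res2[res2$state == "Active TSS", ]
  expect_equal(row$odds_ratio, 11.0)
  expect_equal(row$direction, "enriched")
  # two-sided Fisher p from the oracle: sum of hypergeometric atoms <= observed
  # margins: 100 query draws from 110 in-state + 9990 out-of-state elements
  atoms <- dhyper(0:100, 110, 9990, 100)
  p_oracle <- sum(atoms[atoms <= dhyper(10, 110, 9990, 100) * (1 + 1e-7)])
  expect_equal(row$p, p_oracle, tolerance = 1e-8)

  # a midpoint in a segmentation gap lands in Unannotated
  far <- data.frame(chrom = "chr1", start = 50000L, end = 50100L)
  res3 <- chromhmm_enrichment(far, states, bg)
  expect_equal(res3$n_in_query[res3$state == "Unannotated"], 1)
})

test_that("predicted off-target overlap fractions behave and shrink with thresholds", {
  set.seed(10)
  predicted <- region_annotation("chr1", seq(0L, 990L * 100L, 1000L)[1:100],
                                 seq(0L, 990L * 100L, 1000L)[1:100] + 500L,
                                 c(sprintf("g%02d", 1:50), rep(".", 50)),
                                 "offtarget_locus")
  delta <- data.frame(chrom = "chr1", pos = seq(250L, 99250L, 1000L),
                      delta = c(rep(0.2, 2), rep(0.01, 98)))
  degs <- data.frame(gene = sprintf("g%02d", 1:50),
                     log2fc = c(rep(1, 5), rep(0.01, 45)),
                     p = NA, p_adj = NA, is_deg = FALSE)
  out <- predicted_offtarget_overlap(predicted, delta, degs,
                                     beta_thresh = 0.05, logfc_thresh = 0.05)
  expect_equal(out$n_predicted, 100L)
  expect_equal(out$frac_meth_pct, 2)
  expect_equal(out$n_expr, 5L)
  expect_equal(out$frac_expr_pct, 10)      # 5 of the 50 gene-linked loci
  # raising thresholds is monotone non-increasing
  for (bt in c(0.1, 0.25, 0.5)) {
    out2 <- predicted_offtarget_overlap(predicted, delta, degs, bt, 2)
    expect_lte(out2$n_meth, out$n_meth)
    expect_lte(out2$n_expr, out$n_expr)
  }
  empty <- predicted_offtarget_overlap(predicted[0, ], delta, degs)
  expect_true(empty$empty)
})

test_that("overrepresentation analysis matches the hypergeometric tail and flags extremes", {
  universe <- sprintf("u%03d", 1:200)
  sets <- list(hit = universe[1:20], none = c("x1", "x2"),
               part = universe[15:44])
  query <- universe[1:20]
  res <- ora(sets, query, universe)
  expect_true(res$skipped[res$set == "none"])
  hit <- res[res$set == "hit", ]
  expect_equal(hit$n_overlap, 20)
  expect_equal(hit$p, hyper_tail_p(20, 20, 200, 20), tolerance = 1e-12)
  part <- res[res$set == "part", ]
  expect_equal(part$n_overlap, 6)
  expect_equal(part$p, hyper_tail_p(6, 30, 200, 20), tolerance = 1e-12)
  expect_lt(hit$p, part$p)
  expect_error(ora(sets, c(query, "alien"), universe), "outside the universe")
  expect_error(ora(sets, query, character(0)), "empty universe")
})

test_that("sequence preference counts motifs and builds a full-height PFM", {
  w <- rep("AAGCGCAAAAA", 20)
  bgw <- simulate_cpg_windows(200, k = 5, gc = 0.4, motif_rate = 0, seed = 2)
  sp <- sequence_preference(w, bgw, motif = "GCGC")
  expect_equal(unname(colSums(sp$pfm)), rep(20, 11))
  expect_equal(sp$query_with_motif, 20)
  expect_equal(unname(sp$pfm["G", 3]), 20)
  expect_equal(unname(sp$pfm["C", 4]), 20)
  expect_lt(sp$p, 1e-4)
  expect_gt(sp$odds_ratio, 1)

  # same generator on both sides: no enrichment signal
  same <- sequence_preference(simulate_cpg_windows(300, motif_rate = 0.2, seed = 4),
                              simulate_cpg_windows(300, motif_rate = 0.2, seed = 5))
  expect_gt(same$p, 0.01)

  # enriched GCGC deposition is detected
  enr <- sequence_preference(simulate_cpg_windows(500, motif_rate = 0.5, seed = 6),
                             simulate_cpg_windows(500, motif_rate = 0.05, seed = 7))
  expect_gt(enr$odds_ratio, 1)
  expect_lt(enr$p, 0.01)
})

test_that("window extraction truncates at edges and tallies skips", {
  seqs <- list(chr1 = "AAAAACGAAAAA")  # C at 0-based pos 5
  sites <- data.frame(chrom = c("chr1", "chr1", "chr2"), pos = c(5L, 1L, 5L))
  got <- extract_cpg_windows(seqs, sites, k = 5)
  expect_equal(got$windows, "AAAAACGAAAA")
  expect_equal(got$n_skipped, 2L)  # edge-truncated window and unknown chrom
})
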