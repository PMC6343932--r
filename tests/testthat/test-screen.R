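make_enum_fixture <- function() {
  pairs <- data.frame(
    mirna_id = c("mirA", "mirA", "mirB", "mirC"),
    pathway_id = c("pw1", "pw2", "pw1", "pw1"),
    p = c(0.004, 0.002, 0.02, 0.0005),
    stringsAsFactors = FALSE)
  sets <- list(pw1 = c("G1", "G2"), pw2 = c("G2", "G3"))
  snp_map <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs4"),
    gene_id = c("G1", "G1", "G1", "G2"),
    stringsAsFactors = FALSE)
  list(pairs = pairs, sets = sets, snp_map = snp_map)
}

test_that("enumerate_trios: threshold, dedup, cross product", {
  fx <- make_enum_fixture()
  trios <- enumerate_trios(fx$pairs, fx$sets, fx$snp_map,
                           expressed_genes = c("G1", "G2", "G3"),
                           expressed_mirnas = c("mirA", "mirB", "mirC"),
                           kept_snps = c("rs1", "rs2", "rs3", "rs4"))
  # mirB pair has p = 0.02 >= 0.01 -> contributes nothing
  expect_false("mirB" %in% trios$mirna_id)
  # mirA is on pw1 and pw2; G2 appears on both -> its trio counted once
  expect_equal(sum(trios$mirna_id == "mirA" & trios$gene_id == "G2"), 1L)
  # brute-force triple-loop count on the same fixture
  brute <- unique(do.call(rbind, lapply(
    which(fx$pairs$p < 0.01), function(i) {
      genes <- fx$sets[[fx$pairs$pathway_id[i]]]
      do.call(rbind, lapply(genes, function(g) {
        snps <- fx$snp_map$snp_id[fx$snp_map$gene_id == g]
        if (!length(snps)) return(NULL)
        data.frame(mirna_id = fx$pairs$mirna_id[i], gene_id = g,
                   snp_id = snps)
      }))
    })))
  expect_equal(nrow(trios), nrow(brute))
  # deterministic lexicographic order
  expect_identical(trios,
                   trios[order(trios$mirna_id, trios$gene_id,
                               trios$snp_id), ])
  # G2 on pw1 has 1 SNP, G1 has 3: mirC contributes exactly 4 trios
  expect_equal(sum(trios$mirna_id == "mirC"), 4L)
  expect_error(
    enumerate_trios(data.frame(mirna_id = "m", pathway_id = "nope",
                               p = 0.001),
                    fx$sets, fx$snp_map, "G1", "m", "rs1"),
    "nope")
})

test_that("bh_adjust agrees with the step-up oracle and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(41)
  for (rep in 1:50) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(c(1, 2, 5), 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("run_screen: determinism, intersection contract, empty input", {
  set.seed(42)
  sc <- simulation_scenario(n_samples = 150, seed = 42)
  b <- simulate_screen(sc, n_trios = 12, trios_per_pathway = 4)
  mr <- log2_transform(b$mrna, 1); mi <- log2_transform(b$mirna, 1)
  pcs <- compute_pca_covariates(b$genotypes)
  tr <- enumerate_trios(b$pairs, b$gene_sets, b$snp_map,
                        rownames(mr$values), rownames(mi$values),
                        rownames(b$genotypes$dosage))
  r1 <- run_screen(tr, mr, mi, b$genotypes, pcs)
  r2 <- run_screen(tr, mr, mi, b$genotypes, pcs)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), nrow(tr))

  # a sample missing from genotypes is excluded from every fit
  g_small <- subset_genotypes(b$genotypes,
                              samples = sample_ids(b$genotypes)[-(1:10)])
  r3 <- run_screen(tr, mr, mi, g_small, NULL)
  expect_true(all(r3$n_total == 140))

  r0 <- run_screen(tr[0, ], mr, mi, b$genotypes, pcs)
  expect_identical(nrow(r0), 0L)
  expect_identical(names(r0), regqtl:::RESULT_COLUMNS)

  expect_error(run_screen(tr, mr, mi, b$genotypes, pcs,
                          samples = "not-a-sample"),
               "empty sample intersection")

  # subset runs restrict every fit to the listed samples
  keep <- sample_ids(mr)[1:100]
  r4 <- run_screen(tr, mr, mi, b$genotypes, pcs, samples = keep)
  expect_true(all(r4$n_total == 100))
})

test_that("flag_significant uses strict inequality and sorts by q", {
  tbl <- data.frame(
    mirna_id = "m", gene_id = "g", snp_id = sprintf("rs%d", 1:4),
    chrom = "1", pos = 1:4,
    p_interaction = c(0.001, 0.002, 0.003, 0.2),
    q_value = c(0.09, 0.10, 0.02, NA_real_),
    status = c("ok", "ok", "ok", "skipped_degenerate"))
  sig <- flag_significant(tbl, fdr = 0.1)
  expect_identical(sig$snp_id, c("rs3", "rs1"))  # 0.10 not flagged
  expect_identical(nrow(flag_significant(tbl[0, ], 0.1)), 0L)
})

test_that("summarize_pairs counts significant SNPs per pair", {
  tbl <- data.frame(
    mirna_id = c("m1", "m1", "m1", "m2"),
    gene_id = c("gA", "gA", "gB", "gC"),
    snp_id = c("rs1", "rs2", "rs3", "rs4"),
    chrom = c("1", "1", "2", "3"), pos = 1:4,
    p_interaction = c(1e-4, 0.01, 1e-5, 0.5),
    q_value = c(0.05, 0.2, 0.01, 0.9),
    status = "ok")
  s <- summarize_pairs(tbl, fdr = 0.1)
  expect_identical(nrow(s), 2L)
  a <- s[s$gene_id == "gA", ]
  expect_identical(a$n_significant, 1L)   # q = 0.2 not significant
  expect_identical(a$n_snps, 2L)
  expect_equal(a$min_q, 0.05)
  expect_equal(s$min_q, vapply(seq_len(nrow(s)), function(i) {
    rows <- tbl[tbl$mirna_id == s$mirna_id[i] &
                  tbl$gene_id == s$gene_id[i] & tbl$q_value < 0.1, ]
    min(rows$q_value)
  }, numeric(1)))
  expect_identical(nrow(summarize_pairs(tbl, fdr = 1e-6)), 0L)
})

test_that("export_plot_data: QQ formula, uniform band, manhattan rows", {
  one <- data.frame(mirna_id = "m", gene_id = "g", snp_id = "rs",
                    chrom = "1", pos = 1L, p_interaction = 0.5,
                    q_value = 0.5, status = "ok")
  pd1 <- export_plot_data(one)
  expect_equal(pd1$qq$expected, -log10(0.5))
  expect_equal(pd1$qq$observed, -log10(0.5))

  set.seed(43)
  m <- 10000
  tbl <- data.frame(mirna_id = "m", gene_id = "g",
                    snp_id = sprintf("rs%d", 1:m), chrom = "1",
                    pos = 1:m, p_interaction = runif(m),
                    q_value = NA_real_, status = "ok")
  tbl$q_value <- bh_adjust(tbl$p_interaction)
  pd <- export_plot_data(tbl)
  # 95% pointwise beta order-statistic band around the diagonal;
  # order statistics are correlated, so require 90% of points inside
  i <- seq_len(m)
  lo <- -log10(qbeta(0.975, i, m - i + 1))
  hi <- -log10(qbeta(0.025, i, m - i + 1))
  expect_gte(mean(pd$qq$observed >= lo & pd$qq$observed <= hi), 0.90)
  expect_identical(nrow(pd$manhattan), sum(is.finite(tbl$q_value)))
  expect_equal(pd$manhattan$neg_log10_q, -log10(tbl$q_value))
})
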