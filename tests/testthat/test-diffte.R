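make_two_sample_table <- function(g1, g2) {
  count_table(
    tibble::tibble(gene = c("a", "b"), s1 = c(g1[1], g2[1]),
                   s2 = c(g1[2], g2[2])),
    tibble::tibble(sample_id = c("s1", "s2"), genotype = "WT",
                   condition = "untreated", replicate = 1:2, assay = "RNA"))
}

test_that("size factors reproduce the hand-computed median-of-ratios oracle", {
  # genes (2,8) and (4,16): ratios to gene geometric means are (0.5, 2) for
  # both genes, so the medians are (0.5, 2.0) and already have geomean 1
  ct <- make_two_sample_table(c(2L, 8L), c(4L, 16L))
  expect_equal(unname(size_factors(ct, "RNA")), c(0.5, 2.0))

  ident <- make_two_sample_table(c(5L, 5L), c(9L, 9L))
  expect_equal(unname(size_factors(ident, "RNA")), c(1, 1))
})

test_that("size factors are invariant to gene order", {
  set.seed(2)
  counts <- tibble::tibble(
    gene = sprintf("g%02d", 1:20),
    s1 = rpois(20, 100) + 1L, s2 = rpois(20, 200) + 1L,
    s3 = rpois(20, 50) + 1L)
  design <- tibble::tibble(sample_id = c("s1", "s2", "s3"), genotype = "WT",
                           condition = "untreated", replicate = 1:3,
                           assay = "RNA")
  sf1 <- size_factors(count_table(counts, design), "RNA")
  sf2 <- size_factors(count_table(counts[sample(20), ], design), "RNA")
  expect_equal(sf1, sf2)
})

test_that("bh_fdr matches the hand-computed step-up oracle", {
  # p (0.01, 0.02, 0.03, 0.04), m = 4: p_(i) * m / i = (0.04, 0.04, 0.04,
  # 0.04); running minimum from the largest rank leaves all at 0.04
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  # permutation invariance and monotonicity
  set.seed(3)
  p <- runif(50)
  ord <- sample(50)
  expect_equal(bh_fdr(p)[ord], bh_fdr(p[ord]))
  q1 <- bh_fdr(p)
  p2 <- p; p2[7] <- p2[7] / 2
  expect_lte(bh_fdr(p2)[7], q1[7])
})

test_that("delta_te recovers a planted effect exactly in the noiseless limit", {
  fx <- fixture_counts_planted(n_genes = 60, eff_genes = 1:6,
                               log2_effect = 1, base = 1024,
                               dispersion = 0, seed = 31)
  res <- delta_te(fx$counts, standard_contrasts()$c1)
  genes <- fx$annotation$transcripts$transcript_id
  expect_equal(res$log2_effect[res$gene %in% genes[1:6]], rep(1, 6),
               tolerance = 1e-6)
  expect_equal(res$log2_effect[res$gene %in% genes[7:60]], rep(0, 54),
               tolerance = 1e-6)
  expect_true(all(res$p[res$gene %in% genes[7:60]] > 0.9))
})

test_that("a gene with identical counts everywhere has zero effect and p near 1", {
  fx <- fixture_counts_planted(n_genes = 20, eff_genes = integer(0),
                               dispersion = 0.05, seed = 32)
  flat <- fx$counts$counts
  flat[1, -1] <- as.list(rep(500L, 16))
  ct <- count_table(flat, fx$counts$design)
  res <- delta_te(ct, standard_contrasts()$c1)
  # identical counts: the interaction is absorbed by the size factors up to
  # normalization noise from the other genes
  expect_lt(abs(res$log2_effect[1]), 0.25)
  expect_gt(res$p[1], 0.5)
})

test_that("swapping numerator and denominator negates effects and keeps p", {
  fx <- fixture_counts_planted(n_genes = 40, eff_genes = 1:5,
                               dispersion = 0.02, seed = 33)
  fwd <- standard_contrasts()$c1
  rev <- contrast_spec(fwd$denominator, fwd$numerator)
  r1 <- delta_te(fx$counts, fwd)
  r2 <- delta_te(fx$counts, rev)
  expect_equal(r2$log2_effect, -r1$log2_effect, tolerance = 1e-6)
  expect_equal(r2$p, r1$p, tolerance = 1e-6)
})

test_that("select_by_fold uses strict inequalities", {
  res <- structure(tibble::tibble(
    gene = c("a", "b", "c", "d"),
    log2_effect = c(0.6, 0.5, -0.6, 0.49),
    se = 0.1, p = 0.001, q = c(0.01, 0.01, 0.01, 0.9),
    status = "tested"), class = c("te_contrast", class(tibble::tibble())))
  # the conventional ">1.41-fold" cut is sqrt(2), i.e. > 0.5 log2 units:
  # an effect of exactly 0.5 is NOT selected
  expect_equal(select_by_fold(res, sqrt(2), "up"), "a")
  expect_equal(select_by_fold(res, sqrt(2), "down"), "c")
  expect_equal(select_by_fold(res, sqrt(2), "up", fdr = 0.25), "a")
  expect_equal(select_by_fold(res[0, ], sqrt(2), "up"), character(0))
})

test_that("log2 effects agree with an independent DESeq2 interaction fit", {
  library(DESeq2)
  fx <- fixture_counts_planted(n_genes = 120, eff_genes = 1:12,
                               log2_effect = 1.5, base = 800,
                               dispersion = 0.02, seed = 34)
  ct <- fx$counts
  d <- ct$design %>%
    dplyr::mutate(cell = paste(genotype, condition, sep = ":")) %>%
    dplyr::filter(cell %in% c("eIF2Ad:SM", "WT:SM"))
  m <- as.matrix(ct$counts[d$sample_id])
  rownames(m) <- ct$counts$gene
  coldata <- data.frame(
    assay = factor(d$assay, levels = c("RNA", "RPF")),
    cell = factor(ifelse(d$cell == "eIF2Ad:SM", "num", "den"),
                  levels = c("den", "num")))
  dds <- DESeqDataSetFromMatrix(m, coldata, ~ assay + cell + assay:cell)
  dds <- suppressMessages(DESeq(dds, quiet = TRUE))
  ref <- results(dds, name = "assayRPF.cellnum")$log2FoldChange
  ours <- delta_te(ct, standard_contrasts()$c1)$log2_effect
  expect_gt(cor(ours, ref), 0.98)
  expect_lt(median(abs(ours - ref)), 0.1)
})

test_that("the permutation test agrees with the Wald ranking on strong effects", {
  fx <- fixture_counts_planted(n_genes = 25, eff_genes = 1:3,
                               log2_effect = 2, base = 2000,
                               dispersion = 0.01, seed = 35)
  res <- delta_te(fx$counts, standard_contrasts()$c1, method = "perm")
  genes <- fx$annotation$transcripts$transcript_id
  # 4 replicate units over two cells -> 6 relabellings, of which the
  # complementary pair negates the interaction, so the attainable floor is 2/6
  expect_true(all(res$p[res$gene %in% genes[1:3]] <= 2 / 6 + 1e-12))
  expect_true(all(res$p >= 2 / 6 - 1e-12))
})

test_that("planted effects are recovered with small error and high power", {
  n <- 200
  ann <- simulate_annotation(n, seed = 36)
  genes <- ann$transcripts$transcript_id
  set.seed(37)
  eff <- rnorm(n, 0, 0.5)
  eff[1:20] <- 1
  tr <- simulation_truth(genes, base_mean_rna = 1e4, dispersion = 0.005,
                         log2_te_interaction = eff)
  ct <- simulate_counts(ann, default_design(), tr, seed = 38)
  res <- delta_te(ct, standard_contrasts()$c1)
  est <- res$log2_effect[match(genes, res$gene)]
  # median-of-ratios centres the RPF libraries on the median planted effect
  shift <- median(eff)
  expect_lt(sqrt(mean((est - (eff - shift))^2)), 0.2)
  expect_gte(mean(res$q[match(genes[1:20], res$gene)] < 0.25), 0.8)
})
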