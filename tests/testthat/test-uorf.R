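rro_fixture <- function(uorf_counts, cds_counts) {
  # two RPF samples per genotype (the "combined samples" of one comparison)
  n <- length(uorf_counts[[1]])
  ids <- paste0("u", seq_len(n))
  ann <- genome_annotation(
    tibble::tibble(transcript_id = paste0("tx", seq_len(n)), length = 600L,
                   cds_start = 120L, cds_end = 420L),
    tibble::tibble(uorf_id = ids, transcript_id = paste0("tx", seq_len(n)),
                   start = 10L, end = 40L, start_codon_class = "AUG",
                   annotation_source = "annotated"))
  samples <- c("RPF_WT_SM_a", "RPF_WT_SM_b", "RPF_eIF2Ad_SM_a",
               "RPF_eIF2Ad_SM_b")
  counts <- tibble::tibble(gene = paste0("tx", seq_len(n)))
  region <- tibble::tibble(uorf_id = ids,
                           transcript_id = paste0("tx", seq_len(n)))
  for (i in seq_along(samples)) {
    counts[[samples[i]]] <- as.integer(cds_counts[[i]])
    region[[samples[i]]] <- as.integer(uorf_counts[[i]])
  }
  design <- tibble::tibble(
    sample_id = samples,
    genotype = rep(c("WT", "eIF2Ad"), each = 2),
    condition = "SM", replicate = rep(1:2, 2), assay = "RPF")
  list(ct = count_table(counts, design, region), ann = ann)
}

test_that("RRO equals the per-sample uORF/CDS count ratio with the stated filters", {
  fx <- rro_fixture(
    uorf_counts = list(c(10, 1, 5, 4), c(10, 2, 5, 4),
                       c(10, 1, 5, 4), c(10, 2, 5, 4)),
    cds_counts = list(c(100, 200, 31, 200), c(100, 200, 32, 200),
                      c(100, 200, 32, 200), c(100, 200, 32, 200)))
  rro <- compute_rro(fx$ct, fx$ann)
  t1 <- dplyr::filter(rro, uorf_id == "u1")
  expect_equal(unique(t1$rro), 0.1)           # 10 / 100
  expect_equal(unique(t1$filter_status), "pass")
  # mean uORF RPF 1.5 < 2 -> low_uorf
  expect_equal(unique(rro$filter_status[rro$uorf_id == "u2"]), "low_uorf")
  # mean CDS RPF 31.75 < 32 with healthy uORF counts -> low_cds
  expect_equal(unique(rro$filter_status[rro$uorf_id == "u3"]), "low_cds")
  expect_equal(unique(rro$filter_status[rro$uorf_id == "u4"]), "pass")
})

test_that("low_uorf takes precedence when both filters fail", {
  fx <- rro_fixture(uorf_counts = list(1, 1, 1, 1),
                    cds_counts = list(10, 10, 10, 10))
  rro <- compute_rro(fx$ct, fx$ann)
  expect_equal(unique(rro$filter_status), "low_uorf")
})

test_that("compute_rro equals a brute-force loop over samples and uORFs", {
  ann <- simulate_annotation(40, uorf_fraction = 1, seed = 41)
  tr <- simulation_truth(ann$transcripts$transcript_id, base_mean_rna = 300,
                         dispersion = 0.05,
                         uorf_rro = tibble::tibble(uorf_id = ann$uorfs$uorf_id,
                                                   true_rro = 0.15))
  ct <- simulate_counts(ann, default_design(), tr, seed = 42)
  rro <- compute_rro(ct, ann)
  rpf <- samples_for(ct, assay == "RPF")
  for (row in sample(nrow(rro), 25)) {
    r <- rro[row, ]
    uc <- ct$region_counts[[r$sample_id]][ct$region_counts$uorf_id == r$uorf_id]
    cc <- ct$counts[[r$sample_id]][ct$counts$gene == r$transcript_id]
    expect_identical(r$uorf_count, uc)
    expect_identical(r$cds_count, cc)
    if (cc > 0) expect_identical(r$rro, uc / cc) else expect_true(is.na(r$rro))
    expect_equal(r$mean_uorf_rpf, mean(vapply(rpf, function(s)
      ct$region_counts[[s]][ct$region_counts$uorf_id == r$uorf_id],
      numeric(1))))
  }
})

test_that("RRO is invariant to library-size rescaling", {
  fx <- rro_fixture(uorf_counts = list(c(10, 6), c(12, 8), c(9, 7), c(11, 6)),
                    cds_counts = list(c(100, 60), c(120, 80), c(90, 70),
                                      c(110, 60)))
  r1 <- compute_rro(fx$ct, fx$ann)
  scaled_counts <- fx$ct$counts
  scaled_region <- fx$ct$region_counts
  s <- "RPF_WT_SM_a"
  scaled_counts[[s]] <- scaled_counts[[s]] * 7L
  scaled_region[[s]] <- scaled_region[[s]] * 7L
  ct2 <- count_table(scaled_counts, fx$ct$design, scaled_region)
  r2 <- compute_rro(ct2, fx$ann)
  expect_equal(r2$rro, r1$rro)
})

test_that("every uORF gets exactly one filter status", {
  ann <- simulate_annotation(30, uorf_fraction = 1, seed = 43)
  tr <- simulation_truth(ann$transcripts$transcript_id, base_mean_rna = 50,
                         dispersion = 0.2,
                         uorf_rro = tibble::tibble(uorf_id = ann$uorfs$uorf_id,
                                                   true_rro = 0.05))
  ct <- simulate_counts(ann, default_design(), tr, seed = 44)
  rro <- compute_rro(ct, ann)
  per_uorf <- rro %>% dplyr::distinct(uorf_id, filter_status)
  expect_equal(nrow(per_uorf), dplyr::n_distinct(rro$uorf_id))
  expect_true(all(per_uorf$filter_status %in% c("pass", "low_uorf", "low_cds")))
})

test_that("delta_rro recovers planted RRO changes in the noiseless limit", {
  # mutant RRO halved: uORF counts 64 -> 32 with CDS constant
  fx <- rro_fixture(
    uorf_counts = list(rep(64, 30), rep(64, 30), rep(32, 30), rep(32, 30)),
    cds_counts = list(rep(640, 30), rep(640, 30), rep(640, 30), rep(640, 30)))
  contrast <- standard_contrasts()$c1   # mutant+SM / WT+SM
  res <- delta_rro(fx$ct, contrast, annotation = fx$ann)
  expect_equal(res$log2_effect, rep(-1, 30), tolerance = 1e-6)

  fx2 <- rro_fixture(
    uorf_counts = list(rep(64, 10), rep(64, 10), rep(64, 10), rep(64, 10)),
    cds_counts = list(rep(640, 10), rep(640, 10), rep(640, 10), rep(640, 10)))
  res2 <- delta_rro(fx2$ct, contrast, annotation = fx2$ann)
  expect_equal(res2$log2_effect, rep(0, 10), tolerance = 1e-9)
})

test_that("null RRO simulation keeps q-values above the loose threshold", {
  ann <- simulate_annotation(400, uorf_fraction = 1, seed = 45)
  tr <- simulation_truth(ann$transcripts$transcript_id, base_mean_rna = 500,
                         dispersion = 0.05,
                         uorf_rro = tibble::tibble(uorf_id = ann$uorfs$uorf_id,
                                                   true_rro = 0.3))
  ct <- simulate_counts(ann, default_design(), tr, seed = 46)
  res <- delta_rro(ct, standard_contrasts()$c1,
                   config = analysis_config(), annotation = ann)
  # full null: the number of discoveries at FDR 0.5 should be 0 almost always
  expect_lte(sum(res$q < 0.5, na.rm = TRUE), ceiling(0.02 * nrow(res)))
})

test_that("group summaries match Mann-Whitney expectations", {
  set.seed(47)
  res <- structure(tibble::tibble(
    gene = sprintf("g%04d", 1:1000),
    log2_effect = rnorm(1000), se = 0.1, p = runif(1000),
    q = runif(1000), status = "tested"),
    class = c("te_contrast", class(tibble::tibble())))

  # group == background
  all_g <- group_te_summary(res, list(everything = res$gene))
  expect_equal(all_g$median_log2_effect, median(res$log2_effect))
  expect_gt(all_g$mannwhitney_p, 0.9)

  # shifted group of 100 against N(0,1) background
  res2 <- res
  res2$log2_effect[1:100] <- res2$log2_effect[1:100] + 1
  shifted <- group_te_summary(res2, list(up = res2$gene[1:100]))
  expect_lt(shifted$mannwhitney_p, 1e-10)

  # singleton group still yields a finite exact-tail p
  single <- group_te_summary(res, list(lone = res$gene[1]))
  expect_equal(single$n, 1L)
  expect_true(single$mannwhitney_p > 0 && single$mannwhitney_p <= 1)

  expect_error(group_te_summary(res, list(bad = character(0))), "empty group")
})

test_that("the Mann-Whitney p matches a brute-force U-statistic oracle", {
  set.seed(48)
  x <- rnorm(30, 1)
  y <- rnorm(200)
  res <- structure(tibble::tibble(
    gene = sprintf("g%03d", 1:230), log2_effect = c(x, y), se = 0.1,
    p = 0.5, q = 0.5, status = "tested"),
    class = c("te_contrast", class(tibble::tibble())))
  got <- group_te_summary(res, list(grp = res$gene[1:30]),
                          background = "disjoint")$mannwhitney_p
  # brute-force U and its normal approximation with continuity correction
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  mu <- length(x) * length(y) / 2
  sigma <- sqrt(length(x) * length(y) * (length(x) + length(y) + 1) / 12)
  p_oracle <- 2 * pnorm(-(abs(U - mu) - 0.5) / sigma)
  expect_equal(got, p_oracle, tolerance = 1e-3)
})
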