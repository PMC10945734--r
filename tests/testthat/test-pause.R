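flat_fixture <- function(n_genes = 8, seed = 51, alphabet = c("A", "C", "D")) {
  ann <- simulate_annotation(n_genes, seed = seed)
  pep <- simulate_peptides(ann, seed = seed + 1, alphabet = alphabet)
  truth <- simulation_truth(ann$transcripts$transcript_id)
  trk <- simulate_track(ann, pep, truth, depth = 1e5, seed = seed + 2,
                        noise = "none")
  list(ann = ann, pep = pep, trk = trk)
}

test_that("shift_assign moves 3'-end counts upstream and conserves reads", {
  v <- numeric(200)
  v[101] <- 1  # a read whose 3' end maps to nt 100 (0-based)
  trk <- footprint_track(list(tx = v), library_size = 1)
  shifted <- shift_assign(trk, 18)
  expect_equal(which(shifted$density$tx == 1) - 1L, 82L)

  expect_equal(shift_assign(trk, 0)$density$tx, v)

  # counts landing below zero are dropped and reported
  v2 <- numeric(100); v2[5] <- 3; v2[50] <- 2
  trk2 <- footprint_track(list(tx = v2), library_size = 5)
  s2 <- shift_assign(trk2, 18)
  expect_equal(sum(s2$density$tx), 2)
  expect_equal(attr(s2, "dropped_reads"), 3)
})

test_that("motif occurrences keep only codons whose windows fit inside the CDS", {
  # 100-codon CDS: spans must start >= 50 nt into the CDS and end <= 50 nt
  # before its end, i.e. codons 17..80
  ann <- genome_annotation(tibble::tibble(
    transcript_id = "tx", length = 400L, cds_start = 30L, cds_end = 330L))
  pep <- setNames(paste(rep("A", 99), collapse = ""), "tx")
  sites <- motif_sites(ann, pep, window_nt = 50)
  expect_equal(range(sites$codon), c(17, 80))

  # brute-force oracle over every codon
  brute <- vapply(0:96, function(k) {
    s <- 30 + 3 * k
    (s - 50 >= 30) && (s + 9 + 50 <= 330)
  }, logical(1))
  expect_equal(sites$codon, (0:96)[brute])

  # CDS shorter than 9 + 2*window -> nothing survives
  tiny <- genome_annotation(tibble::tibble(
    transcript_id = "tx", length = 200L, cds_start = 30L, cds_end = 120L))
  pep_tiny <- setNames(paste(rep("A", 29), collapse = ""), "tx")
  expect_equal(nrow(motif_sites(tiny, pep_tiny, 50)), 0)
})

test_that("a flat track yields pause scores of exactly 1", {
  fx <- flat_fixture()
  sites <- motif_sites(fx$ann, fx$pep, 50)
  ps <- pause_scores(fx$trk, sites, analysis_config(min_motif_occurrences = 1))
  expect_equal(ps$mean_score, rep(1, nrow(ps)), tolerance = 1e-12)
})

test_that("occurrence scores equal the motif/flank rpm ratio", {
  # single transcript, density 2 everywhere in the CDS except one motif span
  # at 10: score must be exactly 5
  ann <- genome_annotation(tibble::tibble(
    transcript_id = "tx", length = 600L, cds_start = 100L, cds_end = 499L))
  pep_letters <- rep("A", 132)
  pep_letters[50] <- "W"  # tripeptide WAA at codon 49 (0-based), unique
  pep <- setNames(paste(pep_letters, collapse = ""), "tx")
  v <- numeric(600)
  v[101:499] <- 2
  span <- 100 + 3 * 49 + (1:9)
  v[span] <- 10
  trk <- footprint_track(list(tx = v))
  sites <- motif_sites(ann, pep, 50)
  ps <- pause_scores(trk, sites, analysis_config(min_motif_occurrences = 1))
  expect_equal(ps$mean_score[ps$motif == "WAA"], 5, tolerance = 1e-12)
})

test_that("motifs below the occurrence floor are excluded", {
  fx <- flat_fixture()
  sites <- motif_sites(fx$ann, fx$pep, 50)
  tab <- table(sites$motif)
  floor_n <- as.integer(stats::quantile(as.integer(tab), 0.5))
  ps <- pause_scores(fx$trk, sites,
                     analysis_config(min_motif_occurrences = floor_n))
  expect_equal(ps$included, ps$n_occurrences >= floor_n)
  # boundary: a motif seen floor_n - 1 times is excluded, floor_n is kept
  below <- ps$n_occurrences == floor_n - 1
  if (any(below)) expect_false(any(ps$included[below]))
  at <- ps$n_occurrences == floor_n
  if (any(at)) expect_true(all(ps$included[at]))
})

test_that("pause scores are invariant to rescaling the track", {
  fx <- flat_fixture(seed = 61, alphabet = c("A", "C", "D", "E"))
  sites <- motif_sites(fx$ann, fx$pep, 50)
  noisy <- simulate_track(fx$ann, fx$pep,
                          simulation_truth(fx$ann$transcripts$transcript_id),
                          depth = 1e5, seed = 62, noise = "poisson")
  ps1 <- pause_scores(noisy, sites, analysis_config(min_motif_occurrences = 1))
  scaled <- footprint_track(lapply(noisy$density, `*`, 7),
                            library_size = noisy$library_size * 7)
  ps2 <- pause_scores(scaled, sites, analysis_config(min_motif_occurrences = 1))
  expect_equal(ps2$mean_score, ps1$mean_score, tolerance = 1e-12)
})

test_that("compare_pause joins included motifs and flags the A-site residue", {
  fx <- flat_fixture(seed = 63)
  sites <- motif_sites(fx$ann, fx$pep, 50)
  cfg <- analysis_config(min_motif_occurrences = 1)
  ps <- pause_scores(fx$trk, sites, cfg)
  cmp <- compare_pause(ps, ps, a_site_residue = "C")
  expect_equal(cmp$score_a, cmp$score_b)
  expect_equal(cmp$a_site_flag, substring(cmp$motif, 3, 3) == "C")
})

test_that("a planted pause shows up in the between-condition comparison", {
  ann <- simulate_annotation(60, seed = 64)
  pep <- simulate_peptides(ann, seed = 65,
                           alphabet = strsplit("ACDEFG", "")[[1]])
  genes <- ann$transcripts$transcript_id
  base <- simulation_truth(genes)
  paused <- simulation_truth(genes, pause_multipliers = c(FED = 5))
  cfg <- analysis_config(min_motif_occurrences = 20)
  sites <- motif_sites(ann, pep, 50)
  t_a <- simulate_track(ann, pep, base, depth = 1e5, seed = 66,
                        noise = "poisson")
  t_b <- simulate_track(ann, pep, paused, depth = 1e5, seed = 67,
                        noise = "poisson")
  cmp <- compare_pause(pause_scores(t_a, sites, cfg),
                       pause_scores(t_b, sites, cfg))
  ratio <- cmp$ratio_b_a[cmp$motif == "FED"]
  expect_gt(ratio, 4)
  expect_lt(ratio, 6)
})

test_that("the full 3'-end shift pipeline recovers planted pauses", {
  ann <- simulate_annotation(50, seed = 68)
  pep <- simulate_peptides(ann, seed = 69,
                           alphabet = strsplit("ACDEFGHI", "")[[1]])
  truth <- simulation_truth(ann$transcripts$transcript_id,
                            pause_multipliers = c(ACA = 5))
  raw3p <- simulate_track(ann, pep, truth, depth = 1e5, seed = 70,
                          noise = "poisson", as_3prime = TRUE, shift_nt = 18)
  trk <- shift_assign(raw3p, 18)
  sites <- motif_sites(ann, pep, 50)
  ps <- pause_scores(trk, sites, analysis_config(min_motif_occurrences = 10))
  top <- ps$motif[which.max(ps$mean_score)]
  expect_equal(top, "ACA")
  expect_equal(ps$mean_score[ps$motif == "ACA"], 5, tolerance = 0.2 * 5)
})
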