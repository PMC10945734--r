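# shared fixture builders; everything is generated in code at test time

fixture_annotation <- function() {
  genome_annotation(
    transcripts = tibble::tibble(
      transcript_id = c("tx1", "tx2"),
      length = c(500L, 800L),
      cds_start = c(50L, 100L),
      cds_end = c(350L, 700L)
    ),
    uorfs = tibble::tibble(
      uorf_id = c("tx1_u1", "tx2_u1"),
      transcript_id = c("tx1", "tx2"),
      start = c(10L, 20L),
      end = c(25L, 38L),
      start_codon_class = c("AUG", "NCC"),
      annotation_source = c("annotated", "functional")
    )
  )
}

# minimal 2-cell design (one contrast's worth of samples)
fixture_design_two_cells <- function() {
  dplyr::filter(default_design(), condition == "SM")
}

# deterministic count table with a planted interaction effect on `eff_genes`
fixture_counts_planted <- function(n_genes = 50, eff_genes = 1:5,
                                   log2_effect = 1, base = 1024,
                                   dispersion = 0, seed = 42) {
  ann <- simulate_annotation(n_genes, seed = seed)
  genes <- ann$transcripts$transcript_id
  int <- rep(0, n_genes)
  int[eff_genes] <- log2_effect
  truth <- simulation_truth(genes, base_mean_rna = base,
                            dispersion = dispersion,
                            log2_te_interaction = int)
  list(annotation = ann, truth = truth,
       counts = simulate_counts(ann, default_design(), truth, seed = seed + 1))
}

# gradient dataset matching the worked arithmetic: corrected amounts
# (1, 2, 1), ribosome weights (1, 2, 3), ACT1-normalized input 2 -> TE 4
fixture_toy_gradient <- function() {
  a <- c(1, 2, 1)
  a260 <- c(2, 5, 3)
  ct_18s <- -log2(a260)            # makes 18S shares proportional to A260
  fractions <- tibble::tibble(
    gradient_id = "toy", fraction_id = c("80S", "2mer", "3mer"),
    ribosome_weight = 1:3, a260_area = a260,
    pooled_volume_ul = 300, rna_extraction_volume_ul = 300,
    rt_input_fraction_volume_ul = 25
  )
  # volume corrections and recovery factors are all 1, so the corrected
  # amount reduces to 2^-(ct_target - ct_18s)
  ct <- dplyr::bind_rows(
    tibble::tibble(gradient_id = "toy", fraction_id = fractions$fraction_id,
                   target = "18S", ct = ct_18s),
    tibble::tibble(gradient_id = "toy", fraction_id = fractions$fraction_id,
                   target = "HKR1", ct = ct_18s - log2(a)),
    # input: target amount 2, ACT1 amount 1 (each = 2^-dCT * 5)
    tibble::tibble(gradient_id = "toy", fraction_id = "input",
                   target = c("18S", "HKR1", "ACT1"),
                   ct = c(10, 10 - log2(2 / 5), 10 - log2(1 / 5)))
  )
  gradient_dataset(fractions, ct)
}
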