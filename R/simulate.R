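#' Ground truth for the synthetic-data generators
#'
#' Per-gene expected RNA abundance, negative-binomial dispersion
#' (variance = mu + alpha * mu^2), and log2 TE effects expressed as a
#' genotype main effect, a treatment main effect and their interaction:
#' log2 TE(cell) = base + g * genotype + s * condition + g * s * interaction,
#' with g = 1 for the deletion strain and s = 1 for drug treatment.
#' Optionally carries per-uORF expected uORF/CDS footprint ratios and
#' per-motif pause multipliers.
#'
#' @param genes Character vector of gene ids.
#' @param base_mean_rna Expected RNA-seq count per gene (recycled).
#' @param dispersion NB dispersion alpha; `0` is the exact noiseless limit
#'   (counts equal their rounded expectations).
#' @param base_log2_te,log2_te_genotype,log2_te_condition,log2_te_interaction
#'   Log2 TE components (recycled across genes).
#' @param uorf_rro Optional tibble `uorf_id`, `true_rro` (expected uORF/CDS
#'   RPF ratio, >= 0).
#' @param pause_multipliers Optional named numeric vector: tripeptide motif ->
#'   fold-excess footprint density at its occurrences (>= 1).
#' @return An object of class `"simulation_truth"`.
#' @export
simulation_truth <- function(genes,
                             base_mean_rna = 500,
                             dispersion = 0.05,
                             base_log2_te = 0,
                             log2_te_genotype = 0,
                             log2_te_condition = 0,
                             log2_te_interaction = 0,
                             uorf_rro = NULL,
                             pause_multipliers = NULL) {
  g <- tibble(
    gene = as.character(genes),
    base_mean_rna = rep_len(base_mean_rna, length(genes)),
    dispersion = rep_len(dispersion, length(genes)),
    base_log2_te = rep_len(base_log2_te, length(genes)),
    log2_te_genotype = rep_len(log2_te_genotype, length(genes)),
    log2_te_condition = rep_len(log2_te_condition, length(genes)),
    log2_te_interaction = rep_len(log2_te_interaction, length(genes))
  )
  assert_that(all(g$base_mean_rna > 0), "base_mean_rna must be > 0")
  assert_that(all(g$dispersion >= 0), "dispersion must be >= 0")
  if (!is.null(uorf_rro)) {
    uorf_rro <- as_tibble(uorf_rro)
    assert_that(all(c("uorf_id", "true_rro") %in% names(uorf_rro)),
                "uorf_rro needs columns uorf_id, true_rro")
    assert_that(all(uorf_rro$true_rro >= 0), "true_rro must be >= 0")
  } else {
    uorf_rro <- tibble(uorf_id = character(), true_rro = numeric())
  }
  if (!is.null(pause_multipliers)) {
    assert_that(!is.null(names(pause_multipliers)) &&
                  all(nchar(names(pause_multipliers)) == 3L),
                "pause_multipliers must be named by tripeptide motif")
    assert_that(all(pause_multipliers >= 1), "pause_multiplier must be >= 1")
    motifs <- tibble(motif = names(pause_multipliers),
                     pause_multiplier = unname(pause_multipliers))
  } else {
    motifs <- tibble(motif = character(), pause_multiplier = numeric())
  }
  structure(list(genes = g, uorfs = uorf_rro, motifs = motifs),
            class = "simulation_truth")
}

#' True log2 TE of each gene in one (genotype, condition) cell
#' @param truth A [simulation_truth()].
#' @param genotype,condition Cell coordinates.
#' @return Named numeric vector (gene -> log2 TE).
#' @export
true_log2_te_cell <- function(truth, genotype, condition) {
  g <- as.integer(genotype == "eIF2Ad")
  s <- as.integer(condition == "SM")
  with(truth$genes,
       setNames(base_log2_te + g * log2_te_genotype + s * log2_te_condition +
                  g * s * log2_te_interaction, gene))
}

#' True log2 delta-TE for a contrast of two cells
#' @param truth A [simulation_truth()].
#' @param contrast A [contrast_spec()].
#' @return Named numeric vector (gene -> planted log2 TE change).
#' @export
true_log2_delta_te <- function(truth, contrast) {
  true_log2_te_cell(truth, contrast$numerator[["genotype"]],
                    contrast$numerator[["condition"]]) -
    true_log2_te_cell(truth, contrast$denominator[["genotype"]],
                      contrast$denominator[["condition"]])
}

#' Simulate a transcript annotation
#'
#' CDS lengths are drawn uniformly from 300-3000 nt (multiples of 3),
#' 5' UTRs from 60-300 nt, 3' UTRs from 60-240 nt. A `uorf_fraction` share
#' of transcripts receives 1-2 uORFs (6-30 nt, multiples of 3) placed in the
#' 5' UTR, with AUG and near-cognate (NCC) start classes in equal proportion.
#'
#' @param n_genes Number of transcripts (>= 1).
#' @param uorf_fraction Proportion of transcripts bearing uORFs, in \[0, 1\].
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @return A [genome_annotation()].
#' @export
simulate_annotation <- function(n_genes, uorf_fraction = 0, seed = 1L) {
  assert_that(is_wholenumber(n_genes) && n_genes >= 1, "n_genes must be >= 1")
  assert_that(uorf_fraction >= 0 && uorf_fraction <= 1,
              "uorf_fraction must be in [0, 1]")
  withr::with_seed(as.integer(seed), {
    cds_len <- 3L * sample(100:1000, n_genes, replace = TRUE)
    utr5 <- sample(60:300, n_genes, replace = TRUE)
    utr3 <- sample(60:240, n_genes, replace = TRUE)
    ids <- sprintf("g%04d", seq_len(n_genes))
    transcripts <- tibble(
      transcript_id = ids,
      length = utr5 + cds_len + utr3,
      cds_start = utr5,
      cds_end = utr5 + cds_len
    )
    n_with <- round(uorf_fraction * n_genes)
    if (uorf_fraction == 1) n_with <- n_genes
    uorfs <- NULL
    if (n_with > 0) {
      host <- sample(ids, n_with)
      uorfs <- purrr::map_dfr(host, function(id) {
        u5 <- transcripts$cds_start[transcripts$transcript_id == id]
        k <- sample(1:2, 1)
        purrr::map_dfr(seq_len(k), function(j) {
          len <- 3L * sample(2:10, 1)
          if (len > u5) len <- 3L * max(1L, u5 %/% 3L - 1L)
          start <- sample(0:(u5 - len), 1)
          tibble(
            uorf_id = paste0(id, "_u", j),
            transcript_id = id,
            start = start, end = start + len,
            start_codon_class = sample(UORF_CLASSES, 1),
            annotation_source = sample(UORF_SOURCES, 1)
          )
        })
      })
    }
    genome_annotation(transcripts, uorfs)
  })
}

nb_draw <- function(mu, alpha) {
  # alpha = 0 is the exact noiseless limit: counts are rounded expectations
  out <- numeric(length(mu))
  zero <- alpha <= 0
  out[zero] <- round(mu[zero])
  if (any(!zero)) {
    out[!zero] <- rnbinom(sum(!zero), mu = mu[!zero], size = 1 / alpha[!zero])
  }
  out
}

#' Simulate a paired RPF/RNA count matrix
#'
#' RNA counts are NB(mu = base_mean_rna, alpha); RPF counts are
#' NB(mu = base_mean_rna * TE(cell), alpha) where TE composes the truth's
#' genotype, condition and interaction effects. Per-uORF region counts (RPF
#' libraries only) are drawn with expectation `true_rro` times the host
#' gene's RPF expectation, so planted RRO values are exact in expectation.
#'
#' @param annotation A [genome_annotation()]; its transcripts define genes.
#' @param design Design tibble (see [default_design()]); every
#'   (genotype, condition, assay) cell must have at least one sample.
#' @param truth A [simulation_truth()] covering all genes.
#' @param seed Integer seed.
#' @return A [count_table()] with `region_counts` when the annotation has
#'   uORFs with planted RRO.
#' @export
simulate_counts <- function(annotation, design, truth, seed = 1L) {
  design <- validate_design(design)
  cells <- tidyr::expand_grid(genotype = GENOTYPES, condition = CONDITIONS,
                              assay = ASSAYS)
  have <- design %>% distinct(.data$genotype, .data$condition, .data$assay)
  missing <- dplyr::anti_join(cells, have,
                              by = c("genotype", "condition", "assay"))
  assert_that(nrow(missing) == 0,
              paste0("design cell with no sample: ",
                     paste(missing$genotype, missing$condition, missing$assay,
                           collapse = "; ")))
  genes <- annotation$transcripts$transcript_id
  assert_that(all(genes %in% truth$genes$gene),
              "truth must cover every annotated gene")
  tr <- truth$genes[match(genes, truth$genes$gene), ]

  withr::with_seed(as.integer(seed), {
    counts <- tibble(gene = genes)
    rpf_mu <- list()
    for (i in seq_len(nrow(design))) {
      d <- design[i, ]
      mu <- tr$base_mean_rna
      if (d$assay == "RPF") {
        te <- 2^true_log2_te_cell(truth, d$genotype, d$condition)[genes]
        mu <- mu * te
        rpf_mu[[d$sample_id]] <- mu
      }
      counts[[d$sample_id]] <- as.integer(nb_draw(mu, tr$dispersion))
    }
    region_counts <- NULL
    uorfs <- annotation$uorfs %>% semi_join(truth$uorfs, by = "uorf_id")
    if (nrow(uorfs) > 0) {
      u <- uorfs %>% left_join(truth$uorfs, by = "uorf_id")
      region_counts <- tibble(uorf_id = u$uorf_id,
                              transcript_id = u$transcript_id)
      alpha_u <- tr$dispersion[match(u$transcript_id, genes)]
      for (s in names(rpf_mu)) {
        mu_u <- u$true_rro * rpf_mu[[s]][match(u$transcript_id, genes)]
        region_counts[[s]] <- as.integer(nb_draw(mu_u, alpha_u))
      }
    }
    count_table(counts, design, region_counts)
  })
}

#' Random peptide sequences for an annotation
#'
#' One amino-acid string per transcript, of length CDS codons minus one
#' (the stop codon encodes no residue). A reduced `alphabet` concentrates
#' motif occurrences, which is useful for exercising the 100-occurrence
#' pause-score floor on small simulations.
#'
#' @param annotation A [genome_annotation()].
#' @param seed Integer seed.
#' @param alphabet Amino-acid letters to draw from.
#' @return Named character vector (transcript id -> peptide).
#' @export
simulate_peptides <- function(annotation, seed = 1L,
                              alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  tx <- annotation$transcripts
  withr::with_seed(as.integer(seed), {
    setNames(vapply(seq_len(nrow(tx)), function(i) {
      n_aa <- (tx$cds_end[i] - tx$cds_start[i]) %/% 3L - 1L
      paste(sample(alphabet, n_aa, replace = TRUE), collapse = "")
    }, character(1)), tx$transcript_id)
  })
}

#' Simulate a footprint-assignment track with planted pauses
#'
#' Density is uniform within each CDS (zero in UTRs), multiplied by the
#' truth's `pause_multiplier` over the 9-nt span of every occurrence of a
#' planted motif, then scaled so the expected total equals `depth`.
#'
#' @param annotation A [genome_annotation()].
#' @param peptides Named peptide vector (see [simulate_peptides()]); length
#'   must equal CDS codons minus one per transcript.
#' @param truth A [simulation_truth()] (its `$motifs` drive planted pauses).
#' @param depth Expected total read count.
#' @param seed Integer seed.
#' @param noise `"poisson"` for per-nt Poisson counts, `"none"` for exact
#'   expected densities.
#' @param as_3prime If `TRUE`, return the raw 3'-end track (signal shifted
#'   downstream by `shift_nt`) that [shift_assign()] undoes.
#' @param shift_nt Shift used when `as_3prime = TRUE`.
#' @return A [footprint_track()].
#' @export
simulate_track <- function(annotation, peptides, truth, depth = 1e5,
                           seed = 1L, noise = c("poisson", "none"),
                           as_3prime = FALSE, shift_nt = 18L) {
  noise <- match.arg(noise)
  tx <- annotation$transcripts
  assert_that(all(tx$transcript_id %in% names(peptides)),
              "peptides missing for some transcripts")
  n_aa <- (tx$cds_end - tx$cds_start) %/% 3L - 1L
  got <- nchar(peptides[tx$transcript_id])
  if (any(got != n_aa)) {
    abort(paste0("peptide length must be CDS codons - 1; mismatch for: ",
                 paste(utils::head(tx$transcript_id[got != n_aa], 5),
                       collapse = ", ")))
  }
  dens <- lapply(seq_len(nrow(tx)), function(i) {
    v <- numeric(tx$length[i])
    v[(tx$cds_start[i] + 1):tx$cds_end[i]] <- 1
    if (nrow(truth$motifs) > 0) {
      pep <- peptides[[tx$transcript_id[i]]]
      for (j in seq_len(nrow(truth$motifs))) {
        hits <- gregexpr(truth$motifs$motif[j], pep, fixed = TRUE)[[1]]
        hits <- hits[hits > 0]
        for (h in hits) {
          span <- tx$cds_start[i] + 3L * (h - 1L) + seq_len(9L)
          v[span] <- v[span] * truth$motifs$pause_multiplier[j]
        }
      }
    }
    v
  })
  names(dens) <- tx$transcript_id
  total <- sum(vapply(dens, sum, numeric(1)))
  dens <- lapply(dens, function(v) v * depth / total)
  withr::with_seed(as.integer(seed), {
    if (noise == "poisson") dens <- lapply(dens, function(v) rpois(length(v), v))
  })
  trk <- footprint_track(dens, library_size = sum(vapply(dens, sum, numeric(1))))
  if (as_3prime) {
    trk$density <- lapply(trk$density, function(v) {
      out <- numeric(length(v))
      idx <- seq_along(v) + shift_nt
      keep <- idx <= length(v)
      out[idx[keep]] <- v[keep]
      out
    })
  }
  trk
}

# unimodal allocation of one mRNA across ribosome-weighted fractions whose
# weighted mean load equals te (after blending mass toward the heaviest
# fraction when needed); errors when te exceeds the largest ribosome weight
allocate_fractions <- function(te, r) {
  assert_that(te > 0, "te_true must be > 0")
  if (te > max(r)) {
    abort(sprintf(
      "te_true = %g needs more ribosomes per mRNA than the heaviest fraction (%d)",
      te, max(r)))
  }
  p <- exp(-0.5 * ((r - te) / 1.5)^2) + 1e-3
  p <- p / sum(p)
  m0 <- sum(r * p)
  if (m0 < te) {
    lam <- (te - m0) / (max(r) - m0)
    p <- (1 - lam) * p
    p[which.max(r)] <- p[which.max(r)] + lam
    m0 <- te
  }
  list(p = p, mean_load = m0)
}

#' Simulate a polysome gradient with qPCR readout
#'
#' Builds one gradient whose fractions (80S, 2-mer, ..., `n_fractions`-mer)
#' carry A260 areas, pooled volumes and CT values such that running the full
#' normalization chain ([reconstruct_te()]) returns exactly `te_true` for
#' each target when `noise_sd_ct = 0`; CT values are back-computed through
#' the inverse of that chain. Gaussian noise with standard deviation
#' `noise_sd_ct` (cycles) is added to the target and input CTs.
#'
#' @param te_true Named positive vector: target mRNA -> true TE (mean
#'   ribosomes per mRNA relative to ACT1-normalized input).
#' @param n_fractions Number of pooled fractions (>= 2); fraction i carries
#'   ribosome weight i.
#' @param noise_sd_ct CT noise standard deviation, in cycles.
#' @param seed Integer seed.
#' @param gradient_id Identifier for the gradient.
#' @return A [gradient_dataset()] with a `truth` attribute
#'   (tibble `gradient_id`, `target`, `te_true`).
#' @export
simulate_gradient <- function(te_true, n_fractions = 8L, noise_sd_ct = 0,
                              seed = 1L, gradient_id = "g1") {
  assert_that(n_fractions >= 2, "n_fractions must be >= 2")
  assert_that(!is.null(names(te_true)) && all(te_true > 0),
              "te_true must be a named positive vector")
  r <- seq_len(n_fractions)
  frac_ids <- c("80S", paste0(r[-1], "mer"))

  pooled_volume <- 300 + 60 * (r - 1)                 # uL per pooled fraction
  rt_input_vol <- 25 * (1 + 0.2 * ((r - 1) %% 3))     # uL containing 5 ug RNA
  volcorr <- (pooled_volume / 300) * (25 / rt_input_vol)

  # A260 areas: unimodal, rescaled so every gradient totals 10 units
  a260 <- exp(-0.5 * ((r - n_fractions / 2) / 2)^2) + 0.3
  a260 <- 10 * a260 / sum(a260)
  # 18S distribution deviates from the A260 shares so recovery factors bite
  u18 <- a260 * rep_len(c(0.85, 1.15), n_fractions)
  share_a260 <- a260 / sum(a260)
  share_18s <- u18 / sum(u18)
  rec <- share_a260 / share_18s

  ct_18s <- 12 - log2(u18 / volcorr)
  scale_t <- 1e-3                                     # arbitrary abundance units
  ct_18s_input <- 11

  fr <- tibble(
    gradient_id = gradient_id, fraction_id = frac_ids,
    ribosome_weight = r, a260_area = a260,
    pooled_volume_ul = pooled_volume, rna_extraction_volume_ul = 300,
    rt_input_fraction_volume_ul = rt_input_vol
  )
  ct_rows <- list(tibble(gradient_id = gradient_id, fraction_id = frac_ids,
                         target = "18S", ct = ct_18s),
                  tibble(gradient_id = gradient_id, fraction_id = "input",
                         target = "18S", ct = ct_18s_input),
                  tibble(gradient_id = gradient_id, fraction_id = "input",
                         target = "ACT1", ct = ct_18s_input - log2(1 / 5)))
  withr::with_seed(as.integer(seed), {
    for (tgt in names(te_true)) {
      alloc <- allocate_fractions(te_true[[tgt]], r)
      A <- te_true[[tgt]] / alloc$mean_load            # total fraction amount / D
      a_i <- scale_t * A * alloc$p                     # corrected amounts
      ct_t <- ct_18s - log2(a_i / (volcorr * rec)) +
        rnorm(n_fractions, 0, noise_sd_ct)
      ct_in <- ct_18s_input - log2(scale_t / 5) + rnorm(1, 0, noise_sd_ct)
      ct_rows <- c(ct_rows, list(
        tibble(gradient_id = gradient_id, fraction_id = frac_ids,
               target = tgt, ct = ct_t),
        tibble(gradient_id = gradient_id, fraction_id = "input",
               target = tgt, ct = ct_in)
      ))
    }
  })
  ds <- gradient_dataset(
    fractions = fr,
    ct = bind_rows(ct_rows),
    gradients = tibble(gradient_id = gradient_id,
                       monosome_area = a260[1],
                       polysome_area = sum(a260[-1]))
  )
  attr(ds, "truth") <- tibble(gradient_id = gradient_id,
                              target = names(te_true),
                              te_true = unname(te_true))
  ds
}
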