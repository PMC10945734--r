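#' Relative ribosome occupancy of uORFs
#'
#' RRO of a uORF in one library is its RPF count divided by the host CDS RPF
#' count in the same library (raw counts: numerator and denominator share a
#' library, so size factors cancel). Each uORF also carries the arithmetic
#' mean uORF and CDS RPF counts over all RPF samples considered and a filter
#' flag: `"low_uorf"` when the mean uORF count falls below
#' `config$uorf_min_mean_rpf` (this flag takes precedence), `"low_cds"` when
#' the mean CDS count falls below `config$cds_min_mean_rpf`, `"pass"`
#' otherwise.
#'
#' @param counts A [count_table()] with `region_counts` for every uORF.
#' @param annotation A [genome_annotation()].
#' @param config An [analysis_config()].
#' @param samples Optional character vector restricting the RPF samples used
#'   (defaults to all RPF libraries).
#' @return A tibble of class `"rro_table"`: one row per uORF x sample with
#'   columns `uorf_id`, `transcript_id`, `sample_id`, `uorf_count`,
#'   `cds_count`, `rro`, `mean_uorf_rpf`, `mean_cds_rpf`, `filter_status`.
#' @export
compute_rro <- function(counts, annotation, config = analysis_config(),
                        samples = NULL) {
  stopifnot(inherits(counts, "count_table"))
  assert_that(!is.null(counts$region_counts),
              "counts has no uORF region_counts")
  rc <- counts$region_counts
  missing <- setdiff(annotation$uorfs$uorf_id, rc$uorf_id)
  assert_that(length(missing) == 0,
              paste0("region_counts missing for uORF(s): ",
                     paste(utils::head(missing, 5), collapse = ", ")))
  rpf_samples <- samples %||%
    samples_for(counts, .data$assay == "RPF")
  rpf_samples <- intersect(rpf_samples,
                           setdiff(names(rc), c("uorf_id", "transcript_id")))
  assert_that(length(rpf_samples) > 0, "no RPF samples with region counts")
  host <- counts$counts %>% select(all_of(c("gene", rpf_samples)))
  bad <- setdiff(rc$transcript_id, host$gene)
  assert_that(length(bad) == 0,
              paste0("uORF without a host CDS count: ",
                     paste(utils::head(bad, 5), collapse = ", ")))

  long_u <- rc %>%
    select(all_of(c("uorf_id", "transcript_id", rpf_samples))) %>%
    tidyr::pivot_longer(all_of(rpf_samples), names_to = "sample_id",
                        values_to = "uorf_count")
  long_c <- host %>%
    tidyr::pivot_longer(all_of(rpf_samples), names_to = "sample_id",
                        values_to = "cds_count") %>%
    rename(transcript_id = "gene")
  out <- long_u %>%
    left_join(long_c, by = c("transcript_id", "sample_id")) %>%
    mutate(rro = if_else(.data$cds_count > 0,
                         .data$uorf_count / .data$cds_count, NA_real_)) %>%
    group_by(.data$uorf_id) %>%
    mutate(mean_uorf_rpf = mean(.data$uorf_count),
           mean_cds_rpf = mean(.data$cds_count)) %>%
    ungroup() %>%
    mutate(filter_status = case_when(
      .data$mean_uorf_rpf < config$uorf_min_mean_rpf ~ "low_uorf",
      .data$mean_cds_rpf < config$cds_min_mean_rpf ~ "low_cds",
      TRUE ~ "pass"
    ))
  class(out) <- c("rro_table", class(out))
  out
}

#' @method tidy rro_table
#' @export
tidy.rro_table <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "rro_table")
  out
}

#' Test RRO changes between genotypes
#'
#' Reuses the negative-binomial interaction engine of [delta_te()] with
#' (uORF counts, CDS counts) playing the roles of (RPF, RNA): the
#' interaction coefficient is the log2 change in uORF/CDS ratio between the
#' contrast's cells. Only uORFs passing the [compute_rro()] filters (over
#' the contrast's samples) are tested. Size factors come from the CDS
#' counts and are applied to both count layers.
#'
#' @param counts A [count_table()] with `region_counts`.
#' @param contrast A [contrast_spec()]; both cells must share an assay
#'   design with >= 2 replicates.
#' @param config An [analysis_config()].
#' @param annotation A [genome_annotation()] (used for filtering).
#' @return A tibble of class `"te_contrast"` keyed by `gene = uorf_id`.
#' @export
delta_rro <- function(counts, contrast, config = analysis_config(),
                      annotation = NULL) {
  stopifnot(inherits(counts, "count_table"), inherits(contrast, "contrast_spec"))
  assert_that(!is.null(counts$region_counts), "counts has no region_counts")
  d <- counts$design %>%
    mutate(cell = cell_label(.data$genotype, .data$condition)) %>%
    filter(.data$assay == "RPF")
  num_cell <- cell_label(contrast$numerator[["genotype"]],
                         contrast$numerator[["condition"]])
  den_cell <- cell_label(contrast$denominator[["genotype"]],
                         contrast$denominator[["condition"]])
  d <- d %>% filter(.data$cell %in% c(num_cell, den_cell))
  assert_that(all(c(num_cell, den_cell) %in% d$cell),
              "contrast cell missing from design")
  reps <- d %>% dplyr::count(.data$cell)
  assert_that(all(reps$n >= 2), "need >= 2 replicates per cell")

  rc <- counts$region_counts
  rpf_samples <- d$sample_id
  # apply the mean-count filters over the contrast's combined samples
  if (!is.null(annotation)) {
    rro <- compute_rro(counts, annotation, config, samples = rpf_samples)
    keep_ids <- rro %>% filter(.data$filter_status == "pass") %>%
      distinct(.data$uorf_id) %>% pull("uorf_id")
  } else {
    mu_u <- rowMeans(as.matrix(rc[rpf_samples]))
    mu_c <- rowMeans(as.matrix(
      counts$counts[match(rc$transcript_id, counts$counts$gene), rpf_samples]))
    keep_ids <- rc$uorf_id[mu_u >= config$uorf_min_mean_rpf &
                             mu_c >= config$cds_min_mean_rpf]
  }
  rc <- rc %>% filter(.data$uorf_id %in% keep_ids)
  assert_that(nrow(rc) > 0, "no uORF passes the mean-count filters")

  # stack uORF and CDS counts as two assay layers over the same libraries
  cds <- counts$counts[match(rc$transcript_id, counts$counts$gene),
                       rpf_samples]
  names(cds) <- paste0(rpf_samples, "..CDS")
  uo <- rc[rpf_samples]
  names(uo) <- paste0(rpf_samples, "..uORF")
  stacked <- dplyr::bind_cols(tibble(gene = rc$uorf_id), cds, uo)

  design2 <- bind_rows(
    d %>% mutate(sample_id = paste0(.data$sample_id, "..CDS"), assay = "CDS"),
    d %>% mutate(sample_id = paste0(.data$sample_id, "..uORF"), assay = "uORF")
  )
  # size factors from the CDS layer, shared by both layers of a library
  cds_m <- as.matrix(cds)
  keep <- rowSums(cds_m > 0) == ncol(cds_m)
  assert_that(any(keep), "no uORF host with all-positive CDS counts")
  lm_ <- log(cds_m[keep, , drop = FALSE])
  s <- apply(exp(lm_ - rowMeans(lm_)), 2, median)
  s <- s / geomean(s)
  sf <- c(setNames(s, names(cds)), setNames(s, names(uo)))

  delta_te_fit(stacked, design2, num_cell, config, method = "wald",
               contrast_name = paste0("RRO:", contrast$name),
               assay_levels = c("CDS", "uORF"), sf = sf)
}

#' Summarize TE changes for gene groups against the translatome
#'
#' For each named group, reports the median log2 effect and a two-sided
#' Mann-Whitney U p-value comparing the group's effects with the background
#' of all tested genes (by default including the group, matching how
#' box-plot comparisons against "all mRNAs" are usually drawn).
#'
#' @param result A `te_contrast` tibble.
#' @param groups Named list of character vectors of gene ids.
#' @param background `"all"` (group included) or `"disjoint"`.
#' @return A tibble of class `"group_te_summary"` with columns `group`, `n`,
#'   `median_log2_effect`, `mannwhitney_p`.
#' @export
group_te_summary <- function(result, groups, background = c("all", "disjoint")) {
  background <- match.arg(background)
  assert_that(is.list(groups) && !is.null(names(groups)),
              "groups must be a named list of gene id vectors")
  res <- as_tibble(result) %>% filter(.data$status == "tested")
  out <- purrr::imap_dfr(groups, function(genes, nm) {
    assert_that(length(genes) > 0, paste0("empty group: ", nm))
    in_grp <- res %>% filter(.data$gene %in% genes)
    assert_that(nrow(in_grp) > 0,
                paste0("group '", nm, "' has no tested genes"))
    bg <- if (background == "all") res else res %>%
      filter(!(.data$gene %in% genes))
    pw <- wilcox.test(in_grp$log2_effect, bg$log2_effect,
                      alternative = "two.sided", exact = NULL)$p.value
    tibble(group = nm, n = nrow(in_grp),
           median_log2_effect = median(in_grp$log2_effect),
           mannwhitney_p = pw)
  })
  class(out) <- c("group_te_summary", class(out))
  out
}
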