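#' Shift a raw 3'-end footprint track to ribosome positions
#'
#' Moves the count recorded at nucleotide i to i - `shift_nt`; counts that
#' would land below position 0 are dropped (and counted in the
#' `dropped_reads` attribute). With the default 18-nt shift the first codon
#' of a tripeptide motif sits in the ribosomal E site.
#'
#' @param track A [footprint_track()] of 3'-end assignments.
#' @param shift_nt Non-negative shift in nt.
#' @param verbose Emit a message with the number of dropped reads.
#' @return A [footprint_track()] with attribute `dropped_reads`.
#' @export
shift_assign <- function(track, shift_nt = 18L, verbose = FALSE) {
  stopifnot(inherits(track, "footprint_track"))
  assert_that(shift_nt >= 0, "shift_nt must be >= 0")
  shift_nt <- as.integer(shift_nt)
  dropped <- 0
  dens <- lapply(track$density, function(v) {
    if (shift_nt == 0L) return(v)
    dropped <<- dropped + sum(v[seq_len(min(shift_nt, length(v)))])
    out <- numeric(length(v))
    if (shift_nt < length(v)) {
      out[seq_len(length(v) - shift_nt)] <- v[(shift_nt + 1):length(v)]
    }
    out
  })
  if (verbose && dropped > 0) {
    inform(sprintf("shift_assign: dropped %.0f reads below position 0", dropped))
  }
  out <- footprint_track(dens, library_size = track$library_size)
  attr(out, "dropped_reads") <- dropped
  out
}

#' Enumerate tripeptide motif occurrences with window filtering
#'
#' The tripeptide starting at codon k (E-site codon) occupies the 9-nt span
#' \[cds_start + 3k, cds_start + 3k + 9). Occurrences whose +/- `window_nt`
#' flanks extend outside the CDS are excluded.
#'
#' @param annotation A [genome_annotation()].
#' @param peptides Named character vector of peptides (stop excluded), one
#'   per transcript; length must be CDS codons - 1.
#' @param window_nt Flank half-width in nt.
#' @return A tibble with columns `motif`, `transcript_id`, `codon`,
#'   `span_start`, `span_end`.
#' @export
motif_sites <- function(annotation, peptides, window_nt = 50L) {
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
  purrr::map_dfr(seq_len(nrow(tx)), function(i) {
    pep <- peptides[[tx$transcript_id[i]]]
    n_codons <- nchar(pep) - 2L
    if (n_codons < 1L) return(NULL)
    k <- 0:(n_codons - 1L)
    span_start <- tx$cds_start[i] + 3L * k
    span_end <- span_start + 9L
    keep <- (span_start - window_nt >= tx$cds_start[i]) &
      (span_end + window_nt <= tx$cds_end[i])
    if (!any(keep)) return(NULL)
    k <- k[keep]
    tibble(
      motif = substring(pep, k + 1L, k + 3L),
      transcript_id = tx$transcript_id[i],
      codon = k,
      span_start = span_start[keep],
      span_end = span_end[keep]
    )
  })
}

#' Tripeptide pause scores
#'
#' Each occurrence is scored as the mean rpm over its 9-nt motif span
#' divided by the mean rpm over the +/- `window_nt` flanks (the motif span
#' itself excluded by default). Occurrences with a zero flank mean are
#' skipped (counted in the `n_skipped` attribute). Per motif, `mean_score`
#' is the arithmetic mean over surviving occurrences, and motifs observed
#' fewer than `config$min_motif_occurrences` times are flagged
#' `included = FALSE`.
#'
#' @param track A shifted [footprint_track()].
#' @param sites Occurrence table from [motif_sites()] on the same annotation.
#' @param config An [analysis_config()]; `pause_numerator = "a_site"`
#'   scores the third codon alone instead of the whole span.
#' @return A tibble of class `"pause_score_table"` with columns `motif`,
#'   `mean_score`, `n_occurrences`, `included`.
#' @export
pause_scores <- function(track, sites, config = analysis_config()) {
  stopifnot(inherits(track, "footprint_track"))
  assert_that(nrow(sites) > 0, "no motif occurrences to score")
  w <- config$window_nt
  rpm <- track_rpm(track)
  cums <- lapply(rpm, function(v) c(0, cumsum(v)))
  span_sum <- function(id, from, to) {  # 0-based half-open
    cs <- cums[[id]]
    cs[to + 1L] - cs[from + 1L]
  }
  scores <- sites %>%
    group_by(.data$transcript_id) %>%
    mutate(
      num_from = if (config$pause_numerator == "span") .data$span_start
                 else .data$span_start + 6L,
      num_to = .data$span_end,
      num_len = .data$num_to - .data$num_from,
      num = span_sum(.data$transcript_id[1], .data$num_from, .data$num_to) /
        .data$num_len,
      flank = if (config$flank_excludes_motif) {
        (span_sum(.data$transcript_id[1], .data$span_start - w, .data$span_start) +
           span_sum(.data$transcript_id[1], .data$span_end, .data$span_end + w)) /
          (2 * w)
      } else {
        span_sum(.data$transcript_id[1], .data$span_start - w, .data$span_end + w) /
          (2 * w + 9)
      }
    ) %>%
    ungroup()
  n_skipped <- sum(scores$flank == 0)
  out <- scores %>%
    group_by(.data$motif) %>%
    summarise(
      mean_score = mean((.data$num / .data$flank)[.data$flank > 0]),
      n_occurrences = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(mean_score = if_else(is.nan(.data$mean_score), NA_real_,
                                .data$mean_score),
           included = .data$n_occurrences >= config$min_motif_occurrences)
  class(out) <- c("pause_score_table", class(out))
  attr(out, "n_skipped") <- n_skipped
  out
}

# span_sum inside mutate needs vectorization over rows of one transcript
# (handled because `cums` indexing is vectorized)

#' Pair two pause-score tables for comparison
#'
#' Inner-joins the motifs included in both tables; optionally flags motifs
#' whose A-site residue (third position, E-site-first convention) matches
#' `a_site_residue`.
#'
#' @param table_a,table_b `pause_score_table` objects from the same
#'   annotation.
#' @param a_site_residue Optional single amino-acid letter.
#' @return A tibble of class `"pause_comparison"` with columns `motif`,
#'   `score_a`, `score_b`, `ratio_b_a`, `a_site_flag`.
#' @export
compare_pause <- function(table_a, table_b, a_site_residue = NULL) {
  a <- as_tibble(table_a) %>% filter(.data$included, !is.na(.data$mean_score))
  b <- as_tibble(table_b) %>% filter(.data$included, !is.na(.data$mean_score))
  joined <- inner_join(
    a %>% select(motif = "motif", score_a = "mean_score"),
    b %>% select(motif = "motif", score_b = "mean_score"),
    by = "motif"
  )
  assert_that(nrow(joined) > 0, "no motifs included in both tables")
  out <- joined %>%
    mutate(ratio_b_a = .data$score_b / .data$score_a,
           a_site_flag = if (is.null(a_site_residue)) FALSE else
             substring(.data$motif, 3L, 3L) == a_site_residue)
  class(out) <- c("pause_comparison", class(out))
  out
}

#' Read / write peptide sequences as FASTA
#'
#' @param path FASTA file of amino-acid sequences named by transcript id.
#' @return Named character vector of peptides.
#' @export
read_peptides_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), names(aa))
}

#' @param peptides Named character vector of peptides.
#' @rdname read_peptides_fasta
#' @export
write_peptides_fasta <- function(peptides, path) {
  aa <- Biostrings::AAStringSet(peptides)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
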