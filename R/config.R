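#' Analysis configuration
#'
#' Bundles every tunable threshold used across the pipeline. Defaults follow
#' the published study design: footprint 3'-end shift of 18 nt (first codon of
#' a tripeptide motif in the E site), a +/- 50 nt pause-score window, the
#' 100-occurrence motif floor, uORF filters of mean uORF RPF >= 2 and mean CDS
#' RPF >= 32, FDR thresholds of 0.01 (strict) and 0.25 (loose), and the
#' 1.41-fold TE-change cut used for group selection.
#'
#' @param shift_nt 3'-end shift applied to raw footprint tracks, in nt.
#' @param window_nt Half-width of the pause-score background window, in nt.
#' @param min_motif_occurrences Minimum occurrences for a tripeptide motif to
#'   be reported (`included = TRUE`).
#' @param uorf_min_mean_rpf Minimum mean uORF RPF count over the combined
#'   samples for a uORF to pass filtering.
#' @param cds_min_mean_rpf Minimum mean CDS RPF count over the combined
#'   samples for the host gene.
#' @param fdr_strict,fdr_loose Strict and loose BH FDR thresholds.
#' @param fold_threshold Fold-change cut for [select_by_fold()] (strict `>`).
#' @param classifier_down_log2 Log2 threshold at or below which a TE change
#'   counts as an appreciable reduction (must be <= 0).
#' @param classifier_lesser_log2 Log2 threshold at or above which a TE change
#'   counts as "lesser reduction, no change, or increase" (must be <= 0).
#' @param dispersion_shrinkage Weight in \[0, 1\] pulling per-gene
#'   method-of-moments dispersion estimates toward the mean-dispersion trend.
#' @param pseudocount Pseudocount added to normalized counts when computing
#'   per-sample TE (default 0: zero-RNA genes are excluded, not patched).
#' @param pause_numerator Either `"span"` (mean rpm over the 9-nt motif span,
#'   default) or `"a_site"` (the A-site codon alone).
#' @param flank_excludes_motif Should the background window exclude the motif
#'   span itself? Default `TRUE`.
#' @param rng_seed Optional integer seed recorded alongside results.
#'
#' @return A list with class `"analysis_config"`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$shift_nt
analysis_config <- function(shift_nt = 18L,
                            window_nt = 50L,
                            min_motif_occurrences = 100L,
                            uorf_min_mean_rpf = 2,
                            cds_min_mean_rpf = 32,
                            fdr_strict = 0.01,
                            fdr_loose = 0.25,
                            fold_threshold = 1.41,
                            classifier_down_log2 = -0.5,
                            classifier_lesser_log2 = -0.25,
                            dispersion_shrinkage = 0.5,
                            pseudocount = 0,
                            pause_numerator = c("span", "a_site"),
                            flank_excludes_motif = TRUE,
                            rng_seed = NULL) {
  pause_numerator <- match.arg(pause_numerator)
  assert_scalar_number(shift_nt, "shift_nt", min = 0)
  assert_scalar_number(window_nt, "window_nt", min = 0, strict_min = TRUE)
  assert_scalar_number(min_motif_occurrences, "min_motif_occurrences", min = 0, strict_min = TRUE)
  assert_scalar_number(uorf_min_mean_rpf, "uorf_min_mean_rpf", min = 0, strict_min = TRUE)
  assert_scalar_number(cds_min_mean_rpf, "cds_min_mean_rpf", min = 0, strict_min = TRUE)
  assert_scalar_number(fdr_strict, "fdr_strict", min = 0, strict_min = TRUE)
  assert_scalar_number(fdr_loose, "fdr_loose", min = 0, strict_min = TRUE)
  assert_scalar_number(fold_threshold, "fold_threshold", min = 0, strict_min = TRUE)
  assert_that(classifier_down_log2 <= 0, "`classifier_down_log2` must be <= 0")
  assert_that(classifier_lesser_log2 <= 0, "`classifier_lesser_log2` must be <= 0")
  assert_that(dispersion_shrinkage >= 0 && dispersion_shrinkage <= 1,
              "`dispersion_shrinkage` must be in [0, 1]")
  assert_scalar_number(pseudocount, "pseudocount", min = 0)
  structure(
    list(
      shift_nt = as.integer(shift_nt),
      window_nt = as.integer(window_nt),
      min_motif_occurrences = as.integer(min_motif_occurrences),
      uorf_min_mean_rpf = uorf_min_mean_rpf,
      cds_min_mean_rpf = cds_min_mean_rpf,
      fdr_strict = fdr_strict,
      fdr_loose = fdr_loose,
      fold_threshold = fold_threshold,
      classifier_down_log2 = classifier_down_log2,
      classifier_lesser_log2 = classifier_lesser_log2,
      dispersion_shrinkage = dispersion_shrinkage,
      pseudocount = pseudocount,
      pause_numerator = pause_numerator,
      flank_excludes_motif = isTRUE(flank_excludes_motif),
      rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
    ),
    class = "analysis_config"
  )
}

#' Read or write an analysis configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns an [analysis_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(analysis_config)))
  assert_that(length(unknown) == 0,
              paste0("unknown config fields: ", paste(unknown, collapse = ", ")))
  do.call(analysis_config, vals)
}

#' @param config An [analysis_config()].
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
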