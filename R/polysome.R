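#' Polysome-gradient dataset
#'
#' One or more sucrose-gradient runs with, per pooled fraction, the ribosome
#' weight (1 for 80S monosomes, 2 for disomes, ...), the A260 area under its
#' peak, the pooled volume, the RNA-extraction aliquot volume (default 300
#' uL) and the volume of extracted RNA containing the 5 ug used for reverse
#' transcription; plus qPCR CT values for target mRNAs and 18S rRNA in each
#' fraction and in the unfractionated input extract.
#'
#' @param fractions Tibble: `gradient_id`, `fraction_id`, `ribosome_weight`,
#'   `a260_area`, `pooled_volume_ul`, `rna_extraction_volume_ul`,
#'   `rt_input_fraction_volume_ul`.
#' @param ct Tibble: `gradient_id`, `fraction_id` (`"input"` for the
#'   unfractionated extract), `target`, `ct`.
#' @param gradients Tibble: `gradient_id`, `monosome_area`, `polysome_area`;
#'   derived from `fractions` when omitted.
#' @return An object of class `"gradient_dataset"`.
#' @export
gradient_dataset <- function(fractions, ct, gradients = NULL) {
  fractions <- as_tibble(fractions)
  ct <- as_tibble(ct)
  reqf <- c("gradient_id", "fraction_id", "ribosome_weight", "a260_area",
            "pooled_volume_ul", "rna_extraction_volume_ul",
            "rt_input_fraction_volume_ul")
  assert_that(all(reqf %in% names(fractions)),
              paste("fractions must have columns:", paste(reqf, collapse = ", ")))
  assert_that(all(c("gradient_id", "fraction_id", "target", "ct") %in% names(ct)),
              "ct must have columns gradient_id, fraction_id, target, ct")
  assert_that(all(fractions$ribosome_weight >= 1 &
                    is_wholenumber(fractions$ribosome_weight)),
              "ribosome_weight must be an integer >= 1")
  vols <- c("pooled_volume_ul", "rna_extraction_volume_ul",
            "rt_input_fraction_volume_ul")
  for (v in vols) assert_that(all(fractions[[v]] > 0),
                              paste0(v, " must be > 0"))
  inc <- fractions %>%
    group_by(.data$gradient_id) %>%
    summarise(ok = all(diff(.data$ribosome_weight) > 0), .groups = "drop")
  assert_that(all(inc$ok),
              "ribosome_weight must be strictly increasing along fractions")
  if (is.null(gradients)) {
    gradients <- fractions %>%
      group_by(.data$gradient_id) %>%
      summarise(monosome_area = sum(.data$a260_area[.data$ribosome_weight == 1]),
                polysome_area = sum(.data$a260_area[.data$ribosome_weight > 1]),
                .groups = "drop")
  }
  structure(list(fractions = fractions, ct = ct,
                 gradients = as_tibble(gradients)),
            class = "gradient_dataset")
}

#' @export
print.gradient_dataset <- function(x, ...) {
  cat(sprintf("<gradient_dataset> %d gradient(s), %d fractions, %d targets\n",
              nrow(x$gradients), nrow(x$fractions),
              length(setdiff(unique(x$ct$target), "18S"))))
  invisible(x)
}

#' Combine gradient datasets
#' @param ... `gradient_dataset` objects.
#' @return A single [gradient_dataset()].
#' @export
bind_gradients <- function(...) {
  dots <- list(...)
  stopifnot(all(vapply(dots, inherits, logical(1), "gradient_dataset")))
  out <- gradient_dataset(
    fractions = bind_rows(lapply(dots, `[[`, "fractions")),
    ct = bind_rows(lapply(dots, `[[`, "ct")),
    gradients = bind_rows(lapply(dots, `[[`, "gradients"))
  )
  truths <- purrr::compact(lapply(dots, attr, "truth"))
  if (length(truths) > 0) attr(out, "truth") <- bind_rows(truths)
  out
}

#' Read qPCR plate and fraction-metadata CSV files
#'
#' @param ct_path CSV with columns `gradient_id`, `fraction_id` (`"input"`
#'   allowed), `target`, `ct`.
#' @param fractions_path CSV with the columns of
#'   [gradient_dataset()]`$fractions` (missing
#'   `rna_extraction_volume_ul` defaults to 300).
#' @return A [gradient_dataset()].
#' @export
read_gradient_csv <- function(ct_path, fractions_path) {
  ct <- readr::read_csv(ct_path, show_col_types = FALSE, progress = FALSE)
  fr <- readr::read_csv(fractions_path, show_col_types = FALSE, progress = FALSE)
  if (!"rna_extraction_volume_ul" %in% names(fr)) {
    fr$rna_extraction_volume_ul <- 300
  }
  gradient_dataset(fr, ct)
}

#' @param dataset A [gradient_dataset()].
#' @rdname read_gradient_csv
#' @export
write_gradient_csv <- function(dataset, ct_path, fractions_path) {
  readr::write_csv(dataset$ct, ct_path, progress = FALSE)
  readr::write_csv(dataset$fractions, fractions_path, progress = FALSE)
  invisible(ct_path)
}

#' Bulk polysome-to-monosome ratio
#' @param monosome_area,polysome_area A260 areas (monosome > 0).
#' @return P/M ratio.
#' @export
#' @examples
#' pm_ratio(3, 6)  # 2
pm_ratio <- function(monosome_area, polysome_area) {
  assert_that(all(monosome_area > 0), "monosome_area must be > 0")
  polysome_area / monosome_area
}

#' Relative abundance from qPCR threshold cycles
#'
#' The 2^-CT method against 18S rRNA measured in the same fraction:
#' abundance = 2^-(ct_target - ct_18s).
#'
#' @param ct_target,ct_18s Finite CT values (cycles).
#' @return Relative abundance.
#' @export
#' @examples
#' qpcr_abundance(20, 10)  # 2^-10
qpcr_abundance <- function(ct_target, ct_18s) {
  2^(-(ct_target - ct_18s))
}

#' Volume-correction multiplier for a pooled fraction
#'
#' (pooled volume / RNA-extraction aliquot volume) x (25 uL of extracted RNA
#' / volume of extract containing the 5 ug used for RT).
#'
#' @param pooled_volume_ul Total pooled fraction volume (uL).
#' @param rna_extraction_volume_ul Aliquot taken for RNA extraction
#'   (default 300 uL).
#' @param rt_input_fraction_volume_ul Volume of extracted RNA containing
#'   5 ug (uL).
#' @return Multiplier.
#' @export
#' @examples
#' volume_corrections(600, 300, 25)  # 2
volume_corrections <- function(pooled_volume_ul,
                               rna_extraction_volume_ul = 300,
                               rt_input_fraction_volume_ul = 25) {
  assert_that(all(pooled_volume_ul > 0) && all(rna_extraction_volume_ul > 0) &&
                all(rt_input_fraction_volume_ul > 0), "volumes must be > 0")
  (pooled_volume_ul / rna_extraction_volume_ul) *
    (25 / rt_input_fraction_volume_ul)
}

#' RNA-recovery normalization factor for a fraction
#'
#' Share of total gradient A260 in the fraction divided by the share of
#' total 18S rRNA found in it.
#'
#' @param fraction_a260_share,fraction_18s_share Shares in (0, 1\].
#' @return Multiplier.
#' @export
#' @examples
#' recovery_factor(0.25, 0.5)  # 0.5
recovery_factor <- function(fraction_a260_share, fraction_18s_share) {
  assert_that(all(fraction_18s_share > 0), "18S share must be > 0")
  fraction_a260_share / fraction_18s_share
}

#' Gradient-recovery normalization factors
#'
#' mean(monosome+polysome A260 totals over gradients) / each gradient's
#' total; corrects for run-to-run losses of ribosomal material.
#'
#' @param totals Positive numeric vector of per-gradient totals.
#' @return Numeric vector of multipliers, same order.
#' @export
#' @examples
#' gradient_recovery_factor(c(8, 10, 12))
gradient_recovery_factor <- function(totals) {
  assert_that(length(totals) >= 1 && all(totals > 0),
              "totals must be positive")
  mean(totals) / totals
}

#' Reconstruct per-mRNA TE from a gradient dataset
#'
#' Per fraction i the corrected amount is
#' `a_i = 2^-(ct_target - ct_18s) x volume corrections x recovery factor x
#' gradient-recovery factor`; the TE is `sum(r_i * a_i)` (r_i = ribosomes
#' per mRNA in fraction i) divided by the input amount of the target
#' normalized to ACT1, where input amounts are 2^-dCT values from the
#' unfractionated extract scaled by 5 (RNA was extracted from 1/5 of the
#' input). Fractions with a missing target CT are dropped with a warning;
#' missing input CTs flag the TE as unavailable (NA).
#'
#' @param dataset A [gradient_dataset()].
#' @param target Target mRNA id (must not be `"18S"` or `"ACT1"`).
#' @param input_scale Inverse of the input-extract share used for RNA
#'   extraction (default 5; cancels in the ACT1 ratio but kept explicit).
#' @return A tibble of class `"te_estimate"`: `gradient_id`, `target`, `te`,
#'   `n_fractions_used`.
#' @export
reconstruct_te <- function(dataset, target, input_scale = 5) {
  stopifnot(inherits(dataset, "gradient_dataset"))
  totals <- dataset$gradients$monosome_area + dataset$gradients$polysome_area
  gfac <- setNames(gradient_recovery_factor(totals),
                   dataset$gradients$gradient_id)
  purrr::map_dfr(dataset$gradients$gradient_id, function(gid) {
    fr <- dataset$fractions %>% filter(.data$gradient_id == gid)
    ctg <- dataset$ct %>% filter(.data$gradient_id == gid)
    get_ct <- function(frac, tgt) {
      v <- ctg %>% filter(.data$fraction_id == frac, .data$target == tgt) %>%
        pull("ct")
      if (length(v) == 0 || !is.finite(v[1])) NA_real_ else v[1]
    }
    ct18 <- vapply(fr$fraction_id, get_ct, numeric(1), tgt = "18S")
    ctt <- vapply(fr$fraction_id, get_ct, numeric(1), tgt = target)
    volcorr <- volume_corrections(fr$pooled_volume_ul,
                                  fr$rna_extraction_volume_ul,
                                  fr$rt_input_fraction_volume_ul)
    share_a260 <- fr$a260_area / sum(fr$a260_area)
    s18 <- 2^(-ct18) * volcorr
    share_18s <- s18 / sum(s18, na.rm = TRUE)
    rec <- recovery_factor(share_a260, share_18s)
    a <- qpcr_abundance(ctt, ct18) * volcorr * rec * gfac[[gid]]
    usable <- is.finite(a)
    if (any(!usable)) {
      warn(sprintf("gradient %s: dropping %d fraction(s) with missing CTs for %s",
                   gid, sum(!usable), target))
    }
    in18 <- get_ct("input", "18S")
    in_t <- get_ct("input", target)
    in_act1 <- get_ct("input", "ACT1")
    if (anyNA(c(in18, in_t, in_act1)) || !any(usable)) {
      warn(sprintf("gradient %s: TE unavailable for %s (missing input CTs)",
                   gid, target))
      return(tibble(gradient_id = gid, target = target, te = NA_real_,
                    n_fractions_used = sum(usable)))
    }
    input_norm <- (qpcr_abundance(in_t, in18) * input_scale) /
      (qpcr_abundance(in_act1, in18) * input_scale)
    te <- sum(fr$ribosome_weight[usable] * a[usable]) / input_norm
    tibble(gradient_id = gid, target = target, te = te,
           n_fractions_used = sum(usable))
  }) -> out
  class(out) <- c("te_estimate", class(out))
  out
}

#' Replicate-level TE changes with a between-strain t-test
#'
#' Forms, per strain and replicate, the ratio TE(+drug)/TE(-drug) (pairing
#' by replicate index), reports mean and SEM per strain, and a two-sided
#' Welch t-test of the difference in mean TE change between the two strains.
#' When both ratio sets are constant the p-value is 1 for equal means and 0
#' otherwise.
#'
#' @param estimates Tibble with columns `strain`, `condition`
#'   (`"untreated"`/`"SM"`), `replicate`, `te` (e.g. [reconstruct_te()]
#'   joined with gradient metadata).
#' @return A list of class `"delta_te_summary"`: `$per_strain` (strain,
#'   n, mean_ratio, sem), `$ratios` (per replicate), `$t_p`.
#' @export
summarize_delta_te <- function(estimates) {
  req <- c("strain", "condition", "replicate", "te")
  assert_that(all(req %in% names(estimates)),
              paste("estimates must have columns:", paste(req, collapse = ", ")))
  wide <- as_tibble(estimates) %>%
    select(all_of(req)) %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "te")
  assert_that(all(c("untreated", "SM") %in% names(wide)) &&
                !anyNA(wide$untreated) && !anyNA(wide$SM),
              "unpaired replicates: each (strain, replicate) needs both conditions")
  ratios <- wide %>% mutate(ratio = .data$SM / .data$untreated)
  per_strain <- ratios %>%
    group_by(.data$strain) %>%
    summarise(n = dplyr::n(),
              mean_ratio = mean(.data$ratio),
              sem = sd(.data$ratio) / sqrt(dplyr::n()),
              .groups = "drop")
  assert_that(all(per_strain$n >= 2),
              "need >= 2 replicates per condition per strain")
  strains <- unique(ratios$strain)
  t_p <- NA_real_
  if (length(strains) == 2) {
    x <- ratios$ratio[ratios$strain == strains[1]]
    y <- ratios$ratio[ratios$strain == strains[2]]
    if (sd(x) == 0 && sd(y) == 0) {
      t_p <- if (mean(x) == mean(y)) 1 else 0
    } else {
      t_p <- t.test(x, y, var.equal = FALSE)$p.value
    }
  }
  structure(list(per_strain = per_strain,
                 ratios = ratios %>% select(-"untreated", -"SM"),
                 t_p = t_p),
            class = "delta_te_summary")
}

#' @export
print.delta_te_summary <- function(x, ...) {
  cat("<delta_te_summary>\n")
  print(x$per_strain)
  cat(sprintf("  Welch t-test p = %.4g\n", x$t_p))
  invisible(x)
}

#' @method tidy delta_te_summary
#' @export
tidy.delta_te_summary <- function(x, ...) x$per_strain

#' @method glance delta_te_summary
#' @export
glance.delta_te_summary <- function(x, ...) {
  tibble(n_strains = nrow(x$per_strain), t_p = x$t_p)
}
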