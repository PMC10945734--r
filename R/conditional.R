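#' Assemble per-gene four-contrast TE-change profiles
#'
#' Joins the four standard contrasts (see [standard_contrasts()]): c1 =
#' mutant+SM / WT+SM, c2 = mutant+SM / mutant, c3 = WT+SM / WT, c4 =
#' mutant / WT. Genes excluded from any contrast carry NA there and are
#' labelled `"untested"` by [classify_conditional()].
#'
#' @param c1,c2,c3,c4 `te_contrast` tibbles from [delta_te()].
#' @return A tibble of class `"pattern_profile"` with columns `gene`,
#'   `c1`..`c4`, `q1`..`q4`.
#' @export
pattern_profiles <- function(c1, c2, c3, c4) {
  pick <- function(x, i) {
    as_tibble(x) %>%
      mutate(eff = if_else(.data$status == "tested", .data$log2_effect, NA_real_),
             qv = if_else(.data$status == "tested", .data$q, NA_real_)) %>%
      select("gene", eff, qv) %>%
      setNames(c("gene", paste0("c", i), paste0("q", i)))
  }
  out <- pick(c1, 1) %>%
    inner_join(pick(c2, 2), by = "gene") %>%
    inner_join(pick(c3, 3), by = "gene") %>%
    inner_join(pick(c4, 4), by = "gene")
  class(out) <- c("pattern_profile", class(out))
  out
}

#' Classify genes showing conditional initiation-factor dependence
#'
#' Implements, as an explicit threshold rule, the diagnostic pattern of an
#' appreciable TE reduction both on factor deletion in drug-treated cells
#' (c1) and on drug treatment of deletion cells (c2), with a lesser
#' reduction, no change, or an increase on drug treatment of WT (c3) and on
#' factor deletion alone (c4):
#' `conditional_dependent` iff c1 <= down and c2 <= down and c3 >= lesser
#' and c4 >= lesser and q1 < fdr_loose (the discovery contrast's FDR), with
#' `down = config$classifier_down_log2` and
#' `lesser = config$classifier_lesser_log2`.
#'
#' @param profiles A [pattern_profiles()] tibble.
#' @param config An [analysis_config()].
#' @return The input with an added `label` column
#'   (`conditional_dependent` / `not_conditional` / `untested`).
#' @export
classify_conditional <- function(profiles, config = analysis_config()) {
  req <- c("gene", paste0("c", 1:4), paste0("q", 1:4))
  assert_that(all(req %in% names(profiles)),
              "profiles must come from pattern_profiles()")
  down <- config$classifier_down_log2
  lesser <- config$classifier_lesser_log2
  out <- profiles %>%
    mutate(label = case_when(
      is.na(.data$c1) | is.na(.data$c2) | is.na(.data$c3) | is.na(.data$c4) ~
        "untested",
      .data$c1 <= down & .data$c2 <= down &
        .data$c3 >= lesser & .data$c4 >= lesser &
        .data$q1 < config$fdr_loose ~ "conditional_dependent",
      TRUE ~ "not_conditional"
    ))
  class(out) <- unique(c("pattern_profile", class(out)))
  out
}

#' Hypergeometric overlap enrichment of two gene sets
#'
#' Upper-tail probability of observing at least the realized overlap when
#' `set_a` is drawn from the universe and `set_b` marks successes.
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return A one-row tibble: `k` (overlap), `expected`, `p`.
#' @export
#' @examples
#' # 17 candidates vs 514 uORF-bearing genes among 5482 translated mRNAs
#' u <- sprintf("g%04d", 1:5482)
#' overlap_enrichment(u[1:17], u[c(1:3, 100:610)], u)
overlap_enrichment <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  assert_that(all(set_a %in% universe), "set_a must be contained in universe")
  assert_that(all(set_b %in% universe), "set_b must be contained in universe")
  k <- length(intersect(set_a, set_b))
  n_u <- length(universe)
  tibble(
    k = k,
    expected = length(set_a) * length(set_b) / n_u,
    p = phyper(k - 1, length(set_b), n_u - length(set_b), length(set_a),
               lower.tail = FALSE)
  )
}
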