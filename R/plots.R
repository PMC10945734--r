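#' Volcano plot of a TE (or RRO) contrast
#'
#' @param object A `te_contrast` tibble from [delta_te()] or [delta_rro()].
#' @param fdr FDR threshold drawn as a dashed line and used for colouring.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot te_contrast
#' @export
autoplot.te_contrast <- function(object, fdr = 0.25, ...) {
  d <- as_tibble(object) %>%
    filter(.data$status == "tested") %>%
    mutate(significant = .data$q < fdr)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_effect,
                                  y = -log10(pmax(.data$q, 1e-300)),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(fdr), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(log[2] * Delta * "TE"),
                  y = expression(-log[10] * " FDR"),
                  title = attr(object, "contrast")) +
    ggplot2::theme_minimal()
}

#' Scatterplot of paired tripeptide pause scores
#'
#' @param object A `pause_comparison` from [compare_pause()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot pause_comparison
#' @export
autoplot.pause_comparison <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$score_a, y = .data$score_b,
                               colour = .data$a_site_flag)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "mean pause score (A)", y = "mean pause score (B)") +
    ggplot2::theme_minimal()
}

#' Box plot of TE changes for gene groups versus all mRNAs
#'
#' @param result A `te_contrast` tibble.
#' @param groups Named list of gene id vectors.
#' @return A ggplot object.
#' @export
plot_group_te <- function(result, groups) {
  res <- as_tibble(result) %>% filter(.data$status == "tested")
  d <- bind_rows(
    res %>% mutate(group = "all mRNAs"),
    purrr::imap_dfr(groups, function(g, nm)
      res %>% filter(.data$gene %in% g) %>% mutate(group = nm))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$log2_effect)) +
    ggplot2::geom_boxplot(notch = TRUE, outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(log[2] * Delta * "TE")) +
    ggplot2::theme_minimal()
}

#' Bar plot of reconstructed TEs per gradient
#'
#' @param object A `te_estimate` from [reconstruct_te()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot te_estimate
#' @export
autoplot.te_estimate <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$gradient_id, y = .data$te)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~target) +
    ggplot2::labs(x = "gradient", y = "TE (ribosomes per mRNA / input)") +
    ggplot2::theme_minimal()
}
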