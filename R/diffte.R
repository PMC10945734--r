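#' Specify a contrast between two (genotype, condition) cells
#'
#' @param numerator,denominator Length-2 named character vectors
#'   `c(genotype = , condition = )`.
#' @param name Contrast label; defaults to "numerator/denominator".
#' @param fdr_threshold FDR used by downstream selection helpers.
#' @return An object of class `"contrast_spec"`.
#' @export
#' @examples
#' contrast_spec(c(genotype = "eIF2Ad", condition = "SM"),
#'               c(genotype = "WT", condition = "SM"))
contrast_spec <- function(numerator, denominator, name = NULL,
                          fdr_threshold = 0.25) {
  for (cell in list(numerator, denominator)) {
    assert_that(all(c("genotype", "condition") %in% names(cell)),
                "cells must be c(genotype = , condition = )")
    assert_that(cell[["genotype"]] %in% GENOTYPES &&
                  cell[["condition"]] %in% CONDITIONS,
                "unknown genotype or condition in contrast cell")
  }
  assert_that(!identical(numerator[c("genotype", "condition")],
                         denominator[c("genotype", "condition")]),
              "numerator and denominator cells must differ")
  lbl <- function(cell) {
    paste0(cell[["genotype"]],
           if (cell[["condition"]] == "SM") "+SM" else "")
  }
  structure(
    list(numerator = numerator, denominator = denominator,
         name = name %||% paste0(lbl(numerator), "/", lbl(denominator)),
         fdr_threshold = fdr_threshold),
    class = "contrast_spec"
  )
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat(sprintf("<contrast_spec> %s (FDR %.2g)\n", x$name, x$fdr_threshold))
  invisible(x)
}

#' The four standard contrasts of a 2 x 2 genotype-by-treatment design
#'
#' c1: mutant+SM / WT+SM; c2: mutant+SM / mutant; c3: WT+SM / WT;
#' c4: mutant / WT.
#' @return Named list of [contrast_spec()] objects.
#' @export
standard_contrasts <- function() {
  cell <- function(g, c) c(genotype = g, condition = c)
  list(
    c1 = contrast_spec(cell("eIF2Ad", "SM"), cell("WT", "SM")),
    c2 = contrast_spec(cell("eIF2Ad", "SM"), cell("eIF2Ad", "untreated")),
    c3 = contrast_spec(cell("WT", "SM"), cell("WT", "untreated")),
    c4 = contrast_spec(cell("eIF2Ad", "untreated"), cell("WT", "untreated"))
  )
}

#' Median-of-ratios size factors
#'
#' For each library of the given assay, the size factor is the median over
#' genes (restricted to genes with all-positive counts in that assay) of the
#' ratio of the gene's count to its geometric mean across the assay's
#' libraries; factors are rescaled to geometric mean 1.
#'
#' @param counts A [count_table()].
#' @param assay `"RPF"` or `"RNA"`.
#' @return Named numeric vector of positive size factors.
#' @export
#' @examples
#' ct <- count_table(
#'   tibble::tibble(gene = c("a", "b"), RNA_WT_untreated_a = c(2L, 4L),
#'                  RNA_WT_untreated_b = c(8L, 16L)),
#'   tibble::tibble(sample_id = c("RNA_WT_untreated_a", "RNA_WT_untreated_b"),
#'                  genotype = "WT", condition = "untreated",
#'                  replicate = 1:2, assay = "RNA"))
#' size_factors(ct, "RNA")
size_factors <- function(counts, assay = c("RPF", "RNA")) {
  stopifnot(inherits(counts, "count_table"))
  assay <- match.arg(assay)
  ids <- samples_for(counts, .data$assay == !!assay)
  m <- as.matrix(counts$counts[ids])
  keep <- rowSums(m > 0) == ncol(m)
  assert_that(any(keep), "no gene with all-positive counts for size factors")
  lm_ <- log(m[keep, , drop = FALSE])
  lgeo <- rowMeans(lm_)
  sf <- apply(exp(lm_ - lgeo), 2, median)
  sf <- sf / geomean(sf)
  setNames(sf, ids)
}

# method-of-moments dispersion per gene, shrunk toward an a0 + a1/mu trend
estimate_dispersions <- function(norm_counts, groups, shrinkage = 0.5) {
  ug <- unique(groups)
  n_g <- length(ug)
  m_sum <- 0; a_num <- 0; a_den <- 0
  mu_k <- matrix(0, nrow(norm_counts), n_g)
  raw_num <- numeric(nrow(norm_counts)); raw_den <- numeric(nrow(norm_counts))
  for (k in seq_len(n_g)) {
    idx <- which(groups == ug[k])
    x <- norm_counts[, idx, drop = FALSE]
    mu <- rowMeans(x)
    v <- apply(x, 1, var)
    mu_k[, k] <- mu
    w <- length(idx) - 1
    raw_num <- raw_num + w * (v - mu)
    raw_den <- raw_den + w * mu^2
  }
  alpha_raw <- pmax(raw_num / pmax(raw_den, 1e-12), 1e-8)
  mu_bar <- rowMeans(mu_k)
  fit_ok <- is.finite(alpha_raw) & mu_bar > 0
  if (sum(fit_ok) >= 10 && length(unique(mu_bar[fit_ok])) >= 3) {
    co <- coef(lm(alpha_raw[fit_ok] ~ I(1 / mu_bar[fit_ok])))
    co[is.na(co)] <- 0
    a0 <- max(co[1], 1e-8); a1 <- max(co[2], 0)
  } else {
    a0 <- max(mean(alpha_raw[fit_ok]), 1e-8); a1 <- 0
  }
  trend <- a0 + a1 / pmax(mu_bar, 1e-12)
  pmax(shrinkage * trend + (1 - shrinkage) * alpha_raw, 1e-8)
}

# IRLS fit of a log-link NB GLM with known dispersion and offsets.
# Returns coefficient vector and its covariance (X' W X)^-1.
nb_irls <- function(y, X, offset, alpha, tol = 1e-10, max_iter = 50L) {
  eta <- log(pmax(y, 0.5)) - offset
  beta <- qr.coef(qr(X), eta)
  beta[is.na(beta)] <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    xtw <- t(X * w)
    beta_new <- solve(xtw %*% X, xtw %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta) + offset
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  cov <- solve(t(X * w) %*% X)
  list(beta = drop(beta), cov = cov)
}

#' Test TE changes for one contrast with a negative-binomial interaction model
#'
#' Fits, per gene, a log-link NB GLM over the contrast's samples (both
#' assays, both cells) with terms assay + cell + assay:cell and log size
#' factors as offsets. The assay:cell interaction coefficient is the log
#' fold-change of TE (reported in log2); p-values come from a Wald test
#' (`method = "wald"`) or from enumerating reassignments of replicate units
#' to cells (`method = "perm"`), and q-values from Benjamini-Hochberg over
#' tested genes. Genes with a zero RNA count in any contrasted sample, or an
#' all-zero assay cell, are reported with `status = "excluded"`.
#'
#' Dispersions are per-gene method-of-moments estimates shrunk toward an
#' `a0 + a1/mu` trend (weight `config$dispersion_shrinkage`); with only two
#' replicates per cell the unshrunk estimates are too noisy to use alone.
#'
#' @param counts A [count_table()].
#' @param contrast A [contrast_spec()].
#' @param config An [analysis_config()].
#' @param method `"wald"` (default) or `"perm"`.
#' @return A tibble of class `"te_contrast"` with columns `gene`,
#'   `log2_effect`, `se`, `p`, `q`, `status`, and attributes `contrast`
#'   and `method`.
#' @export
delta_te <- function(counts, contrast, config = analysis_config(),
                     method = c("wald", "perm")) {
  stopifnot(inherits(counts, "count_table"), inherits(contrast, "contrast_spec"))
  method <- match.arg(method)
  d <- counts$design %>%
    mutate(cell = cell_label(.data$genotype, .data$condition))
  num_cell <- cell_label(contrast$numerator[["genotype"]],
                         contrast$numerator[["condition"]])
  den_cell <- cell_label(contrast$denominator[["genotype"]],
                         contrast$denominator[["condition"]])
  d <- d %>% filter(.data$cell %in% c(num_cell, den_cell))
  assert_that(all(c(num_cell, den_cell) %in% d$cell),
              "contrast cell missing from design")
  reps <- d %>% dplyr::count(.data$cell, .data$assay)
  assert_that(nrow(reps) == 4 && all(reps$n >= 2),
              "need >= 2 replicates per cell per assay")
  delta_te_fit(counts$counts, d, num_cell, config, method,
               contrast_name = contrast$name)
}

# shared fitting engine for delta_te and delta_rro: `design` must have
# sample_id, assay (2 levels, second = numerator assay e.g. RPF or uORF),
# cell; `num_cell` is the numerator cell label
delta_te_fit <- function(count_tbl, design, num_cell, config, method,
                         contrast_name, assay_levels = c("RNA", "RPF"),
                         sf = NULL) {
  ids <- design$sample_id
  m <- as.matrix(count_tbl[ids])
  rownames(m) <- count_tbl$gene
  if (is.null(sf)) {
    sf <- unlist(lapply(assay_levels, function(a) {
      sub <- m[, design$sample_id[design$assay == a], drop = FALSE]
      keep <- rowSums(sub > 0) == ncol(sub)
      assert_that(any(keep), "no gene with all-positive counts for size factors")
      lm_ <- log(sub[keep, , drop = FALSE])
      s <- apply(exp(lm_ - rowMeans(lm_)), 2, median)
      setNames(s / geomean(s), colnames(sub))
    }))
  }
  sf <- sf[ids]

  is_num_assay <- design$assay == assay_levels[2]
  is_num_cell <- design$cell == num_cell
  X <- cbind(1, as.integer(is_num_assay), as.integer(is_num_cell),
             as.integer(is_num_assay & is_num_cell))
  colnames(X) <- c("intercept", "assay", "cell", "interaction")
  offset <- log(sf)
  norm <- sweep(m, 2, sf, "/")
  groups <- paste(design$assay, design$cell)
  alpha <- estimate_dispersions(norm, groups, config$dispersion_shrinkage)

  rna_cols <- which(!is_num_assay)
  zero_rna <- rowSums(m[, rna_cols, drop = FALSE] == 0) > 0
  zero_grp <- rep(FALSE, nrow(m))
  for (g in unique(groups)) {
    sub <- m[, which(groups == g), drop = FALSE]
    zero_grp <- zero_grp | rowSums(sub) == 0
  }
  excluded <- zero_rna | zero_grp

  n_gene <- nrow(m)
  log2eff <- se <- p <- rep(NA_real_, n_gene)
  ln2 <- log(2)
  # Wald statistic referred to a moderated t distribution: with two
  # replicates per cell the plug-in dispersion makes a normal reference
  # anti-conservative in the far tail. Residual df is augmented by prior df
  # reflecting the information borrowed from the mean-dispersion trend
  # (weight w on the trend contributes w/(1-w) * residual df, as in
  # empirical-Bayes variance moderation).
  w_shrink <- min(config$dispersion_shrinkage, 0.95)
  df_resid <- max(nrow(X) - ncol(X), 1) *
    (1 + w_shrink / (1 - w_shrink))
  for (i in which(!excluded)) {
    fit <- nb_irls(m[i, ], X, offset, alpha[i])
    log2eff[i] <- fit$beta[4] / ln2
    se[i] <- sqrt(fit$cov[4, 4]) / ln2
    p[i] <- 2 * stats::pt(-abs(fit$beta[4] / sqrt(fit$cov[4, 4])), df = df_resid)
  }
  if (method == "perm") {
    p[!excluded] <- perm_pvalues(m, X, offset, alpha, design, num_cell,
                                 which(!excluded))
  }
  q <- rep(NA_real_, n_gene)
  q[!excluded] <- bh_fdr(p[!excluded])
  out <- tibble(
    gene = rownames(m),
    log2_effect = log2eff, se = se, p = p, q = q,
    status = if_else(excluded, "excluded", "tested")
  )
  class(out) <- c("te_contrast", class(out))
  attr(out, "contrast") <- contrast_name
  attr(out, "method") <- method
  out
}

# enumerate reassignments of replicate units (assay pairs) to the two cells
perm_pvalues <- function(m, X, offset, alpha, design, num_cell, gene_idx) {
  units <- design %>%
    distinct(.data$cell, .data$replicate) %>%
    arrange(dplyr::desc(.data$cell == num_cell), .data$replicate)
  n_num <- sum(units$cell == num_cell)
  combs <- utils::combn(nrow(units), n_num, simplify = FALSE)
  stats <- matrix(NA_real_, length(gene_idx), length(combs))
  for (ci in seq_along(combs)) {
    relab <- rep("den", nrow(units))
    relab[combs[[ci]]] <- "num"
    unit_key <- paste(units$cell, units$replicate)
    samp_key <- paste(design$cell, design$replicate)
    new_cell <- relab[match(samp_key, unit_key)]
    Xp <- X
    Xp[, 3] <- as.integer(new_cell == "num")
    Xp[, 4] <- Xp[, 2] * Xp[, 3]
    for (j in seq_along(gene_idx)) {
      i <- gene_idx[j]
      fit <- try(nb_irls(m[i, ], Xp, offset, alpha[i]), silent = TRUE)
      if (!inherits(fit, "try-error")) stats[j, ci] <- fit$beta[4]
    }
  }
  obs <- stats[, 1]  # first combination is the observed labelling
  vapply(seq_along(gene_idx), function(j) {
    s <- stats[j, ]
    mean(abs(s) >= abs(obs[j]) - 1e-12, na.rm = TRUE)
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH with the usual monotonicity enforcement (delegates to
#' [stats::p.adjust()] after validating the input).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(pvalues) {
  assert_that(is.numeric(pvalues) && all(is.finite(pvalues)),
              "p-values must be finite numbers")
  assert_that(all(pvalues >= 0 & pvalues <= 1), "p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Select genes by fold change (and optionally FDR)
#'
#' Uses strict inequality: a gene qualifies only if its effect exceeds
#' log2(fold) (direction `"up"`) or falls below -log2(fold) (`"down"`).
#' The conventional ">1.41-fold" selection corresponds to `fold = sqrt(2)`,
#' i.e. a strict cut at half a log2 unit.
#'
#' @param result A `te_contrast` tibble from [delta_te()] / [delta_rro()].
#' @param fold Fold-change threshold (> 1), e.g. `1.41`.
#' @param direction `"up"` or `"down"`.
#' @param fdr Optional FDR cut applied on `q`.
#' @return Character vector of gene ids.
#' @export
select_by_fold <- function(result, fold, direction = c("up", "down"),
                           fdr = NULL) {
  direction <- match.arg(direction)
  assert_that(fold > 1, "fold must be > 1")
  res <- as_tibble(result) %>% filter(.data$status == "tested")
  cut <- log2(fold)
  res <- if (direction == "up") {
    res %>% filter(.data$log2_effect > cut)
  } else {
    res %>% filter(.data$log2_effect < -cut)
  }
  if (!is.null(fdr)) res <- res %>% filter(.data$q < fdr)
  res$gene
}

#' @method tidy te_contrast
#' @export
tidy.te_contrast <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "te_contrast")
  out
}

#' @method glance te_contrast
#' @export
glance.te_contrast <- function(x, config = analysis_config(), ...) {
  t <- as_tibble(x)
  tibble(
    contrast = attr(x, "contrast") %||% NA_character_,
    n_tested = sum(t$status == "tested"),
    n_excluded = sum(t$status == "excluded"),
    n_sig_loose = sum(t$q < config$fdr_loose, na.rm = TRUE),
    n_sig_strict = sum(t$q < config$fdr_strict, na.rm = TRUE)
  )
}
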