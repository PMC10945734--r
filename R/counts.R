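#' Experiment design table
#'
#' @param genotypes,conditions,replicates,assays Levels crossed to build the
#'   default fully factorial design (2 genotypes x 2 conditions x 2
#'   replicates x 2 assays = 16 libraries, mirroring a paired ribosome
#'   profiling / RNA-seq experiment).
#' @return A tibble with columns `sample_id`, `genotype`, `condition`,
#'   `replicate`, `assay`.
#' @export
#' @examples
#' default_design()
default_design <- function(genotypes = GENOTYPES, conditions = CONDITIONS,
                           replicates = 1:2, assays = ASSAYS) {
  d <- tidyr::expand_grid(
    assay = assays, genotype = genotypes,
    condition = conditions, replicate = as.integer(replicates)
  )
  d %>%
    mutate(sample_id = paste(.data$assay, .data$genotype, .data$condition,
                             letters[.data$replicate], sep = "_")) %>%
    select(all_of(c("sample_id", "genotype", "condition", "replicate", "assay")))
}

validate_design <- function(design) {
  design <- as_tibble(design)
  req <- c("sample_id", "genotype", "condition", "replicate", "assay")
  assert_that(all(req %in% names(design)),
              paste("design must have columns:", paste(req, collapse = ", ")))
  assert_that(!anyDuplicated(design$sample_id), "duplicated sample_id in design")
  assert_that(all(design$genotype %in% GENOTYPES),
              paste("genotype must be one of:", paste(GENOTYPES, collapse = ", ")))
  assert_that(all(design$condition %in% CONDITIONS),
              paste("condition must be one of:", paste(CONDITIONS, collapse = ", ")))
  assert_that(all(design$assay %in% ASSAYS),
              paste("assay must be one of:", paste(ASSAYS, collapse = ", ")))
  assert_that(all(is_wholenumber(design$replicate) & design$replicate >= 1),
              "replicate must be an integer >= 1")
  key <- design %>% select(all_of(c("genotype", "condition", "replicate", "assay")))
  assert_that(!anyDuplicated(key),
              "(genotype, condition, replicate, assay) must be unique per sample")
  design %>% mutate(replicate = as.integer(.data$replicate))
}

#' Gene-by-sample count container
#'
#' Holds a gene x sample matrix of non-negative integer read counts (as a
#' tibble with a `gene` column), the sample design, and optionally per-uORF
#' region counts for the RPF libraries. Library sizes default to column sums
#' so rpm values are self-consistent on synthetic data; a `library_size`
#' column in `design` overrides them.
#'
#' @param counts Tibble: column `gene` plus one integer column per sample.
#' @param design Design tibble (see [default_design()]); may carry an
#'   optional `library_size` column.
#' @param region_counts Optional tibble: columns `uorf_id`, `transcript_id`
#'   plus one column per RPF sample.
#' @return An object of class `"count_table"`.
#' @export
count_table <- function(counts, design, region_counts = NULL) {
  counts <- as_tibble(counts)
  assert_that("gene" %in% names(counts), "counts must have a `gene` column")
  design <- validate_design(design)
  sample_cols <- setdiff(names(counts), "gene")
  missing <- setdiff(sample_cols, design$sample_id)
  assert_that(length(missing) == 0,
              paste0("samples in counts missing from design: ",
                     paste(missing, collapse = ", ")))
  assert_that(!anyDuplicated(counts$gene), "duplicated gene ids in counts")
  for (s in sample_cols) {
    v <- counts[[s]]
    assert_that(all(is_wholenumber(v)) && all(v >= 0),
                paste0("counts for sample '", s, "' must be non-negative integers"))
    counts[[s]] <- as.integer(round(v))
  }
  design <- design %>% filter(.data$sample_id %in% sample_cols)
  if (!"library_size" %in% names(design)) design$library_size <- NA_real_
  csums <- vapply(design$sample_id, function(s) sum(as.numeric(counts[[s]])), numeric(1))
  design <- design %>%
    mutate(library_size = if_else(is.na(.data$library_size),
                                  unname(csums[.data$sample_id]),
                                  as.numeric(.data$library_size)))
  assert_that(all(design$library_size > 0), "library_size must be > 0")

  if (!is.null(region_counts)) {
    region_counts <- as_tibble(region_counts)
    assert_that(all(c("uorf_id", "transcript_id") %in% names(region_counts)),
                "region_counts needs `uorf_id` and `transcript_id` columns")
    rc_samples <- setdiff(names(region_counts), c("uorf_id", "transcript_id"))
    assert_that(all(rc_samples %in% design$sample_id),
                "region_counts samples missing from design")
    for (s in rc_samples) {
      v <- region_counts[[s]]
      assert_that(all(is_wholenumber(v)) && all(v >= 0),
                  paste0("region counts for sample '", s, "' must be non-negative integers"))
      region_counts[[s]] <- as.integer(round(v))
    }
  }

  structure(
    list(counts = counts, design = design, region_counts = region_counts),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d genes x %d samples%s\n",
              nrow(x$counts), nrow(x$design),
              if (!is.null(x$region_counts))
                sprintf(", %d uORF region rows", nrow(x$region_counts)) else ""))
  invisible(x)
}

#' @method tidy count_table
#' @export
tidy.count_table <- function(x, ...) {
  x$counts %>%
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "count") %>%
    left_join(x$design, by = "sample_id")
}

#' Samples of a count table matching a genotype/condition/assay
#' @param x A [count_table()].
#' @param ... Passed to [dplyr::filter()] on the design.
#' @return Character vector of sample ids.
#' @export
samples_for <- function(x, ...) {
  stopifnot(inherits(x, "count_table"))
  x$design %>% filter(...) %>% pull("sample_id")
}

#' Read a count table from TSV files
#'
#' @param counts_path Gene x sample TSV with a `gene` column.
#' @param design_path Design TSV with columns `sample_id`, `genotype`,
#'   `condition`, `replicate`, `assay` and optional `library_size`.
#' @param region_counts_path Optional uORF x sample TSV.
#' @return A [count_table()].
#' @export
read_count_table <- function(counts_path, design_path, region_counts_path = NULL) {
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE, progress = FALSE)
  design <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  region <- if (!is.null(region_counts_path)) {
    readr::read_tsv(region_counts_path, show_col_types = FALSE, progress = FALSE)
  }
  count_table(counts, design, region)
}

#' Write a count table (and its design) to TSV
#'
#' @param x A [count_table()].
#' @param counts_path,design_path,region_counts_path Output files; the region
#'   file is only written when region counts are present.
#' @return `counts_path`, invisibly.
#' @export
write_count_table <- function(x, counts_path, design_path,
                              region_counts_path = NULL) {
  stopifnot(inherits(x, "count_table"))
  readr::write_tsv(x$counts %>% arrange(.data$gene), counts_path, progress = FALSE)
  readr::write_tsv(x$design, design_path, progress = FALSE)
  if (!is.null(x$region_counts) && !is.null(region_counts_path)) {
    readr::write_tsv(x$region_counts %>% arrange(.data$uorf_id),
                     region_counts_path, progress = FALSE)
  }
  invisible(counts_path)
}

#' Write any result table as deterministic TSV
#'
#' Columns keep their order, rows are sorted on the first column, and floats
#' round-trip with full precision (relative error < 1e-5 guaranteed, in
#' practice ~1e-15).
#'
#' @param x A data frame (e.g. a tidied contrast result).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  x <- as_tibble(x)
  if (nrow(x) > 0) x <- x[order(x[[1]]), ]
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
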