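#' Transcript annotation with CDS spans and uORF records
#'
#' All coordinates are transcript-relative, 0-based, half-open. GFF3 input
#' (1-based closed) is converted at the boundary by [read_annotation()].
#'
#' @param transcripts Tibble with columns `transcript_id`, `length`,
#'   `cds_start`, `cds_end` (nt offsets on the transcript).
#' @param uorfs Optional tibble with columns `uorf_id`, `transcript_id`,
#'   `start`, `end`, `start_codon_class` (`"AUG"` or `"NCC"`) and
#'   `annotation_source` (`"annotated"`, `"conserved"` or `"functional"`).
#'
#' @return An object of class `"genome_annotation"`: a list with tibbles
#'   `$transcripts` and `$uorfs`.
#' @export
genome_annotation <- function(transcripts, uorfs = NULL) {
  transcripts <- as_tibble(transcripts)
  req <- c("transcript_id", "length", "cds_start", "cds_end")
  assert_that(all(req %in% names(transcripts)),
              paste("transcripts must have columns:", paste(req, collapse = ", ")))
  assert_that(!anyDuplicated(transcripts$transcript_id),
              "duplicated transcript_id in annotation")
  bad <- transcripts %>%
    filter(!(.data$cds_start >= 0 & .data$cds_start < .data$cds_end &
               .data$cds_end <= .data$length))
  if (nrow(bad) > 0) {
    abort(paste0("invalid CDS coordinates for transcript(s): ",
                 paste(utils::head(bad$transcript_id, 5), collapse = ", ")))
  }
  bad3 <- transcripts %>% filter((.data$cds_end - .data$cds_start) %% 3L != 0L)
  if (nrow(bad3) > 0) {
    abort(paste0("CDS length not a multiple of 3 for: ",
                 paste(utils::head(bad3$transcript_id, 5), collapse = ", ")))
  }

  if (is.null(uorfs)) {
    uorfs <- tibble(uorf_id = character(), transcript_id = character(),
                    start = integer(), end = integer(),
                    start_codon_class = character(),
                    annotation_source = character())
  }
  uorfs <- as_tibble(uorfs)
  requ <- c("uorf_id", "transcript_id", "start", "end",
            "start_codon_class", "annotation_source")
  assert_that(all(requ %in% names(uorfs)),
              paste("uorfs must have columns:", paste(requ, collapse = ", ")))
  if (nrow(uorfs) > 0) {
    assert_that(all(uorfs$transcript_id %in% transcripts$transcript_id),
                "uORF references unknown transcript")
    u <- uorfs %>%
      left_join(transcripts, by = "transcript_id")
    bad <- u %>% filter(!(.data$start >= 0 & .data$start < .data$end))
    if (nrow(bad) > 0) {
      abort(paste0("uORF span empty or negative for: ",
                   paste(utils::head(bad$uorf_id, 5), collapse = ", ")))
    }
    bad <- u %>% filter((.data$end - .data$start) %% 3L != 0L)
    if (nrow(bad) > 0) {
      abort(paste0("uORF length not a multiple of 3 for: ",
                   paste(utils::head(bad$uorf_id, 5), collapse = ", ")))
    }
    bad <- u %>% filter(.data$end > .data$cds_end | .data$start >= .data$length)
    if (nrow(bad) > 0) {
      abort(paste0("uORF outside transcript / extends past CDS end: ",
                   paste(utils::head(bad$uorf_id, 5), collapse = ", ")))
    }
    assert_that(all(uorfs$start_codon_class %in% UORF_CLASSES),
                "start_codon_class must be 'AUG' or 'NCC'")
    assert_that(all(uorfs$annotation_source %in% UORF_SOURCES),
                "annotation_source must be annotated/conserved/functional")
    assert_that(!anyDuplicated(uorfs$uorf_id), "duplicated uorf_id")
  }

  structure(
    list(
      transcripts = transcripts %>%
        mutate(across(c("length", "cds_start", "cds_end"), as.integer)) %>%
        select(all_of(req)),
      uorfs = uorfs %>%
        mutate(across(c("start", "end"), as.integer)) %>%
        select(all_of(requ))
    ),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d transcripts, %d uORFs\n",
              nrow(x$transcripts), nrow(x$uorfs)))
  invisible(x)
}

#' @method tidy genome_annotation
#' @export
tidy.genome_annotation <- function(x, ...) x$transcripts

#' Read a transcript annotation from GFF3 or BED12
#'
#' Expects transcript-oriented records: the sequence name is the transcript
#' id and coordinates run 5' to 3' along the transcript. In GFF3, a
#' `transcript`/`mRNA` feature gives the transcript length and a `CDS`
#' feature the coding span; in BED12 the `thick` range is the CDS.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file.
#' @param uorf_path Optional TSV of uORFs with columns `transcript_id`,
#'   `uorf_start`, `uorf_end`, `start_codon_class`, `annotation_source`
#'   (coordinates 0-based half-open, transcript-relative).
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, uorf_path = NULL, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    tx <- gr[type %in% c("transcript", "mRNA")]
    cds <- gr[type == "CDS"]
    assert_that(length(tx) > 0, "no transcript/mRNA features in GFF3")
    assert_that(length(cds) > 0, "no CDS features in GFF3")
    tx_tbl <- tibble(
      transcript_id = as.character(GenomicRanges::seqnames(tx)),
      length = GenomicRanges::end(tx)
    )
    cds_tbl <- tibble(
      transcript_id = as.character(GenomicRanges::seqnames(cds)),
      cds_start = GenomicRanges::start(cds) - 1L,  # 1-based closed -> 0-based half-open
      cds_end = GenomicRanges::end(cds)
    )
    transcripts <- inner_join(tx_tbl, cds_tbl, by = "transcript_id")
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    thick <- gr$thick
    transcripts <- tibble(
      transcript_id = as.character(gr$name),
      length = GenomicRanges::end(gr),
      cds_start = GenomicRanges::start(thick) - 1L,
      cds_end = GenomicRanges::end(thick)
    )
  }
  uorfs <- if (!is.null(uorf_path)) read_uorf_table(uorf_path) else NULL
  genome_annotation(transcripts, uorfs)
}

read_uorf_table <- function(path) {
  u <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("transcript_id", "uorf_start", "uorf_end",
           "start_codon_class", "annotation_source")
  assert_that(all(req %in% names(u)),
              paste("uORF table must have columns:", paste(req, collapse = ", ")))
  bad <- u$uorf_end <= u$uorf_start
  if (any(bad)) {
    ids <- paste0(u$transcript_id[bad], ":", u$uorf_start[bad])
    abort(paste0("uORF end <= start for: ",
                 paste(utils::head(ids, 5), collapse = ", ")))
  }
  u %>%
    mutate(uorf_id = if ("uorf_id" %in% names(u)) .data$uorf_id else
             paste0(.data$transcript_id, "_uorf", dplyr::row_number())) %>%
    rename(start = "uorf_start", end = "uorf_end") %>%
    select(all_of(c("uorf_id", "transcript_id", "start", "end",
                    "start_codon_class", "annotation_source")))
}

#' Write an annotation to GFF3, BED12, and/or a uORF TSV
#'
#' Emits the same transcript-oriented dialect [read_annotation()] consumes.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  tx <- annotation$transcripts
  gr_tx <- GenomicRanges::GRanges(
    seqnames = tx$transcript_id,
    ranges = IRanges::IRanges(start = 1L, end = tx$length),
    strand = "+", type = "transcript", ID = tx$transcript_id
  )
  gr_cds <- GenomicRanges::GRanges(
    seqnames = tx$transcript_id,
    ranges = IRanges::IRanges(start = tx$cds_start + 1L, end = tx$cds_end),
    strand = "+", type = "CDS", ID = paste0(tx$transcript_id, "_CDS"),
    phase = 0L
  )
  gr_tx$phase <- NA_integer_
  rtracklayer::export(c(gr_tx, gr_cds), path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
write_annotation_bed12 <- function(annotation, path) {
  tx <- annotation$transcripts
  gr <- GenomicRanges::GRanges(
    seqnames = tx$transcript_id,
    ranges = IRanges::IRanges(start = 1L, end = tx$length),
    strand = "+",
    name = tx$transcript_id,
    score = 0L,
    thick = IRanges::IRanges(start = tx$cds_start + 1L, end = tx$cds_end),
    blocks = IRanges::IRangesList(lapply(tx$length, function(l)
      IRanges::IRanges(start = 1L, end = l)))
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
write_uorf_tsv <- function(annotation, path) {
  annotation$uorfs %>%
    rename(uorf_start = "start", uorf_end = "end") %>%
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}
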