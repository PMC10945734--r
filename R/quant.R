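#' Per-nucleotide footprint track
#'
#' Stores raw per-nt footprint-assignment counts for one library, as a named
#' list of numeric vectors (one per transcript, transcript orientation), plus
#' the library size. Reads-per-million values are `raw * 1e6 / library_size`.
#'
#' @param density Named list of non-negative numeric vectors.
#' @param library_size Total mapped reads; defaults to the track total.
#' @return An object of class `"footprint_track"`.
#' @export
footprint_track <- function(density, library_size = NULL) {
  assert_that(is.list(density) && !is.null(names(density)),
              "density must be a named list of numeric vectors")
  ok <- vapply(density, function(v) is.numeric(v) && all(v >= 0), logical(1))
  assert_that(all(ok), "track densities must be non-negative")
  total <- sum(vapply(density, sum, numeric(1)))
  library_size <- library_size %||% total
  assert_that(library_size > 0, "library_size must be > 0")
  structure(list(density = density, library_size = library_size),
            class = "footprint_track")
}

#' @export
print.footprint_track <- function(x, ...) {
  cat(sprintf("<footprint_track> %d transcripts, library size %.0f\n",
              length(x$density), x$library_size))
  invisible(x)
}

#' @method tidy footprint_track
#' @export
tidy.footprint_track <- function(x, ...) {
  purrr::map_dfr(names(x$density), function(id) {
    v <- x$density[[id]]
    tibble(transcript_id = id, pos = seq_along(v) - 1L, count = v)
  })
}

#' Convert a track to reads per million
#' @param track A [footprint_track()].
#' @return Named list of rpm vectors.
#' @export
track_rpm <- function(track) {
  lapply(track$density, function(v) v * 1e6 / track$library_size)
}

#' Read / write a footprint track as bedGraph
#'
#' The bedGraph is transcript-oriented: column 1 is the transcript id and
#' intervals are 0-based half-open, as in the genomic format.
#'
#' @param path bedGraph file.
#' @param annotation A [genome_annotation()] supplying transcript lengths.
#' @param library_size Optional override; defaults to the track total.
#' @return A [footprint_track()].
#' @export
read_track_bedgraph <- function(path, annotation, library_size = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tx <- annotation$transcripts
  dens <- setNames(lapply(tx$length, numeric), tx$transcript_id)
  ids <- as.character(GenomicRanges::seqnames(gr))
  assert_that(all(ids %in% tx$transcript_id),
              "bedGraph names unknown transcripts")
  st <- GenomicRanges::start(gr) - 1L
  en <- GenomicRanges::end(gr)
  sc <- gr$score
  for (i in seq_along(gr)) {
    dens[[ids[i]]][(st[i] + 1):en[i]] <- sc[i]
  }
  footprint_track(dens, library_size)
}

#' @param track A [footprint_track()].
#' @rdname read_track_bedgraph
#' @export
write_track_bedgraph <- function(track, path) {
  rows <- purrr::map_dfr(names(track$density), function(id) {
    v <- track$density[[id]]
    nz <- which(v != 0)
    if (length(nz) == 0) return(NULL)
    # collapse runs of equal value into intervals
    brk <- c(TRUE, diff(nz) != 1L | diff(v[nz]) != 0)
    run <- cumsum(brk)
    tibble(chrom = id,
           start = as.integer(tapply(nz, run, min)) - 1L,
           end = as.integer(tapply(nz, run, max)),
           score = as.numeric(tapply(v[nz], run, function(z) z[1])))
  })
  readr::write_tsv(rows, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

region_span <- function(annotation, region) {
  tx <- annotation$transcripts
  if (region %in% tx$transcript_id) {
    i <- match(region, tx$transcript_id)
    return(list(transcript_id = region, start = tx$cds_start[i],
                end = tx$cds_end[i]))
  }
  u <- annotation$uorfs
  if (region %in% u$uorf_id) {
    i <- match(region, u$uorf_id)
    return(list(transcript_id = u$transcript_id[i], start = u$start[i],
                end = u$end[i]))
  }
  abort(paste0("unknown region id: ", region))
}

#' Sum footprint density over a CDS or uORF
#'
#' @param track A [footprint_track()].
#' @param annotation A [genome_annotation()].
#' @param region A transcript id (its CDS span) or a uORF id.
#' @return Integer read count (rounded sum of raw density over the span).
#' @export
#' @examples
#' ann <- simulate_annotation(2, seed = 1)
#' trk <- simulate_track(ann, simulate_peptides(ann),
#'                       simulation_truth(ann$transcripts$transcript_id),
#'                       depth = 1000, noise = "none")
#' count_region(trk, ann, ann$transcripts$transcript_id[1])
count_region <- function(track, annotation, region) {
  sp <- region_span(annotation, region)
  v <- track$density[[sp$transcript_id]]
  assert_that(!is.null(v), paste0("track missing transcript ", sp$transcript_id))
  if (sp$end <= sp$start) return(0L)
  as.integer(round(sum(v[(sp$start + 1):sp$end])))
}

#' Reads per kilobase per million mapped reads
#'
#' @param count Read count over the region.
#' @param region_length Region length in nt (> 0).
#' @param library_size Total mapped reads (> 0).
#' @return rpkm value.
#' @export
#' @examples
#' rpkm(100, 1000, 1e6)  # 100
rpkm <- function(count, region_length, library_size) {
  assert_that(all(region_length > 0), "region_length must be > 0")
  assert_that(all(library_size > 0), "library_size must be > 0")
  count / ((region_length / 1000) * (library_size / 1e6))
}

#' Per-sample translational efficiency
#'
#' TE of gene g in the (genotype, condition, replicate) unit is the
#' size-factor-normalized RPF count divided by the normalized RNA count.
#' Genes with a zero RNA count in any contributing sample are excluded with
#' reason `"zero_rna"` unless a positive `config$pseudocount` is set.
#'
#' @param counts A [count_table()] with paired RPF and RNA samples.
#' @param size_factors Optional named vector of per-sample size factors;
#'   defaults to median-of-ratios factors computed per assay
#'   (see [size_factors()]).
#' @param config An [analysis_config()].
#' @return An object of class `"te_matrix"`: list with `$te` (tibble `gene`,
#'   `genotype`, `condition`, `replicate`, `te`, `log2_te`) and `$excluded`
#'   (tibble `gene`, `reason`).
#' @export
compute_te <- function(counts, size_factors = NULL, config = analysis_config()) {
  stopifnot(inherits(counts, "count_table"))
  d <- counts$design
  if (is.null(size_factors)) {
    size_factors <- c(size_factors(counts, "RPF"), size_factors(counts, "RNA"))
  }
  assert_that(all(d$sample_id %in% names(size_factors)),
              "size_factors must cover every sample")
  pairs <- d %>%
    select(all_of(c("sample_id", "genotype", "condition", "replicate", "assay"))) %>%
    tidyr::pivot_wider(names_from = "assay", values_from = "sample_id")
  assert_that(all(c("RPF", "RNA") %in% names(pairs)) &&
                !anyNA(pairs$RPF) && !anyNA(pairs$RNA),
              "each (genotype, condition, replicate) unit needs both an RPF and an RNA sample")
  pc <- config$pseudocount
  long <- purrr::pmap_dfr(pairs, function(genotype, condition, replicate, RPF, RNA) {
    tibble(gene = counts$counts$gene, genotype = genotype,
           condition = condition, replicate = replicate,
           rpf_norm = counts$counts[[RPF]] / size_factors[[RPF]],
           rna_norm = counts$counts[[RNA]] / size_factors[[RNA]])
  })
  excluded <- long %>%
    filter(.data$rna_norm == 0 & pc == 0) %>%
    distinct(.data$gene) %>%
    mutate(reason = "zero_rna")
  te <- long %>%
    dplyr::anti_join(excluded, by = "gene") %>%
    mutate(te = (.data$rpf_norm + pc) / (.data$rna_norm + pc),
           log2_te = log2(.data$te)) %>%
    select(-"rpf_norm", -"rna_norm")
  structure(list(te = te, excluded = excluded), class = "te_matrix")
}

#' @export
print.te_matrix <- function(x, ...) {
  cat(sprintf("<te_matrix> %d TE values (%d genes excluded)\n",
              nrow(x$te), nrow(x$excluded)))
  invisible(x)
}

#' @method tidy te_matrix
#' @export
tidy.te_matrix <- function(x, ...) x$te
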