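#' Read a transcript annotation (GTF or BED)
#'
#' Parses a GTF (1-based, inclusive) or BED file via rtracklayer and converts
#' coordinates to the package's internal 0-based half-open convention.
#' Biotype is taken from the `gene_biotype` attribute (GTF); for BED, from a
#' `biotype` extra column when present, otherwise inferred from the record
#' name (`lnc*` prefixes become `lncRNA`, all else `protein_coding`).
#' Records with a biotype other than `protein_coding` / `lncRNA` are skipped
#' with a warning. Records are returned sorted per chromosome.
#'
#' @param path Path to the annotation file.
#' @param format `"gtf"` or `"bed"`; inferred from the file extension by
#'   default.
#'
#' @return A tibble with `transcript_id`, `biotype`, `chromosome`, `strand`,
#'   `start`, `end` (0-based half-open), `length`.
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Annotation file not found: %s", path),
          class = "spheroseq_input_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gtf"
  }

  if (format == "gtf") {
    lines <- readLines(path)
    body <- which(!grepl("^#", lines) & nzchar(lines))
    bad <- body[vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L) < 9]
    if (length(bad)) {
      abort(sprintf("Malformed GTF record at line %d of %s (fewer than 9 tab-separated fields).",
                    bad[1], path),
            class = "spheroseq_parse_error")
    }
    if (!length(body)) {
      return(tibble(transcript_id = character(), biotype = character(),
                    chromosome = character(), strand = character(),
                    start = numeric(), end = numeric(), length = numeric()))
    }
    gr <- rtracklayer::import(path, format = "gtf")
    mc <- as.data.frame(GenomicRanges::mcols(gr))
    biotype <- mc$gene_biotype %||% mc$transcript_biotype %||%
      rep(NA_character_, length(gr))
    id <- mc$transcript_id %||% sprintf("record_%d", seq_along(gr))
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    mc <- as.data.frame(GenomicRanges::mcols(gr))
    id <- mc$name %||% sprintf("record_%d", seq_along(gr))
    biotype <- mc$biotype %||%
      ifelse(grepl("^lnc", id, ignore.case = TRUE), "lncRNA", "protein_coding")
  }

  ann <- tibble(
    transcript_id = as.character(id),
    biotype = as.character(biotype),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    # GRanges is 1-based inclusive; internal convention is 0-based half-open
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"

  known <- ann$biotype %in% c("protein_coding", "lncRNA")
  if (any(!known)) {
    warn(sprintf("Skipping %d record(s) with unknown biotype (%s).",
                 sum(!known),
                 paste(unique(ann$biotype[!known]), collapse = ", ")))
    ann <- ann[known, , drop = FALSE]
  }
  ann |>
    dplyr::mutate(length = .data$end - .data$start) |>
    dplyr::arrange(.data$chromosome, .data$start, .data$transcript_id)
}

#' Write an annotation as GTF
#'
#' Emits one `transcript` feature per record with `transcript_id` and
#' `gene_biotype` attributes, converting internal 0-based half-open
#' coordinates to GTF's 1-based inclusive convention. Deterministic:
#' identical input gives a byte-identical file.
#'
#' @param annotation Annotation tibble (see [read_annotation()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  header <- "##gff-version 2"
  if (nrow(annotation) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chromosome,
    ranges = IRanges::IRanges(start = annotation$start + 1, end = annotation$end),
    strand = annotation$strand
  )
  GenomicRanges::mcols(gr)$source <- "spheroseq"
  GenomicRanges::mcols(gr)$type <- "transcript"
  GenomicRanges::mcols(gr)$transcript_id <- annotation$transcript_id
  GenomicRanges::mcols(gr)$gene_biotype <- annotation$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write cluster calls as BED
#'
#' One line per cluster: chromosome, span (0-based half-open, BED's native
#' convention), and a name of the form `cluster_<i>_n<members>`.
#'
#' @param clusters Cluster tibble from [detect_clusters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, path) {
  if (nrow(clusters) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\tcluster_%d_n%d",
                   clusters$chromosome,
                   as.integer(clusters$start), as.integer(clusters$end),
                   seq_len(nrow(clusters)), clusters$n_members)
  writeLines(lines, path)
  invisible(path)
}
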