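#' Nearest protein-coding neighbors of lncRNAs
#'
#' For each queried lncRNA, finds the nearest protein-coding gene(s) on each
#' genomic side plus all overlapping genes, on the same chromosome, within
#' `max_distance`. Distance is measured gene-body to gene-body: the gap
#' between the two intervals, 0 when they overlap (or touch). Equal-distance
#' ties are all returned, each as a separate pair. Strand affects only the
#' reported `orientation`, never the distance.
#'
#' @param annotation Annotation tibble (both biotypes).
#' @param lncrna_ids lncRNA transcript ids to query; default all lncRNAs in
#'   the annotation.
#' @param k_per_side Number of nearest genes returned on each side (ties all
#'   kept). Default 1.
#' @param max_distance Maximum gap in bp for a gene to count as a neighbor
#'   (default 1e6).
#'
#' @return A tibble with one row per (lncRNA, gene) pair: `lncRNA_id`,
#'   `gene_id`, `distance`, `side` (`upstream` = gene at lower coordinates,
#'   `downstream` = higher, `overlapping` when `distance == 0`),
#'   `orientation` (`same_strand` / `opposite_strand`). An lncRNA whose
#'   chromosome holds no coding gene yields no rows.
#' @export
nearest_coding_neighbors <- function(annotation, lncrna_ids = NULL,
                                     k_per_side = 1, max_distance = 1e6) {
  if (k_per_side < 0 || max_distance < 0) {
    abort("`k_per_side` and `max_distance` must be non-negative.",
          class = "spheroseq_parameter_error")
  }
  lnc <- dplyr::filter(annotation, .data$biotype == "lncRNA")
  if (!is.null(lncrna_ids)) {
    lnc <- dplyr::filter(lnc, .data$transcript_id %in% lncrna_ids)
  }
  genes <- dplyr::filter(annotation, .data$biotype == "protein_coding")
  empty <- tibble(lncRNA_id = character(), gene_id = character(),
                  distance = numeric(), side = character(),
                  orientation = character())
  if (nrow(lnc) == 0 || nrow(genes) == 0) return(empty)

  out <- vector("list", nrow(lnc))
  genes_by_chrom <- split(genes, genes$chromosome)
  for (i in seq_len(nrow(lnc))) {
    g <- genes_by_chrom[[lnc$chromosome[i]]]
    if (is.null(g) || nrow(g) == 0) next
    ls <- lnc$start[i]; le <- lnc$end[i]
    # half-open gap: 0 when the intervals overlap or touch
    gap <- pmax(0, pmax(g$start - le, ls - g$end))
    overl <- g$start < le & ls < g$end
    side <- dplyr::case_when(
      gap == 0 ~ "overlapping",
      g$end <= ls ~ "upstream",
      .default = "downstream"
    )
    keep <- gap <= max_distance
    # book-ended (touching) genes have gap 0 and are treated as overlapping
    sel <- (overl | gap == 0) & keep
    for (sd in c("upstream", "downstream")) {
      on_side <- which(side == sd & keep)
      if (length(on_side) && k_per_side > 0) {
        d <- gap[on_side]
        kth <- sort(unique(d))[min(k_per_side, length(unique(d)))]
        sel[on_side[d <= kth]] <- TRUE
      }
    }
    if (!any(sel)) next
    out[[i]] <- tibble(
      lncRNA_id = lnc$transcript_id[i],
      gene_id = g$transcript_id[sel],
      distance = gap[sel],
      side = side[sel],
      orientation = ifelse(g$strand[sel] == lnc$strand[i],
                           "same_strand", "opposite_strand")
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty)
  dplyr::arrange(res, .data$lncRNA_id, .data$distance, .data$gene_id)
}

#' Classify co-regulation of lncRNA/gene pairs
#'
#' Labels each neighbor pair by the regulation classes of its members:
#' `concordant` when both are in the positive class (up or de novo) or both
#' in the negative class (down or switched off); `discordant` when the
#' classes oppose; `none` when either member is unchanged or filtered. The
#' label is symmetric in the two members.
#'
#' @param pairs Neighbor-pair tibble from [nearest_coding_neighbors()].
#' @param calls Regulation calls from [classify_regulation()].
#'
#' @return `pairs` with a `coregulation` column added.
#' @export
classify_coregulation <- function(pairs, calls) {
  if (nrow(pairs) == 0) {
    pairs$coregulation <- character()
    return(pairs)
  }
  lookup <- setNames(as.character(calls$status), calls$transcript_id)
  missing_ids <- setdiff(unique(c(pairs$lncRNA_id, pairs$gene_id)),
                         names(lookup))
  if (length(missing_ids)) {
    abort(sprintf("No regulation call for transcript(s): %s",
                  paste(head(missing_ids, 5), collapse = ", ")),
          class = "spheroseq_lookup_error")
  }
  cls <- function(st) dplyr::case_when(
    st %in% .positive_statuses ~ "positive",
    st %in% .negative_statuses ~ "negative",
    .default = "none"
  )
  a <- cls(lookup[pairs$lncRNA_id])
  b <- cls(lookup[pairs$gene_id])
  pairs$coregulation <- dplyr::case_when(
    a == "none" | b == "none" ~ "none",
    a == b ~ "concordant",
    .default = "discordant"
  )
  pairs
}

#' lncRNAs co-regulated with multiple neighbors
#'
#' Returns the lncRNAs whose number of co-regulated neighboring genes
#' (coregulation not `none`) reaches `min_coregulated`, with their neighbor
#' genes sorted by distance.
#'
#' @param pairs Pair tibble with a `coregulation` column
#'   (see [classify_coregulation()]).
#' @param min_coregulated Minimum number of co-regulated neighbors
#'   (default 2).
#'
#' @return A tibble with `lncRNA_id`, `n_coregulated`, and a `neighbors`
#'   list-column of gene ids ordered by increasing distance.
#' @export
multi_neighbor_lncRNAs <- function(pairs, min_coregulated = 2) {
  co <- dplyr::filter(pairs, .data$coregulation != "none")
  if (nrow(co) == 0) {
    return(tibble(lncRNA_id = character(), n_coregulated = integer(),
                  neighbors = list()))
  }
  co |>
    dplyr::arrange(.data$lncRNA_id, .data$distance, .data$gene_id) |>
    dplyr::group_by(.data$lncRNA_id) |>
    dplyr::summarise(n_coregulated = dplyr::n(),
                     neighbors = list(.data$gene_id),
                     .groups = "drop") |>
    dplyr::filter(.data$n_coregulated >= min_coregulated)
}
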