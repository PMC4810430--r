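#' Detect chromosomal clusters of dysregulated features
#'
#' Scans each chromosome for maximal runs of dysregulated features (status
#' `up`, `down`, `de_novo` or `switched_off`) in which every consecutive pair
#' of run members lies within `window` bp (gap between the two intervals,
#' 0 on overlap). Interleaved unchanged/filtered features do not break a run;
#' only the spacing of the dysregulated members matters. Runs with fewer than
#' `min_members` members are discarded. Clusters never span chromosomes, and
#' no two reported clusters on one chromosome could be merged without
#' violating the window rule (maximality).
#'
#' @param calls Regulation calls from [classify_regulation()].
#' @param annotation Annotation tibble with coordinates for every called
#'   transcript.
#' @param window Maximum gap between consecutive cluster members, bp
#'   (default 1e5).
#' @param min_members Minimum run length reported (default 3).
#'
#' @return A tibble with one row per cluster: `chromosome`, `start`, `end`
#'   (0-based half-open span of the member intervals), `n_members`,
#'   `n_lncRNA`, `n_mRNA`, and a `members` list-column of transcript ids
#'   sorted by coordinate.
#' @export
detect_clusters <- function(calls, annotation, window = 1e5, min_members = 3) {
  if (window < 0 || min_members < 1) {
    abort("`window` must be >= 0 and `min_members` >= 1.",
          class = "spheroseq_parameter_error")
  }
  dys_ids <- calls$transcript_id[as.character(calls$status) %in% .regulated_statuses]
  feats <- annotation |>
    dplyr::filter(.data$transcript_id %in% dys_ids) |>
    dplyr::arrange(.data$chromosome, .data$start, .data$transcript_id)
  empty <- tibble(chromosome = character(), start = numeric(), end = numeric(),
                  n_members = integer(), n_lncRNA = integer(),
                  n_mRNA = integer(), members = list())
  if (nrow(feats) == 0) return(empty)

  res <- feats |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::group_modify(function(df, key) {
      # gap between consecutive dysregulated intervals; a new run starts
      # where the gap exceeds the window
      gap <- df$start[-1] - cummax(df$end)[-nrow(df)]
      run <- cumsum(c(TRUE, gap > window))
      df |>
        dplyr::mutate(run = run) |>
        dplyr::group_by(.data$run) |>
        dplyr::summarise(
          start = min(.data$start), end = max(.data$end),
          n_members = dplyr::n(),
          n_lncRNA = sum(.data$biotype == "lncRNA"),
          n_mRNA = sum(.data$biotype == "protein_coding"),
          members = list(.data$transcript_id),
          .groups = "drop") |>
        dplyr::select(-"run")
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_members >= min_members)
  if (nrow(res) == 0) return(empty)
  dplyr::arrange(res, .data$chromosome, .data$start)
}
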