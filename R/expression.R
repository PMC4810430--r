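#' Relative expression (RPKM)
#'
#' Reads per kilobase of transcript per million mapped reads, the
#' relative-expression proxy that the detection filter's 0.2 cutoff is applied
#' to.
#'
#' @param reads Non-negative read counts (vectorized).
#' @param transcript_length Transcript length in nucleotides; must be > 0.
#' @param library_size Total mapped reads of the library; must be > 0.
#'
#' @return Numeric vector: `reads * 1e9 / (transcript_length * library_size)`.
#'   Zero exactly when `reads` is zero.
#' @export
#' @examples
#' relative_expression(10, 1000, 1e6) # 10
#' relative_expression(3, 1500, 2e7)  # 0.1, below the 0.2 detection cutoff
relative_expression <- function(reads, transcript_length, library_size) {
  if (any(transcript_length <= 0)) {
    abort("`transcript_length` must be positive.", class = "spheroseq_parameter_error")
  }
  if (any(library_size <= 0)) {
    abort("`library_size` must be positive.", class = "spheroseq_parameter_error")
  }
  if (any(reads < 0)) {
    abort("`reads` must be non-negative.", class = "spheroseq_input_error")
  }
  reads * 1e9 / (transcript_length * library_size)
}

#' Detection filter
#'
#' A transcript counts as detected in a condition unless it falls below both
#' cutoffs: relative expression below `min_relexpr` *and* fewer than
#' `min_reads` reads (`semantics = "and"`, the literal reading of the
#' filtering rule). `semantics = "or"` instead requires both cutoffs to be
#' met, i.e. a transcript failing either one is treated as undetected.
#'
#' @param reads Read counts.
#' @param relexpr Relative-expression values (see [relative_expression()]).
#' @param min_relexpr Relative-expression cutoff (default 0.2).
#' @param min_reads Read-count cutoff (default 10).
#' @param semantics `"and"` (default): undetected only when both cutoffs fail.
#'   `"or"`: undetected when either fails.
#'
#' @return Logical vector, `TRUE` where detected.
#' @export
#' @examples
#' is_detected(reads = 5, relexpr = 0.1)  # FALSE: both below
#' is_detected(reads = 15, relexpr = 0.1) # TRUE under "and" semantics
is_detected <- function(reads, relexpr, min_relexpr = 0.2, min_reads = 10,
                        semantics = c("and", "or")) {
  semantics <- match.arg(semantics)
  if (min_relexpr < 0 || min_reads < 0) {
    abort("Detection thresholds must be non-negative.",
          class = "spheroseq_parameter_error")
  }
  below_re <- relexpr < min_relexpr
  below_rd <- reads < min_reads
  if (semantics == "and") !(below_re & below_rd) else !(below_re | below_rd)
}

#' Signed fold change
#'
#' Expression ratio under the negative-reciprocal convention: the ratio
#' `r = mts / mono` is reported as `r` when `r >= 1` and as `-1/r` otherwise,
#' so a 15-fold decrease reads as -15 rather than 0.067. Binary on/off cases
#' (one side zero with no pseudocount) have no finite fold change and must be
#' routed to the de-novo / switched-off classification instead.
#'
#' @param value_mts,value_mono Expression values (counts or relative
#'   expression) for the spheroid and monolayer conditions.
#' @param pseudocount Added to both values before forming the ratio
#'   (default 0).
#'
#' @return Numeric vector of signed fold changes; `abs()` is always >= 1.
#' @export
#' @examples
#' signed_fold_change(30, 10) # +3
#' signed_fold_change(10, 30) # -3
signed_fold_change <- function(value_mts, value_mono, pseudocount = 0) {
  m <- value_mts + pseudocount
  b <- value_mono + pseudocount
  if (any(m <= 0) || any(b <= 0)) {
    abort(paste("Signed fold change is undefined when either value (plus",
                "pseudocount) is zero; binary on/off transcripts are",
                "classified as de_novo / switched_off instead."),
          class = "spheroseq_undefined_fold_error")
  }
  r <- m / b
  ifelse(r >= 1, r, -1 / r)
}

#' Classify per-transcript regulation
#'
#' Applies the detection filter to both conditions and assigns each transcript
#' one of the six statuses in [regulation_statuses()]: `filtered` when
#' undetected in both conditions; `de_novo` when detected only in MTS;
#' `switched_off` when detected only in monolayer; otherwise `up` / `down`
#' when the absolute signed fold change reaches `fc_threshold` (and, when
#' `require_significance = TRUE`, the `significant` column is set), else
#' `unchanged`.
#'
#' @param expression A data frame with columns `transcript_id`, `reads_mono`,
#'   `reads_mts`, `relexpr_mono`, `relexpr_mts`, and optionally `significant`
#'   (logical, externally supplied, e.g. from an edgeR-style test).
#' @param fc_threshold Minimum absolute signed fold change to call up/down
#'   (default 2; must be > 1).
#' @param min_relexpr,min_reads,semantics Detection-filter settings, see
#'   [is_detected()].
#' @param fc_on Basis of the fold change: `"relexpr"` (default; normalizes the
#'   two library depths) or `"reads"` (raw counts).
#' @param require_significance When `TRUE`, up/down additionally requires
#'   `significant == TRUE`; transcripts passing the fold threshold without the
#'   flag are reported `unchanged`.
#' @param pseudocount Passed to [signed_fold_change()].
#'
#' @return A tibble with one row per transcript: `transcript_id`, `status`,
#'   `signed_fold_change` (`NA` for the binary and filtered statuses),
#'   `detected_mono`, `detected_mts`.
#' @export
#' @examples
#' x <- tibble::tibble(
#'   transcript_id = c("a", "b", "c"),
#'   reads_mono = c(10, 0, 10), reads_mts = c(40, 50, 15),
#'   relexpr_mono = c(1, 0, 1), relexpr_mts = c(4, 5, 1.5)
#' )
#' classify_regulation(x)
classify_regulation <- function(expression, fc_threshold = 2,
                                min_relexpr = 0.2, min_reads = 10,
                                semantics = c("and", "or"),
                                fc_on = c("relexpr", "reads"),
                                require_significance = FALSE,
                                pseudocount = 0) {
  semantics <- match.arg(semantics)
  fc_on <- match.arg(fc_on)
  if (fc_threshold <= 1) {
    abort("`fc_threshold` must be > 1.", class = "spheroseq_parameter_error")
  }
  needed <- c("transcript_id", "reads_mono", "reads_mts",
              "relexpr_mono", "relexpr_mts")
  missing_cols <- setdiff(needed, names(expression))
  if (length(missing_cols)) {
    abort(paste0("`expression` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "spheroseq_input_error")
  }
  if (any(expression$reads_mono < 0) || any(expression$reads_mts < 0)) {
    abort("Read counts must be non-negative.", class = "spheroseq_input_error")
  }
  if (require_significance && !"significant" %in% names(expression)) {
    abort("`require_significance = TRUE` needs a `significant` column.",
          class = "spheroseq_input_error")
  }

  det_mono <- is_detected(expression$reads_mono, expression$relexpr_mono,
                          min_relexpr, min_reads, semantics)
  det_mts <- is_detected(expression$reads_mts, expression$relexpr_mts,
                         min_relexpr, min_reads, semantics)

  if (fc_on == "relexpr") {
    v_mts <- expression$relexpr_mts
    v_mono <- expression$relexpr_mono
  } else {
    v_mts <- expression$reads_mts
    v_mono <- expression$reads_mono
  }

  fc <- rep(NA_real_, nrow(expression))
  both <- det_mono & det_mts
  pos <- both & (v_mts + pseudocount > 0) & (v_mono + pseudocount > 0)
  if (any(pos)) {
    fc[pos] <- signed_fold_change(v_mts[pos], v_mono[pos], pseudocount)
  }

  sig <- if (require_significance) {
    isTRUE_v <- expression$significant
    !is.na(isTRUE_v) & isTRUE_v
  } else {
    rep(TRUE, nrow(expression))
  }

  status <- dplyr::case_when(
    !det_mono & !det_mts ~ "filtered",
    det_mts & !det_mono ~ "de_novo",
    det_mono & !det_mts ~ "switched_off",
    !is.na(fc) & fc >= fc_threshold & sig ~ "up",
    !is.na(fc) & fc <= -fc_threshold & sig ~ "down",
    .default = "unchanged"
  )

  tibble(
    transcript_id = expression$transcript_id,
    status = factor(status, levels = .status_levels),
    signed_fold_change = ifelse(status %in% c("up", "down", "unchanged"), fc, NA_real_),
    detected_mono = det_mono,
    detected_mts = det_mts
  )
}

#' Summarize regulation calls
#'
#' Tallies regulation statuses, optionally split by biotype, and reports the
#' positive/negative class percentages the way the study prints them: the
#' positive class is `up + de_novo`, the negative class `down + switched_off`,
#' and percentages are computed over regulated transcripts only
#' (positive + negative), rounded half-up to integers.
#'
#' @param calls A tibble from [classify_regulation()].
#' @param annotation Optional annotation tibble (with `transcript_id`,
#'   `biotype`) used to split the summary by biotype.
#'
#' @return A tibble with columns `biotype` (`"all"` when no annotation is
#'   given), `status`, `n`, `class` (`positive` / `negative` / `none`), and
#'   `pct` (integer percentage of the regulated total for the positive and
#'   negative classes; `NA` for unregulated statuses). When a biotype has no
#'   regulated transcripts its percentages are reported as 0 and the attribute
#'   `"no_regulated"` lists the affected biotypes.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   transcript_id = paste0("t", 1:4),
#'   status = factor(c("up", "de_novo", "down", "unchanged"),
#'                   levels = regulation_statuses())
#' )
#' summarize_regulation(calls)
summarize_regulation <- function(calls, annotation = NULL) {
  if (nrow(calls) == 0) {
    abort("`calls` is empty; nothing to summarize.",
          class = "spheroseq_empty_summary_error")
  }
  df <- tibble(
    transcript_id = calls$transcript_id,
    status = factor(as.character(calls$status), levels = .status_levels)
  )
  if (!is.null(annotation)) {
    df <- dplyr::left_join(df,
      dplyr::select(annotation, "transcript_id", "biotype"),
      by = "transcript_id")
    df$biotype <- dplyr::coalesce(df$biotype, "unknown")
  } else {
    df$biotype <- "all"
  }

  out <- df |>
    dplyr::count(.data$biotype, .data$status, .drop = FALSE) |>
    dplyr::mutate(class = dplyr::case_when(
      as.character(.data$status) %in% .positive_statuses ~ "positive",
      as.character(.data$status) %in% .negative_statuses ~ "negative",
      .default = "none"
    ))

  class_totals <- out |>
    dplyr::filter(.data$class != "none") |>
    dplyr::group_by(.data$biotype, .data$class) |>
    dplyr::summarise(class_n = sum(.data$n), .groups = "drop_last") |>
    dplyr::mutate(reg_total = sum(.data$class_n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(class_pct = ifelse(.data$reg_total > 0,
                                     round_half_up(100 * .data$class_n / .data$reg_total),
                                     0))

  out <- out |>
    dplyr::left_join(class_totals, by = c("biotype", "class")) |>
    dplyr::mutate(pct = ifelse(.data$class == "none", NA_real_, .data$class_pct)) |>
    dplyr::select("biotype", "status", "n", "class", "pct")

  none_reg <- class_totals |>
    dplyr::distinct(.data$biotype, .data$reg_total) |>
    dplyr::filter(.data$reg_total == 0)
  attr(out, "no_regulated") <- none_reg$biotype
  out
}

#' Positive/negative class percentages from class counts
#'
#' Convenience wrapper for reproducing printed tallies directly from class
#' totals: given counts of positively and negatively regulated transcripts
#' (binary subcategories included), returns the integer percentages, rounded
#' half-up, computed over their sum.
#'
#' @param n_positive,n_negative Counts of the positive (up + de novo) and
#'   negative (down + switched off) regulation classes.
#'
#' @return A tibble with one row per class: `class`, `n`, `pct`.
#' @export
#' @examples
#' regulation_percentages(866, 636) # 58 / 42
#' regulation_percentages(921, 201) # 82 / 18
regulation_percentages <- function(n_positive, n_negative) {
  total <- n_positive + n_negative
  if (total <= 0) {
    abort("At least one regulated transcript is required.",
          class = "spheroseq_empty_summary_error")
  }
  tibble(
    class = c("positive", "negative"),
    n = c(n_positive, n_negative),
    pct = round_half_up(100 * c(n_positive, n_negative) / total)
  )
}

#' Transcript-length histogram
#'
#' Bins transcript lengths into the three reporting bins used for regulated
#' lncRNAs (< 1000 nt, 1000-2499 nt, >= 2500 nt) or any custom set of
#' half-open `[lo, hi)` bins.
#'
#' @param lengths Positive transcript lengths in nucleotides, or a data frame
#'   with a `length` column.
#' @param bin_edges Increasing numeric vector of bin edges; the implicit last
#'   edge is `Inf`. Default `c(0, 1000, 2500)`.
#'
#' @return A tibble with `bin` (label), `n`, and `pct` (percentage of the
#'   input, 1 decimal; zero row counts give `pct = 0` on empty input).
#' @export
#' @examples
#' length_histogram(c(500, 1500, 3000))
length_histogram <- function(lengths, bin_edges = c(0, 1000, 2500)) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  if (any(lengths <= 0)) {
    abort("Transcript lengths must be positive.", class = "spheroseq_input_error")
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    abort("`bin_edges` must be strictly increasing.",
          class = "spheroseq_parameter_error")
  }
  edges <- c(bin_edges, Inf)
  labels <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
  idx <- findInterval(lengths, edges)
  idx <- idx[idx >= 1]  # lengths below the first edge are not binned
  n <- tabulate(idx, nbins = length(labels))
  tibble(
    bin = labels,
    n = n,
    pct = if (length(lengths)) round_half_up(100 * n / length(lengths), 1) else rep(0, length(labels))
  )
}
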