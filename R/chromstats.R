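#' Per-chromosome regulation counts
#'
#' Tallies annotated and regulated (dysregulated: up, down, de novo, switched
#' off) transcripts per chromosome and biotype, with up-class/down-class
#' splits. Chromosomes present in the annotation (or the optional length
#' table) but lacking regulated features are still reported with zero counts;
#' the per-chromosome sums conserve the global totals exactly.
#'
#' @param calls Regulation calls from [classify_regulation()]; every
#'   transcript must exist in `annotation`.
#' @param annotation Annotation tibble.
#' @param chromosome_lengths Optional tibble (`chromosome`, `length`) giving
#'   chromosome sizes in bp; lengths default to the maximal annotated end
#'   coordinate per chromosome.
#'
#' @return A tibble with one row per chromosome x biotype: `chromosome`,
#'   `biotype`, `chrom_length`, `n_total`, `n_regulated`, `n_up_class`,
#'   `n_down_class`.
#' @export
per_chromosome_counts <- function(calls, annotation, chromosome_lengths = NULL) {
  missing_ids <- setdiff(calls$transcript_id, annotation$transcript_id)
  if (length(missing_ids)) {
    abort(sprintf("Call(s) without an annotation record: %s",
                  paste(head(missing_ids, 5), collapse = ", ")),
          class = "spheroseq_lookup_error")
  }
  status_of <- setNames(as.character(calls$status), calls$transcript_id)
  df <- annotation |>
    dplyr::mutate(
      status = dplyr::coalesce(status_of[.data$transcript_id], "unchanged"),
      regulated = .data$status %in% .regulated_statuses,
      up_class = .data$status %in% .positive_statuses,
      down_class = .data$status %in% .negative_statuses
    )
  chroms <- union(unique(annotation$chromosome),
                  if (!is.null(chromosome_lengths)) chromosome_lengths$chromosome)
  biotypes <- c("protein_coding", "lncRNA")
  out <- df |>
    dplyr::group_by(.data$chromosome, .data$biotype) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_regulated = sum(.data$regulated),
      n_up_class = sum(.data$up_class),
      n_down_class = sum(.data$down_class),
      .groups = "drop") |>
    tidyr::complete(
      chromosome = chroms, biotype = biotypes,
      fill = list(n_total = 0L, n_regulated = 0L,
                  n_up_class = 0L, n_down_class = 0L))

  len <- if (!is.null(chromosome_lengths)) {
    setNames(chromosome_lengths$length, chromosome_lengths$chromosome)
  } else {
    tapply(annotation$end, annotation$chromosome, max)
  }
  out$chrom_length <- as.numeric(len[out$chromosome])
  out |>
    dplyr::select("chromosome", "biotype", "chrom_length", "n_total",
                  "n_regulated", "n_up_class", "n_down_class") |>
    dplyr::arrange(.data$chromosome, .data$biotype)
}

#' Correlate per-chromosome regulated counts with length or gene density
#'
#' Pearson product-moment correlation between the number of regulated
#' transcripts per chromosome and either the chromosome length (`x =
#' "length"`) or the gene density, i.e. the total annotated transcripts of
#' the biotype on the chromosome (`x = "density"`).
#'
#' @param summaries Per-chromosome tibble from [per_chromosome_counts()].
#' @param x Predictor: `"length"` or `"density"`.
#' @param biotype Restrict to one biotype (`"protein_coding"` or `"lncRNA"`);
#'   `NULL` computes one coefficient per biotype present.
#'
#' @return A tibble with `biotype`, `x`, `r` (Pearson coefficient in
#'   \[-1, 1\]).
#' @export
correlate_counts <- function(summaries, x = c("length", "density"),
                             biotype = NULL) {
  x <- match.arg(x)
  df <- summaries
  if (!is.null(biotype)) df <- dplyr::filter(df, .data$biotype %in% !!biotype)
  df |>
    dplyr::group_by(.data$biotype) |>
    dplyr::group_modify(function(d, key) {
      xv <- if (x == "length") d$chrom_length else d$n_total
      if (nrow(d) < 3) {
        abort("At least 3 chromosomes are required for a correlation.",
              class = "spheroseq_parameter_error")
      }
      if (sd(xv) == 0 || sd(d$n_regulated) == 0) {
        abort("Correlation undefined: constant predictor or response.",
              class = "spheroseq_undefined_correlation_error")
      }
      tibble(x = x, r = cor(xv, d$n_regulated))
    }) |>
    dplyr::ungroup()
}

#' Strand-bias chi-square test
#'
#' Tests whether the +/- strand split of regulated transcripts deviates from
#' the strand split of the annotated background. The default is a 1-df
#' goodness-of-fit test of the regulated counts against the background strand
#' proportions, without continuity correction. `method = "independence"`
#' instead runs the 2x2 independence test on
#' `rbind(regulated, background)` (1 df; Yates correction via `correct`),
#' provided as a sensitivity check.
#'
#' @param regulated Length-2 vector: regulated transcripts on the + and -
#'   strand.
#' @param background Length-2 vector: background (all annotated) transcripts
#'   on the + and - strand.
#' @param method `"gof"` (default) or `"independence"`.
#' @param correct Yates continuity correction for the independence variant
#'   (default `FALSE`).
#'
#' @return An object of class `htest` with `statistic`, `parameter` (df = 1),
#'   and `p.value`.
#' @export
#' @examples
#' strand_bias_test(c(767, 735), c(58271, 53339))
strand_bias_test <- function(regulated, background,
                             method = c("gof", "independence"),
                             correct = FALSE) {
  method <- match.arg(method)
  if (length(regulated) != 2 || length(background) != 2) {
    abort("`regulated` and `background` must each have two strand counts.",
          class = "spheroseq_input_error")
  }
  if (sum(background) == 0 || any(background == 0)) {
    abort("Background strand counts must be positive (zero expected cell).",
          class = "spheroseq_degenerate_table_error")
  }
  if (method == "gof") {
    if (sum(regulated) == 0) {
      abort("No regulated transcripts: the test table is degenerate.",
            class = "spheroseq_degenerate_table_error")
    }
    res <- suppressWarnings(
      chisq.test(regulated, p = background / sum(background)))
    res$method <- "Chi-squared goodness-of-fit of regulated strand split against background proportions"
  } else {
    res <- suppressWarnings(
      chisq.test(rbind(regulated, background), correct = correct))
  }
  res$data.name <- "regulated strand counts vs background"
  res
}
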