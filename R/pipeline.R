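#' Run the full spheroid-transcriptome pipeline
#'
#' Orchestrates the analysis stages on an annotation plus two-condition
#' expression table: regulation classification, per-biotype summary, nearest
#' coding-neighbor assignment for the regulated lncRNAs with co-regulation
#' classes, multi-neighbor lncRNAs, chromosomal cluster detection,
#' per-chromosome distribution statistics with length/density correlations,
#' and the strand-bias test of regulated lncRNAs against the annotated lncRNA
#' background. Deterministic for fixed inputs.
#'
#' @param annotation Annotation tibble (see [read_annotation()] /
#'   [simulate_annotation()]).
#' @param expression Expression tibble (see [simulate_counts()] /
#'   [read_expression_table()]).
#' @param fc_threshold,min_relexpr,min_reads,semantics,fc_on,require_significance
#'   Classification settings, see [classify_regulation()].
#' @param k_per_side,max_distance Neighbor settings, see
#'   [nearest_coding_neighbors()].
#' @param window,min_members Cluster settings, see [detect_clusters()].
#' @param chromosome_lengths Optional chromosome-length tibble, see
#'   [per_chromosome_counts()].
#'
#' @return An object of class `mts_report`: a list with `calls`, `summary`,
#'   `pairs`, `multi_neighbors`, `clusters`, `chromosomes`, `correlations`,
#'   `strand_test`, and `params`. Use [glance()] for a one-row overview,
#'   [tidy()] for the per-transcript calls, and [write_report()] to export
#'   all tables.
#' @export
#' @examples
#' sim <- simulate_mts_experiment(sim_config(n_coding = 60, n_lncRNA = 60,
#'                                           n_up = 6, n_down = 6,
#'                                           n_de_novo = 2, n_switched_off = 2,
#'                                           n_concordant_pairs = 2,
#'                                           n_discordant_pairs = 1,
#'                                           cluster_size = 5, dispersion = 0,
#'                                           seed = 7))
#' rep <- run_pipeline(sim$annotation, sim$expression)
#' glance(rep)
run_pipeline <- function(annotation, expression,
                         fc_threshold = 2, min_relexpr = 0.2, min_reads = 10,
                         semantics = "and", fc_on = "relexpr",
                         require_significance = FALSE,
                         k_per_side = 1, max_distance = 1e6,
                         window = 1e5, min_members = 3,
                         chromosome_lengths = NULL) {
  if (nrow(annotation) == 0 || nrow(expression) == 0) {
    abort("Both `annotation` and `expression` must be non-empty.",
          class = "spheroseq_config_error")
  }
  missing_ids <- setdiff(expression$transcript_id, annotation$transcript_id)
  if (length(missing_ids)) {
    abort(sprintf("Expression entries without annotation: %s",
                  paste(head(missing_ids, 5), collapse = ", ")),
          class = "spheroseq_config_error")
  }

  calls <- classify_regulation(expression, fc_threshold = fc_threshold,
                               min_relexpr = min_relexpr, min_reads = min_reads,
                               semantics = semantics, fc_on = fc_on,
                               require_significance = require_significance)
  summary <- summarize_regulation(calls, annotation)

  regulated_lnc <- annotation |>
    dplyr::semi_join(
      dplyr::filter(calls, as.character(.data$status) %in% .regulated_statuses),
      by = "transcript_id") |>
    dplyr::filter(.data$biotype == "lncRNA")
  pairs <- nearest_coding_neighbors(annotation,
                                    lncrna_ids = regulated_lnc$transcript_id,
                                    k_per_side = k_per_side,
                                    max_distance = max_distance) |>
    classify_coregulation(calls)
  multi <- multi_neighbor_lncRNAs(pairs)
  clusters <- detect_clusters(calls, annotation, window = window,
                              min_members = min_members)
  chromosomes <- per_chromosome_counts(calls, annotation, chromosome_lengths)
  safe_cor <- function(x) {
    tryCatch(correlate_counts(chromosomes, x),
             error = function(e) tibble(
               biotype = unique(chromosomes$biotype), x = x, r = NA_real_))
  }
  correlations <- dplyr::bind_rows(safe_cor("length"), safe_cor("density"))

  lnc_all <- dplyr::filter(annotation, .data$biotype == "lncRNA")
  reg_strand <- c(sum(regulated_lnc$strand == "+"),
                  sum(regulated_lnc$strand == "-"))
  bg_strand <- c(sum(lnc_all$strand == "+"), sum(lnc_all$strand == "-"))
  strand_test <- if (all(bg_strand > 0) && sum(reg_strand) > 0) {
    strand_bias_test(reg_strand, bg_strand)
  } else {
    NULL
  }

  params <- list(fc_threshold = fc_threshold, min_relexpr = min_relexpr,
                 min_reads = min_reads, semantics = semantics, fc_on = fc_on,
                 require_significance = require_significance,
                 k_per_side = k_per_side, max_distance = max_distance,
                 window = window, min_members = min_members)
  structure(
    list(calls = calls, summary = summary, pairs = pairs,
         multi_neighbors = multi, clusters = clusters,
         chromosomes = chromosomes, correlations = correlations,
         strand_test = strand_test, params = params),
    class = "mts_report")
}

#' @export
print.mts_report <- function(x, ...) {
  g <- glance(x)
  cat("<mts_report>\n")
  cat(sprintf("  transcripts: %d (%d regulated: %d up, %d down, %d de novo, %d switched off)\n",
              g$n_transcripts, g$n_regulated, g$n_up, g$n_down,
              g$n_de_novo, g$n_switched_off))
  cat(sprintf("  lncRNA-coding neighbor pairs: %d (%d concordant, %d discordant)\n",
              nrow(x$pairs), g$n_concordant, g$n_discordant))
  cat(sprintf("  clusters: %d; chromosomes: %d\n",
              g$n_clusters, length(unique(x$chromosomes$chromosome))))
  if (!is.null(x$strand_test)) {
    cat(sprintf("  strand bias: chi2 = %.4f, p = %.5f\n",
                unname(x$strand_test$statistic), x$strand_test$p.value))
  }
  invisible(x)
}

#' Tidy the per-transcript regulation calls of a report
#'
#' @param x An `mts_report`.
#' @param ... Unused.
#' @return The `calls` tibble.
#' @export
tidy.mts_report <- function(x, ...) x$calls

#' One-row overview of a pipeline report
#'
#' @param x An `mts_report`.
#' @param ... Unused.
#' @return A one-row tibble with transcript, status, pair, cluster and
#'   strand-test summaries.
#' @export
glance.mts_report <- function(x, ...) {
  st <- table(x$calls$status)
  tibble(
    n_transcripts = nrow(x$calls),
    n_up = as.integer(st[["up"]]),
    n_down = as.integer(st[["down"]]),
    n_de_novo = as.integer(st[["de_novo"]]),
    n_switched_off = as.integer(st[["switched_off"]]),
    n_unchanged = as.integer(st[["unchanged"]]),
    n_filtered = as.integer(st[["filtered"]]),
    n_regulated = as.integer(sum(st[.regulated_statuses])),
    n_concordant = sum(x$pairs$coregulation == "concordant"),
    n_discordant = sum(x$pairs$coregulation == "discordant"),
    n_clusters = nrow(x$clusters),
    strand_chi2 = if (is.null(x$strand_test)) NA_real_ else unname(x$strand_test$statistic),
    strand_p = if (is.null(x$strand_test)) NA_real_ else x$strand_test$p.value
  )
}

#' Score pipeline calls against a simulation truth table
#'
#' Compares called statuses (and, optionally, recovered co-regulated pairs)
#' with the planted truth of [simulate_counts()]. For each planted status the
#' recall is the fraction of planted transcripts receiving that call and the
#' precision the fraction of such calls that were planted.
#'
#' @param report An `mts_report`, or a calls tibble.
#' @param truth Truth tibble from [simulate_counts()].
#'
#' @return A tibble with `status`, `n_planted`, `n_called`, `n_correct`,
#'   `recall`, `precision` for the four dysregulated statuses, plus a
#'   `pairs` row when `report` is an `mts_report`. Pair recall is the
#'   fraction of planted concordant/discordant pairs recovered with the
#'   correct class; pair precision is the fraction of reported co-regulated
#'   pairs whose class is consistent with the planted statuses of both
#'   members (independently planted neighbors that genuinely co-vary are
#'   correct detections, not false positives).
#' @export
score_against_truth <- function(report, truth) {
  calls <- if (inherits(report, "mts_report")) report$calls else report
  joined <- dplyr::inner_join(
    dplyr::select(calls, "transcript_id", called = "status"),
    dplyr::select(truth, "transcript_id", planted = "status"),
    by = "transcript_id")
  joined$called <- as.character(joined$called)

  per_status <- purrr::map_dfr(.regulated_statuses, function(s) {
    n_planted <- sum(joined$planted == s)
    n_called <- sum(joined$called == s)
    n_correct <- sum(joined$planted == s & joined$called == s)
    tibble(status = s, n_planted = n_planted, n_called = n_called,
           n_correct = n_correct,
           recall = ifelse(n_planted > 0, n_correct / n_planted, NA_real_),
           precision = ifelse(n_called > 0, n_correct / n_called, NA_real_))
  })

  if (!inherits(report, "mts_report")) return(per_status)

  planted_lnc <- truth |>
    dplyr::filter(!is.na(.data$pair_id)) |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::summarise(
      lncRNA_id = .data$transcript_id[which.max(grepl("^lnc", .data$transcript_id))],
      gene_id = .data$transcript_id[which.min(grepl("^lnc", .data$transcript_id))],
      pair_class = .data$pair_class[1], .groups = "drop")
  found <- report$pairs |>
    dplyr::filter(.data$coregulation != "none") |>
    dplyr::select("lncRNA_id", "gene_id", "coregulation")
  hit <- dplyr::inner_join(planted_lnc, found,
                           by = c("lncRNA_id", "gene_id")) |>
    dplyr::filter(.data$pair_class == .data$coregulation)
  # precision: of all pairs reported co-regulated, how many have a class
  # consistent with the planted statuses (independently planted neighbors
  # that genuinely co-vary count as correct, not as false positives)
  truth_status <- setNames(truth$status, truth$transcript_id)
  truth_cls <- function(st) dplyr::case_when(
    st %in% .positive_statuses ~ "positive",
    st %in% .negative_statuses ~ "negative",
    .default = "none")
  a <- truth_cls(truth_status[found$lncRNA_id])
  b <- truth_cls(truth_status[found$gene_id])
  truth_pair_class <- dplyr::case_when(
    a == "none" | b == "none" ~ "none",
    a == b ~ "concordant",
    .default = "discordant")
  n_consistent <- sum(!is.na(truth_pair_class) &
                        truth_pair_class == found$coregulation)
  pair_row <- tibble(
    status = "pairs",
    n_planted = nrow(planted_lnc), n_called = nrow(found),
    n_correct = nrow(hit),
    recall = ifelse(nrow(planted_lnc) > 0, nrow(hit) / nrow(planted_lnc), NA_real_),
    precision = ifelse(nrow(found) > 0, n_consistent / nrow(found), NA_real_))
  dplyr::bind_rows(per_status, pair_row)
}

#' Write all report tables to a directory
#'
#' Exports the regulation calls, summary JSON, co-regulated pairs table,
#' clusters BED, per-chromosome statistics, a JSON stats block (correlations
#' and strand test), and a human-readable text report. Tabular files carry a
#' provenance header comment with the package version and a hash of the
#' pipeline parameters. Every number in the text report is re-derivable from
#' the emitted tables.
#'
#' @param report An `mts_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mts_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- sprintf("# spheroseq %s; params %s",
                 as.character(packageVersion("spheroseq")),
                 rlang::hash(report$params))
  write_tsv_h <- function(x, file) {
    path <- file.path(dir, file)
    writeLines(hdr, path)
    suppressWarnings(readr::write_tsv(x, path, append = TRUE, col_names = TRUE))
    path
  }

  write_tsv_h(report$calls, "regulation_calls.tsv")
  pairs_flat <- report$pairs
  write_tsv_h(pairs_flat, "coregulated_pairs.tsv")
  write_tsv_h(report$chromosomes, "chromosome_summary.tsv")
  write_clusters_bed(report$clusters, file.path(dir, "clusters.bed"))

  summary_list <- split(report$summary, report$summary$biotype) |>
    lapply(function(d) setNames(as.list(d$n), as.character(d$status)))
  jsonlite::write_json(summary_list, file.path(dir, "regulation_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  stats <- list(correlations = report$correlations)
  if (!is.null(report$strand_test)) {
    stats$strand_chi2 <- unname(report$strand_test$statistic)
    stats$strand_p <- report$strand_test$p.value
  }
  jsonlite::write_json(stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  g <- glance(report)
  lines <- c(
    hdr,
    sprintf("Transcripts analyzed: %d", g$n_transcripts),
    sprintf("Regulated: %d (up %d, down %d, de novo %d, switched off %d)",
            g$n_regulated, g$n_up, g$n_down, g$n_de_novo, g$n_switched_off),
    sprintf("Unchanged: %d; filtered: %d", g$n_unchanged, g$n_filtered),
    sprintf("Co-regulated lncRNA-mRNA pairs: %d (%d concordant, %d discordant)",
            g$n_concordant + g$n_discordant, g$n_concordant, g$n_discordant),
    sprintf("Multi-neighbor lncRNAs: %d", nrow(report$multi_neighbors)),
    sprintf("Clusters of dysregulated features: %d", g$n_clusters),
    if (!is.na(g$strand_chi2)) {
      sprintf("Strand bias (regulated vs background lncRNAs): chi2 = %.5f, p = %.5f",
              g$strand_chi2, g$strand_p)
    },
    "Correlations (regulated count vs predictor):",
    sprintf("  %s / %s: R = %.3f", report$correlations$biotype,
            report$correlations$x, report$correlations$r)
  )
  writeLines(lines, file.path(dir, "report.txt"))
  invisible(dir)
}
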