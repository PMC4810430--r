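#' Simulation configuration
#'
#' Parameters of the synthetic two-condition (monolayer vs spheroid) bulk
#' RNA-seq experiment. Defaults emulate the structure of the study the
#' pipeline was designed around: a genome annotation of protein-coding and
#' lncRNA transcripts, negative-binomial counts with planted fold changes,
#' planted binary (de novo / switched off) transcripts, planted
#' concordant/discordant lncRNA-mRNA neighbor pairs, and one histone-like
#' chromosomal cluster of co-regulated features.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bp (recycled to
#'   `n_chromosomes`).
#' @param n_coding,n_lncRNA Number of protein-coding and lncRNA transcripts
#'   (totals, including pair and cluster members).
#' @param lncrna_length_mix Proportions of lncRNA lengths in the three
#'   reporting bins `< 1000`, `1000-2499`, `>= 2500` nt; must sum to 1.
#'   Default `c(0.61, 0.27, 0.12)`, the observed bin proportions of regulated
#'   lncRNAs in early-stage spheroids.
#' @param coding_length_range Uniform range of coding-transcript lengths (nt).
#' @param baseline_mean Mean baseline expression count per transcript.
#' @param baseline_sdlog Log-normal sd of per-transcript baseline means
#'   (0 = identical baselines).
#' @param dispersion Negative-binomial dispersion; 0 gives deterministic
#'   counts equal to the rounded means (the noiseless limit).
#' @param n_up,n_down Numbers of planted up-/down-regulated singleton
#'   transcripts.
#' @param fold_change Planted fold-change magnitude (> 1).
#' @param n_de_novo,n_switched_off Numbers of planted binary transcripts
#'   (expressed only in MTS / only in monolayer).
#' @param n_concordant_pairs,n_discordant_pairs Numbers of planted
#'   lncRNA-coding neighbor pairs regulated in the same / opposite direction.
#' @param pair_max_gap Maximum genomic gap within a planted pair (bp).
#' @param cluster_size Member count of the planted chromosomal cluster
#'   (0 disables it).
#' @param cluster_gap_range Uniform range of gaps between consecutive cluster
#'   members (bp).
#' @param feature_gap_range Uniform range of gaps between unrelated features
#'   (bp); the lower bound should exceed the cluster-detection window so that
#'   only planted structures chain.
#' @param seed Integer seed; one seed drives annotation, counts and truth.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_coding = 50, n_lncRNA = 50, seed = 7)
sim_config <- function(n_chromosomes = 10,
                       chromosome_length = 60e6,
                       n_coding = 1000,
                       n_lncRNA = 1000,
                       lncrna_length_mix = c(0.61, 0.27, 0.12),
                       coding_length_range = c(1000, 5000),
                       baseline_mean = 200,
                       baseline_sdlog = 0.5,
                       dispersion = 0.05,
                       n_up = 100,
                       n_down = 100,
                       fold_change = 4,
                       n_de_novo = 50,
                       n_switched_off = 50,
                       n_concordant_pairs = 10,
                       n_discordant_pairs = 6,
                       pair_max_gap = 50e3,
                       cluster_size = 25,
                       cluster_gap_range = c(5e3, 20e3),
                       feature_gap_range = c(120e3, 300e3),
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = rep_len(as.numeric(chromosome_length), n_chromosomes),
    n_coding = as.integer(n_coding),
    n_lncRNA = as.integer(n_lncRNA),
    lncrna_length_mix = lncrna_length_mix,
    coding_length_range = coding_length_range,
    baseline_mean = baseline_mean,
    baseline_sdlog = baseline_sdlog,
    dispersion = dispersion,
    n_up = as.integer(n_up),
    n_down = as.integer(n_down),
    fold_change = fold_change,
    n_de_novo = as.integer(n_de_novo),
    n_switched_off = as.integer(n_switched_off),
    n_concordant_pairs = as.integer(n_concordant_pairs),
    n_discordant_pairs = as.integer(n_discordant_pairs),
    pair_max_gap = pair_max_gap,
    cluster_size = as.integer(cluster_size),
    cluster_gap_range = cluster_gap_range,
    feature_gap_range = feature_gap_range,
    seed = as.integer(seed)
  )

  counts <- cfg[c("n_chromosomes", "n_coding", "n_lncRNA", "n_up", "n_down",
                  "n_de_novo", "n_switched_off", "n_concordant_pairs",
                  "n_discordant_pairs", "cluster_size")]
  if (any(unlist(counts) < 0)) {
    abort("All simulation counts must be non-negative.",
          class = "spheroseq_parameter_error")
  }
  if (cfg$fold_change <= 1) {
    abort("`fold_change` must be a magnitude > 1.",
          class = "spheroseq_parameter_error")
  }
  if (abs(sum(cfg$lncrna_length_mix) - 1) > 1e-8 || any(cfg$lncrna_length_mix < 0)) {
    abort("`lncrna_length_mix` must be non-negative proportions summing to 1.",
          class = "spheroseq_parameter_error")
  }
  if (cfg$dispersion < 0 || cfg$baseline_mean < 0 || cfg$baseline_sdlog < 0) {
    abort("`dispersion`, `baseline_mean` and `baseline_sdlog` must be >= 0.",
          class = "spheroseq_parameter_error")
  }
  n_pairs <- cfg$n_concordant_pairs + cfg$n_discordant_pairs
  cl_coding <- ceiling(cfg$cluster_size / 2)
  cl_lnc <- cfg$cluster_size - cl_coding
  if (n_pairs + cl_coding > cfg$n_coding || n_pairs + cl_lnc > cfg$n_lncRNA) {
    abort("Planted pairs and cluster need more transcripts than the configured totals.",
          class = "spheroseq_parameter_error")
  }
  n_singles <- cfg$n_coding + cfg$n_lncRNA - 2 * n_pairs - cfg$cluster_size
  if (cfg$n_up + cfg$n_down + cfg$n_de_novo + cfg$n_switched_off > n_singles) {
    abort("Planted singleton effects exceed the number of unplanted transcripts.",
          class = "spheroseq_parameter_error")
  }
  structure(cfg, class = "sim_config")
}

# draw one lncRNA length from the three-bin mixture
.draw_lnc_lengths <- function(n, mix) {
  bin <- sample.int(3, n, replace = TRUE, prob = mix)
  lo <- c(200, 1000, 2500)[bin]
  hi <- c(999, 2499, 8000)[bin]
  round(runif(n, lo, hi))
}

#' Generate a synthetic genome annotation
#'
#' Places coding and lncRNA transcripts on the configured chromosomes.
#' Planted neighbor pairs are laid out as adjacent lncRNA/coding features
#' separated by at most `pair_max_gap`; the planted cluster is a run of
#' alternating coding/lncRNA features with small gaps; all other features are
#' separated by gaps drawn from `feature_gap_range`, whose lower bound
#' exceeds the default cluster window so no accidental clusters or pair
#' ambiguities arise. Coordinates are 0-based half-open internally.
#'
#' @param config A [sim_config()].
#'
#' @return A tibble with columns `transcript_id`, `biotype`, `chromosome`,
#'   `strand`, `start`, `end`, `length`, plus planted-structure columns
#'   consumed by [simulate_counts()]: `role` (`single`, `pair`, `cluster`),
#'   `pair_id`, `pair_class`, `partner_id`.
#' @export
#' @examples
#' ann <- simulate_annotation(sim_config(n_coding = 20, n_lncRNA = 20,
#'                                       n_concordant_pairs = 2,
#'                                       n_discordant_pairs = 1,
#'                                       cluster_size = 5,
#'                                       n_up = 2, n_down = 2,
#'                                       n_de_novo = 1, n_switched_off = 1,
#'                                       seed = 7))
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pairs <- config$n_concordant_pairs + config$n_discordant_pairs

  cl_coding <- ceiling(config$cluster_size / 2)
  cl_lnc <- config$cluster_size - cl_coding
  n_single_coding <- config$n_coding - n_pairs - cl_coding
  n_single_lnc <- config$n_lncRNA - n_pairs - cl_lnc

  total_coding <- config$n_coding
  total_lnc <- config$n_lncRNA
  if (total_coding + total_lnc == 0) {
    return(tibble(
      transcript_id = character(), biotype = character(),
      chromosome = character(), strand = character(),
      start = numeric(), end = numeric(), length = numeric(),
      role = character(), pair_id = integer(),
      pair_class = character(), partner_id = character()
    ))
  }

  coding_ids <- sprintf("mrna_%04d", seq_len(total_coding))
  lnc_ids <- sprintf("lnc_%04d", seq_len(total_lnc))
  coding_len <- round(runif(total_coding, config$coding_length_range[1],
                            config$coding_length_range[2]))
  lnc_len <- .draw_lnc_lengths(total_lnc, config$lncrna_length_mix)

  # build placement units: one cluster, the pairs, then shuffled singles
  units <- list()
  ci <- 0L; li <- 0L
  take_coding <- function() { ci <<- ci + 1L; ci }
  take_lnc <- function() { li <<- li + 1L; li }

  if (config$cluster_size > 0) {
    members <- lapply(seq_len(config$cluster_size), function(k) {
      if (k %% 2 == 1) list(biotype = "protein_coding", idx = take_coding())
      else list(biotype = "lncRNA", idx = take_lnc())
    })
    units[[length(units) + 1]] <- list(kind = "cluster", members = members)
  }
  if (n_pairs > 0) {
    pair_class <- c(rep("concordant", config$n_concordant_pairs),
                    rep("discordant", config$n_discordant_pairs))
    for (p in seq_len(n_pairs)) {
      lnc_first <- runif(1) < 0.5
      m1 <- list(biotype = "lncRNA", idx = take_lnc())
      m2 <- list(biotype = "protein_coding", idx = take_coding())
      members <- if (lnc_first) list(m1, m2) else list(m2, m1)
      units[[length(units) + 1]] <- list(kind = "pair", members = members,
                                         pair_id = p, pair_class = pair_class[p])
    }
  }
  singles_bt <- sample(c(rep("protein_coding", n_single_coding),
                         rep("lncRNA", n_single_lnc)))
  for (bt in singles_bt) {
    idx <- if (bt == "protein_coding") take_coding() else take_lnc()
    units[[length(units) + 1]] <- list(kind = "single",
                                       members = list(list(biotype = bt, idx = idx)))
  }

  # round-robin units over chromosomes, then lay each chromosome out
  # left-to-right with unit-appropriate gaps
  chrom_of_unit <- ((seq_along(units) - 1L) %% config$n_chromosomes) + 1L
  cursor <- rep(0, config$n_chromosomes)
  n_feat <- total_coding + total_lnc
  v_id <- character(n_feat); v_bt <- character(n_feat)
  v_chrom <- character(n_feat); v_start <- numeric(n_feat)
  v_end <- numeric(n_feat); v_len <- numeric(n_feat)
  v_role <- character(n_feat); v_pair <- rep(NA_integer_, n_feat)
  v_pcls <- rep(NA_character_, n_feat)
  ri <- 0L
  for (u in seq_along(units)) {
    unit <- units[[u]]
    chrom <- chrom_of_unit[u]
    pos <- cursor[chrom] + runif(1, config$feature_gap_range[1],
                                 config$feature_gap_range[2])
    nm <- length(unit$members)
    for (k in seq_len(nm)) {
      m <- unit$members[[k]]
      len <- if (m$biotype == "protein_coding") coding_len[m$idx] else lnc_len[m$idx]
      ri <- ri + 1L
      v_id[ri] <- if (m$biotype == "protein_coding") coding_ids[m$idx] else lnc_ids[m$idx]
      v_bt[ri] <- m$biotype
      v_chrom[ri] <- sprintf("chr%d", chrom)
      v_start[ri] <- round(pos)
      v_end[ri] <- v_start[ri] + len
      v_len[ri] <- len
      v_role[ri] <- unit$kind
      if (unit$kind == "pair") {
        v_pair[ri] <- unit$pair_id
        v_pcls[ri] <- unit$pair_class
      }
      pos <- v_end[ri]
      if (k < nm) {
        gap <- switch(unit$kind,
          cluster = runif(1, config$cluster_gap_range[1], config$cluster_gap_range[2]),
          pair = runif(1, 1e3, config$pair_max_gap),
          0)
        pos <- pos + gap
      }
    }
    cursor[chrom] <- pos
    if (pos > config$chromosome_length[chrom]) {
      abort(sprintf("Features do not fit on chr%d (%.0f bp needed, %.0f available); increase `chromosome_length`.",
                    chrom, pos, config$chromosome_length[chrom]),
            class = "spheroseq_placement_error")
    }
  }

  ann <- tibble(
    transcript_id = v_id, biotype = v_bt, chromosome = v_chrom,
    strand = sample(c("+", "-"), n_feat, replace = TRUE),
    start = v_start, end = v_end, length = v_len,
    role = v_role, pair_id = v_pair, pair_class = v_pcls,
    partner_id = NA_character_
  ) |>
    dplyr::arrange(.data$chromosome, .data$start, .data$transcript_id)

  # fill pair partners
  pair_rows <- ann |>
    dplyr::filter(!is.na(.data$pair_id)) |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::mutate(partner_id = rev(.data$transcript_id)) |>
    dplyr::ungroup()
  ann$partner_id[match(pair_rows$transcript_id, ann$transcript_id)] <-
    pair_rows$partner_id
  ann
}

#' Simulate two-condition counts with planted effects
#'
#' Draws negative-binomial counts for the monolayer and spheroid (MTS)
#' conditions around per-transcript baseline means, applying the planted
#' effects encoded by [simulate_annotation()] plus randomly sampled singleton
#' effects: planted up/down transcripts have an MTS/monolayer mean ratio
#' equal to `fold_change`, de-novo transcripts have monolayer counts exactly
#' zero, switched-off transcripts the mirror image, concordant pairs share a
#' direction, discordant pairs oppose, and cluster members are up-regulated.
#' At `dispersion = 0` counts equal the rounded means (noiseless limit).
#' Relative expression is RPKM computed from the drawn counts, the transcript
#' lengths and the per-condition library sizes.
#'
#' @param annotation Annotation tibble from [simulate_annotation()] (an
#'   external annotation works too; planted pairs/clusters then require the
#'   `role`/`pair_id`/`pair_class` columns to be present, otherwise only
#'   singleton effects are planted).
#' @param config A [sim_config()].
#'
#' @return A list with `expression` (tibble: `transcript_id`, `reads_mono`,
#'   `reads_mts`, `relexpr_mono`, `relexpr_mts`) and `truth` (tibble:
#'   `transcript_id`, `status`, `fold_change` (signed; `NA` for binary
#'   statuses), `pair_id`, `pair_class`, `partner_id`, `in_cluster`).
#' @export
simulate_counts <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(annotation) == 0) {
    abort("`annotation` is empty; generate or load one first.",
          class = "spheroseq_input_error")
  }
  set.seed(config$seed + 1L)
  n <- nrow(annotation)

  role <- annotation$role %||% rep("single", n)
  if (is.null(annotation$role)) {
    pair_id <- rep(NA_integer_, n); pair_class <- rep(NA_character_, n)
    partner_id <- rep(NA_character_, n)
  } else {
    pair_id <- annotation$pair_id; pair_class <- annotation$pair_class
    partner_id <- annotation$partner_id
  }

  status <- rep("unchanged", n)
  fc <- rep(1, n)

  # planted pairs: concordant share a random direction, discordant oppose
  # (the lncRNA member draws the direction)
  for (p in unique(stats::na.omit(pair_id))) {
    idx <- which(pair_id == p)
    lnc <- idx[annotation$biotype[idx] == "lncRNA"][1]
    gene <- setdiff(idx, lnc)[1]
    dir_lnc <- sample(c("up", "down"), 1)
    cls <- pair_class[idx][1]
    dir_gene <- if (cls == "concordant") dir_lnc else setdiff(c("up", "down"), dir_lnc)
    status[lnc] <- dir_lnc; status[gene] <- dir_gene
    fc[c(lnc, gene)] <- ifelse(status[c(lnc, gene)] == "up",
                               config$fold_change, 1 / config$fold_change)
  }

  in_cluster <- role == "cluster"
  status[in_cluster] <- "up"
  fc[in_cluster] <- config$fold_change

  # singleton effects sampled from unplanted transcripts, disjointly
  free <- which(status == "unchanged" & role == "single")
  need <- config$n_up + config$n_down + config$n_de_novo + config$n_switched_off
  if (need > length(free)) {
    abort("Planted singleton effects exceed available transcripts.",
          class = "spheroseq_parameter_error")
  }
  picked <- sample(free, need)
  groups <- rep(c("up", "down", "de_novo", "switched_off"),
                times = c(config$n_up, config$n_down,
                          config$n_de_novo, config$n_switched_off))
  status[picked] <- groups
  fc[picked] <- dplyr::case_when(
    groups == "up" ~ config$fold_change,
    groups == "down" ~ 1 / config$fold_change,
    .default = 1
  )

  mu <- if (config$baseline_sdlog > 0) {
    rlnorm(n, log(config$baseline_mean) - config$baseline_sdlog^2 / 2,
           config$baseline_sdlog)
  } else {
    rep(config$baseline_mean, n)
  }
  mean_mono <- ifelse(status == "de_novo", 0, mu)
  mean_mts <- dplyr::case_when(
    status == "switched_off" ~ 0,
    .default = mu * fc
  )

  draw <- function(m) {
    if (config$dispersion > 0) rnbinom(n, mu = m, size = 1 / config$dispersion)
    else round(m)
  }
  reads_mono <- draw(mean_mono)
  reads_mts <- draw(mean_mts)

  lib_mono <- sum(reads_mono); lib_mts <- sum(reads_mts)
  re <- function(reads, lib) {
    if (lib > 0) relative_expression(reads, annotation$length, lib)
    else rep(0, n)
  }

  expression <- tibble(
    transcript_id = annotation$transcript_id,
    reads_mono = as.numeric(reads_mono),
    reads_mts = as.numeric(reads_mts),
    relexpr_mono = re(reads_mono, lib_mono),
    relexpr_mts = re(reads_mts, lib_mts)
  )
  truth <- tibble(
    transcript_id = annotation$transcript_id,
    status = status,
    fold_change = dplyr::case_when(
      status == "up" ~ fc,
      status == "down" ~ -1 / fc,
      status == "unchanged" ~ 1,
      .default = NA_real_
    ),
    pair_id = pair_id,
    pair_class = pair_class,
    partner_id = partner_id,
    in_cluster = in_cluster
  )
  list(expression = expression, truth = truth)
}

#' Simulate a complete synthetic experiment
#'
#' Convenience wrapper: seeds once from `config$seed`, generates the
#' annotation and the two-condition counts, and returns all three tables.
#'
#' @param config A [sim_config()].
#' @return A list with `annotation`, `expression`, and `truth` tibbles.
#' @export
#' @examples
#' sim <- simulate_mts_experiment(sim_config(n_coding = 50, n_lncRNA = 50,
#'                                           n_up = 5, n_down = 5,
#'                                           n_de_novo = 2, n_switched_off = 2,
#'                                           n_concordant_pairs = 2,
#'                                           n_discordant_pairs = 1,
#'                                           cluster_size = 5, seed = 7))
#' names(sim)
simulate_mts_experiment <- function(config) {
  annotation <- simulate_annotation(config)
  cx <- simulate_counts(annotation, config)
  list(annotation = annotation, expression = cx$expression, truth = cx$truth)
}

#' Read/write the tab-separated expression and truth tables
#'
#' The expression table schema (`transcript_id`, `reads_mono`, `reads_mts`,
#' `relexpr_mono`, `relexpr_mts`) is shared between simulated and real data;
#' the truth table carries the planted statuses used as the simulation
#' oracle.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `write_*` return `x` invisibly; `read_*` return a tibble.
#' @export
write_expression_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname write_expression_table
#' @export
read_expression_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, comment = "#")
}

#' @rdname write_expression_table
#' @export
write_truth_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname write_expression_table
#' @export
read_truth_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, comment = "#")
}
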