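# small, fast simulation configurations used across tests

tiny_config <- function(seed = 7, dispersion = 0, ...) {
  args <- list(
    n_chromosomes = 4, chromosome_length = 30e6,
    n_coding = 60, n_lncRNA = 60,
    baseline_sdlog = 0, dispersion = dispersion,
    n_up = 6, n_down = 6, n_de_novo = 3, n_switched_off = 3,
    n_concordant_pairs = 3, n_discordant_pairs = 2,
    cluster_size = 6, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# expression table with hand-set values and self-consistent RPKM columns
make_expression <- function(reads_mono, reads_mts, length = 1000,
                            ids = sprintf("t%03d", seq_along(reads_mono))) {
  lib_mono <- max(sum(reads_mono), 1)
  lib_mts <- max(sum(reads_mts), 1)
  tibble::tibble(
    transcript_id = ids,
    reads_mono = reads_mono, reads_mts = reads_mts,
    relexpr_mono = relative_expression(reads_mono, length, lib_mono),
    relexpr_mts = relative_expression(reads_mts, length, lib_mts)
  )
}

# brute-force nearest-coding-neighbor oracle: plain loops over all genes,
# re-stating the definition independently of the package implementation
brute_force_neighbors <- function(annotation, k_per_side = 1,
                                  max_distance = 1e6) {
  lnc <- annotation[annotation$biotype == "lncRNA", ]
  genes <- annotation[annotation$biotype == "protein_coding", ]
  rows <- list()
  for (i in seq_len(nrow(lnc))) {
    g <- genes[genes$chromosome == lnc$chromosome[i], ]
    if (nrow(g) == 0) next
    ng <- nrow(g)
    dist_v <- numeric(ng); side_v <- character(ng); orient_v <- character(ng)
    for (j in seq_len(ng)) {
      gap <- max(0, g$start[j] - lnc$end[i], lnc$start[i] - g$end[j])
      dist_v[j] <- gap
      side_v[j] <- if (gap == 0) "overlapping"
        else if (g$end[j] <= lnc$start[i]) "upstream" else "downstream"
      orient_v[j] <- if (g$strand[j] == lnc$strand[i])
        "same_strand" else "opposite_strand"
    }
    recs <- data.frame(gene_id = g$transcript_id, distance = dist_v,
                       side = side_v, orientation = orient_v)
    recs <- recs[recs$distance <= max_distance, , drop = FALSE]
    keep <- recs$side == "overlapping"
    for (sd in c("upstream", "downstream")) {
      d <- sort(unique(recs$distance[recs$side == sd]))
      if (length(d) && k_per_side > 0) {
        kth <- d[min(k_per_side, length(d))]
        keep <- keep | (recs$side == sd & recs$distance <= kth)
      }
    }
    recs <- recs[keep, , drop = FALSE]
    if (nrow(recs)) {
      recs$lncRNA_id <- lnc$transcript_id[i]
      rows[[length(rows) + 1]] <- recs
    }
  }
  if (!length(rows)) {
    return(data.frame(lncRNA_id = character(), gene_id = character(),
                      distance = numeric(), side = character(),
                      orientation = character()))
  }
  out <- do.call(rbind, rows)[, c("lncRNA_id", "gene_id", "distance",
                                  "side", "orientation")]
  out[order(out$lncRNA_id, out$distance, out$gene_id), ]
}

# brute-force window-chained cluster oracle: explicit loop, chaining a
# feature to the current run when its gap to the nearest previous run
# member is within the window
brute_force_clusters <- function(calls, annotation, window = 1e5,
                                 min_members = 3) {
  dys <- as.character(calls$status) %in%
    c("up", "down", "de_novo", "switched_off")
  feats <- annotation[annotation$transcript_id %in%
                        calls$transcript_id[dys], ]
  feats <- feats[order(feats$chromosome, feats$start, feats$transcript_id), ]
  out <- list()
  for (chrom in unique(feats$chromosome)) {
    f <- feats[feats$chromosome == chrom, ]
    run <- list(1)
    if (nrow(f) > 1) {
      for (i in 2:nrow(f)) {
        members <- run[[length(run)]]
        gap <- min(sapply(members, function(j)
          max(0, f$start[i] - f$end[j], f$start[j] - f$end[i])))
        if (gap <= window) {
          run[[length(run)]] <- c(members, i)
        } else {
          run[[length(run) + 1]] <- i
        }
      }
    }
    for (members in run) {
      if (length(members) >= min_members) {
        out[[length(out) + 1]] <- data.frame(
          chromosome = chrom,
          start = min(f$start[members]), end = max(f$end[members]),
          n_members = length(members),
          members = paste(sort(f$transcript_id[members]), collapse = ","))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), n_members = integer(),
                      members = character()))
  }
  out <- do.call(rbind, out)
  out[order(out$chromosome, out$start), ]
}

# random annotation instance for oracle-equivalence tests
random_instance <- function(n, seed) {
  set.seed(seed)
  n_chrom <- sample(1:3, 1)
  tibble::tibble(
    transcript_id = sprintf("f%03d", seq_len(n)),
    biotype = sample(c("protein_coding", "lncRNA"), n, replace = TRUE),
    chromosome = sample(sprintf("chr%d", seq_len(n_chrom)), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    start = round(runif(n, 0, 5e6)),
    end = start + round(runif(n, 100, 5e4))
  ) |>
    dplyr::mutate(length = end - start) |>
    dplyr::arrange(chromosome, start, transcript_id)
}
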