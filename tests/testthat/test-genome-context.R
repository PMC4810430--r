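test_that("GTF coordinates convert between 1-based inclusive and half-open", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste0("chr1\tsrc\ttranscript\t101\t200\t.\t+\t.\t",
                    'transcript_id "x"; gene_biotype "protein_coding";'), f)
  ann <- read_annotation(f)
  expect_equal(ann$start, 100)
  expect_equal(ann$end, 200)
  expect_equal(ann$length, 100)
})

test_that("annotation parsing flags malformed lines and skips unknown biotypes", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\ttranscript\t1\t100", "chr1\tmore"), f)
  expect_error(read_annotation(f), class = "spheroseq_parse_error",
               regexp = "line 1")

  f2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\ttranscript\t1\t100\t.\t+\t.\t",
           'transcript_id "a"; gene_biotype "lncRNA";'),
    paste0("chr1\tsrc\ttranscript\t200\t300\t.\t-\t.\t",
           'transcript_id "b"; gene_biotype "rRNA";')), f2)
  expect_warning(ann <- read_annotation(f2), "unknown biotype")
  expect_equal(ann$transcript_id, "a")

  expect_error(read_annotation("/nonexistent.gtf"),
               class = "spheroseq_input_error")
})

test_that("simulated annotations survive a GTF round trip unchanged", {
  ann <- simulate_annotation(tiny_config(seed = 13))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  back <- read_annotation(f)
  cols <- c("transcript_id", "biotype", "chromosome", "strand",
            "start", "end", "length")
  expect_equal(as.data.frame(back[cols]),
               as.data.frame(ann[order(ann$chromosome, ann$start,
                                       ann$transcript_id), cols]))
})

test_that("nearest neighbors follow the distance and side definitions", {
  ann <- tibble::tibble(
    transcript_id = c("lncA", "g1"),
    biotype = c("lncRNA", "protein_coding"),
    chromosome = "chr1", strand = c("+", "+"),
    start = c(1000, 3000), end = c(2000, 4000), length = 1000
  )
  p <- nearest_coding_neighbors(ann)
  expect_equal(p$gene_id, "g1")
  expect_equal(p$distance, 1000)
  expect_equal(p$side, "downstream")
  expect_equal(p$orientation, "same_strand")

  # overlap gives distance 0
  ann$start[2] <- 1500; ann$end[2] <- 2500
  p2 <- nearest_coding_neighbors(ann)
  expect_equal(p2$distance, 0)
  expect_equal(p2$side, "overlapping")

  # absent chromosome yields an empty result, not an error
  ann$chromosome[2] <- "chr2"
  expect_equal(nrow(nearest_coding_neighbors(ann)), 0)

  # max_distance bounds the search
  ann$chromosome[2] <- "chr1"; ann$start[2] <- 3e6; ann$end[2] <- 3.001e6
  expect_equal(nrow(nearest_coding_neighbors(ann, max_distance = 1e6)), 0)
})

test_that("neighbor assignment matches the brute-force oracle on random instances", {
  for (s in 1:30) {
    inst <- random_instance(n = sample(10:120, 1), seed = 1000 + s)
    for (k in 1:2) {
      got <- nearest_coding_neighbors(inst, k_per_side = k, max_distance = 2e6)
      want <- brute_force_neighbors(inst, k_per_side = k, max_distance = 2e6)
      expect_equal(as.data.frame(got), as.data.frame(want),
                   ignore_attr = TRUE)
    }
  }
})

test_that("co-regulation classes follow member regulation classes symmetrically", {
  calls <- tibble::tibble(
    transcript_id = c("l1", "l2", "l3", "g1", "g2", "g3"),
    status = factor(c("up", "de_novo", "up", "up", "down", "unchanged"),
                    levels = regulation_statuses())
  )
  pairs <- tibble::tibble(
    lncRNA_id = c("l1", "l2", "l3"), gene_id = c("g1", "g2", "g3"),
    distance = c(10, 20, 30), side = "downstream",
    orientation = "same_strand"
  )
  cp <- classify_coregulation(pairs, calls)
  expect_equal(cp$coregulation, c("concordant", "discordant", "none"))

  # symmetric in which member carries which status
  swapped <- calls
  swapped$transcript_id <- c("g1", "g2", "g3", "l1", "l2", "l3")
  cp_sw <- classify_coregulation(pairs, swapped)
  expect_equal(cp_sw$coregulation, cp$coregulation)

  expect_error(classify_coregulation(pairs, calls[-1, ]),
               class = "spheroseq_lookup_error", regexp = "l1")
})

test_that("multi-neighbor lncRNAs require the co-regulated minimum", {
  pairs <- tibble::tibble(
    lncRNA_id = c("lA", "lA", "lA", "lB", "lC"),
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    distance = c(30, 10, 20, 5, 5),
    side = "downstream", orientation = "same_strand",
    coregulation = c("concordant", "concordant", "discordant",
                     "concordant", "none")
  )
  m <- multi_neighbor_lncRNAs(pairs)
  expect_equal(m$lncRNA_id, "lA")
  expect_equal(m$n_coregulated, 3)
  expect_equal(m$neighbors[[1]], c("g2", "g3", "g1")) # sorted by distance

  none <- pairs; none$coregulation <- "none"
  expect_equal(nrow(multi_neighbor_lncRNAs(none)), 0)
})

test_that("cluster detection obeys window chaining, minimum size and maximality", {
  mk <- function(starts, len = 1000) tibble::tibble(
    transcript_id = sprintf("f%d", seq_along(starts)),
    biotype = "protein_coding", chromosome = "chr1", strand = "+",
    start = starts, end = starts + len, length = len
  )
  all_up <- function(ann) tibble::tibble(
    transcript_id = ann$transcript_id,
    status = factor("up", levels = regulation_statuses())
  )

  # 4 features 10 kb apart chain into one cluster under a 100 kb window
  ann <- mk(c(0, 11e3, 22e3, 33e3))
  cl <- detect_clusters(all_up(ann), ann, window = 1e5, min_members = 3)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 4)

  # 200 kb spacing exceeds the window: no clusters
  ann2 <- mk(c(0, 201e3, 402e3))
  expect_equal(nrow(detect_clusters(all_up(ann2), ann2,
                                    window = 1e5, min_members = 3)), 0)

  # maximality: the two reported runs cannot be merged
  ann3 <- mk(c(0, 1e4, 2e4, 5e5, 51e4, 52e4))
  cl3 <- detect_clusters(all_up(ann3), ann3, window = 1e5, min_members = 3)
  expect_equal(nrow(cl3), 2)
  expect_gt(cl3$start[2] - cl3$end[1], 1e5)
})

test_that("cluster detection matches the brute-force oracle on random instances", {
  for (s in 1:30) {
    inst <- random_instance(n = sample(10:120, 1), seed = 2000 + s)
    set.seed(3000 + s)
    calls <- tibble::tibble(
      transcript_id = inst$transcript_id,
      status = factor(sample(regulation_statuses(), nrow(inst), replace = TRUE),
                      levels = regulation_statuses())
    )
    got <- detect_clusters(calls, inst, window = 2e5, min_members = 2)
    want <- brute_force_clusters(calls, inst, window = 2e5, min_members = 2)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$chromosome, want$chromosome)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_members, want$n_members)
      expect_equal(sapply(got$members, function(m) paste(sort(m), collapse = ",")),
                   want$members)
    }
  }
})

test_that("a planted cluster is recovered exactly at zero noise", {
  cfg <- tiny_config(seed = 17, cluster_size = 25, n_coding = 80, n_lncRNA = 80)
  sim <- simulate_mts_experiment(cfg)
  calls <- classify_regulation(sim$expression)
  cl <- detect_clusters(calls, sim$annotation)
  expect_equal(nrow(cl), 1)
  expect_setequal(cl$members[[1]],
                  sim$truth$transcript_id[sim$truth$in_cluster])

  f <- withr::local_tempfile(fileext = ".bed")
  write_clusters_bed(cl, f)
  expect_match(readLines(f), "^chr\\d+\t\\d+\t\\d+\tcluster_1_n25$")
})
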