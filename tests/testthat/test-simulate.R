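test_that("configuration invariants are enforced", {
  expect_error(sim_config(fold_change = 0.5), class = "spheroseq_parameter_error")
  expect_error(sim_config(n_up = -1), class = "spheroseq_parameter_error")
  expect_error(sim_config(lncrna_length_mix = c(0.5, 0.3, 0.3)),
               class = "spheroseq_parameter_error")
  expect_error(sim_config(n_coding = 3, n_lncRNA = 3, n_concordant_pairs = 5),
               class = "spheroseq_parameter_error")
})

test_that("annotation generation respects bounds, biotypes and determinism", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 10e6,
                    n_coding = 25, n_lncRNA = 25,
                    n_up = 2, n_down = 2, n_de_novo = 1, n_switched_off = 1,
                    n_concordant_pairs = 2, n_discordant_pairs = 1,
                    cluster_size = 4, seed = 7)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann), 50)
  expect_true(all(ann$start >= 0 & ann$end <= 10e6))
  expect_true(all(ann$start < ann$end))
  expect_equal(sum(ann$biotype == "protein_coding"), 25)
  expect_equal(sum(ann$biotype == "lncRNA"), 25)
  expect_true(all(ann$strand %in% c("+", "-")))

  # same seed twice: identical tibble and byte-identical GTF
  ann2 <- simulate_annotation(cfg)
  expect_identical(ann, ann2)
  f1 <- withr::local_tempfile(fileext = ".gtf")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f1); write_gtf(ann2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # empty config gives an empty annotation and a header-only GTF
  empty <- simulate_annotation(sim_config(n_coding = 0, n_lncRNA = 0,
                                          n_up = 0, n_down = 0, n_de_novo = 0,
                                          n_switched_off = 0,
                                          n_concordant_pairs = 0,
                                          n_discordant_pairs = 0,
                                          cluster_size = 0))
  expect_equal(nrow(empty), 0)
  fe <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(empty, fe)
  expect_true(all(grepl("^#", readLines(fe))))
})

test_that("placement fails loudly when chromosomes are too small", {
  cfg <- tiny_config(chromosome_length = 1e5)
  expect_error(simulate_annotation(cfg), class = "spheroseq_placement_error")
})

test_that("planted structures are disjoint and pairs sit within the gap", {
  cfg <- tiny_config(seed = 3)
  sim <- simulate_mts_experiment(cfg)
  truth <- sim$truth

  # exactly one status per transcript; planted sets disjoint by construction
  expect_equal(anyDuplicated(truth$transcript_id), 0)
  expect_equal(as.vector(table(factor(truth$status,
                                      c("up", "down", "de_novo",
                                        "switched_off", "unchanged")))[
    c("de_novo", "switched_off")]),
    c(3, 3), ignore_attr = TRUE)

  # every planted pair appears in both members' rows, same chromosome,
  # within the configured gap
  pairs <- truth[!is.na(truth$pair_id), ]
  expect_equal(nrow(pairs), 2 * (cfg$n_concordant_pairs + cfg$n_discordant_pairs))
  for (p in unique(pairs$pair_id)) {
    m <- pairs[pairs$pair_id == p, ]
    expect_equal(nrow(m), 2)
    expect_setequal(m$partner_id, rev(m$transcript_id))
    a <- sim$annotation[sim$annotation$transcript_id %in% m$transcript_id, ]
    expect_equal(length(unique(a$chromosome)), 1)
    gap <- max(a$start) - min(a$end)
    expect_lte(gap, cfg$pair_max_gap)
  }
})

test_that("counts honor the planted means, binary zeros and the noiseless limit", {
  cfg <- tiny_config(seed = 5, baseline_mean = 100, fold_change = 4)
  sim <- simulate_mts_experiment(cfg)
  x <- dplyr::inner_join(sim$expression, sim$truth, by = "transcript_id")

  expect_true(all(x$reads_mono[x$status == "de_novo"] == 0))
  expect_true(all(x$reads_mts[x$status == "de_novo"] > 0))
  expect_true(all(x$reads_mts[x$status == "switched_off"] == 0))
  # noiseless limit with constant baseline: exact planted ratios
  expect_true(all(x$reads_mts[x$status == "up"] == 400))
  expect_true(all(x$reads_mono[x$status == "up"] == 100))
  expect_true(all(x$reads_mts[x$status == "down"] == 25))
  expect_true(all(x$reads_mono[x$status == "unchanged"] ==
                    x$reads_mts[x$status == "unchanged"]))

  expect_error(simulate_counts(sim$annotation[0, ], cfg),
               class = "spheroseq_input_error")
})

test_that("the noiseless no-effect genome classifies as all unchanged", {
  cfg <- tiny_config(seed = 9, n_up = 0, n_down = 0, n_de_novo = 0,
                     n_switched_off = 0, n_concordant_pairs = 0,
                     n_discordant_pairs = 0, cluster_size = 0)
  sim <- simulate_mts_experiment(cfg)
  calls <- classify_regulation(sim$expression)
  expect_true(all(calls$status == "unchanged"))
  s <- summarize_regulation(calls)
  expect_equal(sum(s$n[s$class != "none"]), 0)
})

test_that("noisy planted effects are recovered with high recall", {
  cfg <- tiny_config(seed = 2, dispersion = 0.05, baseline_sdlog = 0.5,
                     n_coding = 150, n_lncRNA = 150, n_up = 15, n_down = 15)
  sim <- simulate_mts_experiment(cfg)
  sc <- score_against_truth(classify_regulation(sim$expression), sim$truth)
  expect_gte(sum(sc$n_correct) / sum(sc$n_planted), 0.9)
})

test_that("fixed seed reproduces expression, truth and files end-to-end", {
  a <- simulate_mts_experiment(tiny_config(seed = 21, dispersion = 0.1))
  b <- simulate_mts_experiment(tiny_config(seed = 21, dispersion = 0.1))
  expect_identical(a, b)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(a$expression, f)
  expect_equal(as.data.frame(read_expression_table(f)),
               as.data.frame(a$expression))
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(a$truth, ft)
  back <- read_truth_table(ft)
  expect_equal(back$status, a$truth$status)
})
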