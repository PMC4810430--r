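test_that("relative expression follows the RPKM formula", {
  expect_equal(relative_expression(0, 1000, 1e6), 0)
  expect_equal(relative_expression(10, 1000, 1e6), 10)
  # 3 reads on a 1.5 kb transcript in a 20 M library sit below the 0.2 cutoff
  expect_equal(relative_expression(3, 1500, 2e7), 0.1)
  expect_error(relative_expression(1, 0, 1e6), class = "spheroseq_parameter_error")
  expect_error(relative_expression(1, 1000, 0), class = "spheroseq_parameter_error")
})

test_that("detection filter uses AND semantics by default, OR when asked", {
  expect_false(is_detected(reads = 5, relexpr = 0.1))
  expect_true(is_detected(reads = 15, relexpr = 0.1))
  expect_true(is_detected(reads = 5, relexpr = 0.5))
  expect_false(is_detected(reads = 15, relexpr = 0.1, semantics = "or"))
  expect_false(is_detected(reads = 5, relexpr = 0.5, semantics = "or"))
  expect_true(is_detected(reads = 15, relexpr = 0.5, semantics = "or"))
})

test_that("signed fold change uses the negative-reciprocal convention", {
  expect_equal(signed_fold_change(30, 10), 3)
  expect_equal(signed_fold_change(10, 30), -3)
  expect_equal(signed_fold_change(17, 17), 1)
  expect_equal(abs(signed_fold_change(c(5, 50), c(50, 5))), c(10, 10))
  expect_error(signed_fold_change(10, 0),
               class = "spheroseq_undefined_fold_error")
  expect_equal(signed_fold_change(10, 0, pseudocount = 1), 11)
})

test_that("classification assigns the six statuses by definition", {
  x <- make_expression(
    reads_mono = c(10, 0, 100, 100, 100, 0),
    reads_mts  = c(40, 50, 0,   150, 100, 0)
  )
  calls <- classify_regulation(x, fc_on = "reads")
  expect_equal(as.character(calls$status),
               c("up", "de_novo", "switched_off", "unchanged", "unchanged",
                 "filtered"))
  expect_equal(calls$signed_fold_change[1], 4)
  expect_true(all(is.na(calls$signed_fold_change[c(2, 3, 6)])))
  # binary invariants
  expect_true(all(calls$detected_mts[calls$status == "de_novo"]))
  expect_false(any(calls$detected_mono[calls$status == "de_novo"]))
  expect_true(all(calls$detected_mono[calls$status == "switched_off"]))
  expect_false(any(calls$detected_mts[calls$status == "switched_off"]))
})

test_that("significance gating moves sub-threshold calls to unchanged", {
  x <- make_expression(reads_mono = c(100, 100), reads_mts = c(400, 400))
  x$significant <- c(TRUE, FALSE)
  calls <- classify_regulation(x, fc_on = "reads", require_significance = TRUE)
  expect_equal(as.character(calls$status), c("up", "unchanged"))
})

test_that("status partition is conserved and condition swap is antisymmetric", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 60
    x <- make_expression(
      reads_mono = rnbinom(n, mu = sample(c(0, 5, 100, 400), n, TRUE), size = 5),
      reads_mts  = rnbinom(n, mu = sample(c(0, 5, 100, 400), n, TRUE), size = 5)
    )
    calls <- classify_regulation(x)
    expect_equal(sum(table(calls$status)), n)

    swapped <- x
    names(swapped) <- c("transcript_id", "reads_mts", "reads_mono",
                        "relexpr_mts", "relexpr_mono")
    calls_sw <- classify_regulation(swapped)
    map <- c(up = "down", down = "up", de_novo = "switched_off",
             switched_off = "de_novo", unchanged = "unchanged",
             filtered = "filtered")
    expect_equal(as.character(calls_sw$status),
                 unname(map[as.character(calls$status)]))
    both <- !is.na(calls$signed_fold_change)
    expect_equal(calls_sw$signed_fold_change[both],
                 ifelse(abs(calls$signed_fold_change[both]) == 1,
                        calls$signed_fold_change[both],
                        -calls$signed_fold_change[both]))
  }
})

test_that("raising the fold threshold never increases the dysregulated count", {
  set.seed(11)
  x <- make_expression(
    reads_mono = rnbinom(200, mu = 100, size = 2) + 1,
    reads_mts = rnbinom(200, mu = 100, size = 2) + 1
  )
  thresholds <- c(1.5, 2, 3, 5, 10)
  n_dys <- sapply(thresholds, function(th) {
    calls <- classify_regulation(x, fc_threshold = th)
    sum(calls$status %in% c("up", "down"))
  })
  expect_true(all(diff(n_dys) <= 0))
})

test_that("regulation summary reproduces class counts and percentages", {
  mk_calls <- function(n_by_status) {
    tibble::tibble(
      transcript_id = sprintf("t%d", seq_len(sum(n_by_status))),
      status = factor(rep(names(n_by_status), n_by_status),
                      levels = regulation_statuses())
    )
  }
  calls <- mk_calls(c(up = 476, de_novo = 390, down = 238, switched_off = 398,
                      unchanged = 10, filtered = 2))
  s <- summarize_regulation(calls)
  expect_equal(sum(s$n), nrow(calls))
  expect_equal(s$n[s$status == "de_novo"], 390)
  expect_equal(unique(s$pct[s$class == "positive"]), 58)
  expect_equal(unique(s$pct[s$class == "negative"]), 42)

  # all-unchanged input: zero classes, flagged
  s0 <- summarize_regulation(mk_calls(c(unchanged = 5)))
  expect_equal(sum(s0$n[s0$class != "none"]), 0)
  expect_equal(attr(s0, "no_regulated"), "all")
  expect_error(summarize_regulation(calls[0, ]),
               class = "spheroseq_empty_summary_error")
})

test_that("class percentages round half-up the way the tallies are printed", {
  expect_equal(regulation_percentages(866, 636)$pct, c(58, 42))
  expect_equal(regulation_percentages(921, 201)$pct, c(82, 18))
  expect_equal(regulation_percentages(1, 3)$pct, c(25, 75))
})

test_that("length histogram bins are half-open and conserve counts", {
  h <- length_histogram(c(500, 1500, 3000))
  expect_equal(h$n, c(1, 1, 1))
  expect_equal(length_histogram(c(999, 1000, 2499, 2500))$n, c(1, 2, 1))
  expect_equal(length_histogram(numeric())$n, c(0, 0, 0))
  expect_error(length_histogram(c(10, -1)), class = "spheroseq_input_error")

  # counting draws directly: membership is deterministic given the bin draws
  set.seed(5)
  bins <- sample(1:3, 300, replace = TRUE, prob = c(0.6, 0.27, 0.13))
  lengths <- c(500, 1700, 4000)[bins]
  h2 <- length_histogram(lengths)
  expect_equal(h2$n, as.integer(table(factor(bins, levels = 1:3))))
  expect_equal(sum(h2$n), 300)
})
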