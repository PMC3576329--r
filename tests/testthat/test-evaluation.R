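# small synthetic truth + call tables for scoring checks
make_truth <- function(n = 1000) {
  feats <- data.frame(type = c("de_novo_del", "transmitted_del"),
                      start = c(101L, 501L), end = c(200L, 600L),
                      size = c(100L, 100L), state = c("332", "232"),
                      chrom = 1L, start_bp = c(101000, 501000),
                      end_bp = c(200000, 600000), stringsAsFactors = FALSE)
  state <- rep("333", n)
  state[101:200] <- "332"; state[501:600] <- "232"
  structure(list(state = state, features = feats, n_markers = n, chrom = 1L),
            class = "truth_track")
}

make_call <- function(start, end, state) {
  data.frame(chrom = 1L, start_bp = start * 1000, end_bp = end * 1000,
             start_index = start, end_index = end,
             n_markers = end - start + 1L, state = state,
             map_posterior = 0.99, log10_odds_vs_diploid = 5,
             is_de_novo = is_de_novo(state), stringsAsFactors = FALSE)
}

test_that("marker-level FP/FN counts match their definitions", {
  truth <- make_truth()
  perfect <- rbind(make_call(1, 100, "333"), make_call(101, 200, "332"),
                   make_call(201, 500, "333"), make_call(501, 600, "232"),
                   make_call(601, 1000, "333"))
  ev <- marker_fp_fn(perfect, truth)
  expect_equal(ev$fp, 0L)
  expect_equal(ev$fn, 0L)

  # everything diploid: all 100 de novo markers are missed
  all333 <- make_call(1, 1000, "333")
  ev <- marker_fp_fn(all333, truth)
  expect_equal(ev$fp, 0L)
  expect_equal(ev$fn, 100L)
  expect_equal(ev$fn_rate, 1)

  # a 20-marker de novo call inside a normal region: 20 false positives
  stray <- rbind(all333[0, ], make_call(701, 720, "332"))
  ev <- marker_fp_fn(stray, truth)
  expect_equal(ev$fp, 20L)
  expect_equal(ev$fp_rate, 20 / 900)

  bad <- make_call(990, 1020, "332")
  expect_error(marker_fp_fn(bad, truth), "marker index space")
})

test_that("feature detection applies the 50-percent rule inclusively", {
  truth <- make_truth()
  # exactly half the de novo feature called de novo: boundary counts
  half <- make_call(101, 150, "332")
  fd <- feature_detection(half, truth)
  expect_true(fd$detected[fd$type == "de_novo_del"])
  # 49 of 100: below the rule
  under <- make_call(101, 149, "332")
  fd <- feature_detection(under, truth)
  expect_false(fd$detected[fd$type == "de_novo_del"])

  # a transmitted feature swallowed by a de novo call is miscalled
  wrong <- make_call(490, 620, "332")
  fd <- feature_detection(wrong, truth)
  expect_true(fd$miscalled[fd$type == "transmitted_del"])

  # fractions agree with a brute-force recount
  calls <- rbind(make_call(101, 160, "332"), make_call(540, 560, "335"))
  fd <- feature_detection(calls, truth)
  ind <- rep(FALSE, 1000)
  ind[101:160] <- TRUE; ind[540:560] <- TRUE
  for (j in seq_len(nrow(fd)))
    expect_equal(fd$frac_called_de_novo[j],
                 mean(ind[fd$start[j]:fd$end[j]]))
})

test_that("FP and FN decompose by region type", {
  truth <- make_truth()
  calls <- rbind(make_call(101, 160, "332"),   # partial hit
                 make_call(550, 570, "332"),   # on the transmitted feature
                 make_call(801, 820, "332"))   # in background
  ev <- marker_fp_fn(calls, truth)
  expect_equal(ev$fn, 40L)            # 100 - 60 de novo markers missed
  expect_equal(ev$fp, 21L + 20L)      # transmitted + background strays
})

test_that("concordance at the top behaves on identifier lists", {
  a <- paste0("cnv", 1:10)
  expect_equal(concordance_at_top(a, a, 5), 1)
  expect_equal(concordance_at_top(a, paste0("other", 1:10), 5), 0)
  expect_equal(concordance_at_top(a, rev(a), 10), 1)
  b <- c("cnv1", paste0("x", 2:10))
  expect_equal(concordance_at_top(a, b, 1), 1)
  expect_equal(concordance_at_top(a, b, 4), 0.25)
  # symmetric in its arguments
  expect_equal(concordance_at_top(b, a, 4), concordance_at_top(a, b, 4))
  expect_error(concordance_at_top(a, b, 0), "positive")
  expect_error(concordance_at_top(a, b, 11), "exceeds")
})

test_that("concordance at the top matches intervals by reciprocal overlap", {
  la <- data.frame(chrom = c(1, 2, 3), start_bp = c(100, 500, 900),
                   end_bp = c(199, 599, 999))
  lb <- data.frame(chrom = c(1, 2, 4), start_bp = c(110, 1500, 900),
                   end_bp = c(205, 1599, 999))
  # first pair overlaps reciprocally ~90%; the others do not match
  expect_equal(concordance_at_top(la, lb, 3), 1 / 3)
  expect_equal(concordance_at_top(lb, la, 3), 1 / 3)
  # below 50% reciprocal overlap: no match
  lc <- data.frame(chrom = 1, start_bp = 160, end_bp = 400)
  expect_equal(concordance_at_top(la[1, ], lc, 1), 0)
})
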