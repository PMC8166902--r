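test_that("window means match direct recomputation and known values", {
  rows <- tibble::tibble(chrom = "chr1", pos = c(16268, 394612, 1.5e6),
                         delta = c(0.73, 0.58, 0.2))
  w <- window_scan(rows)
  expect_equal(w$mean_delta[w$start == 1], mean(c(0.73, 0.58)))
  expect_equal(w$mean_delta[w$start == 1e6 + 1], 0.2)  # single-SNP window
  expect_equal(w$n_snps, c(2L, 1L))

  set.seed(13)
  fuzz <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 500, replace = TRUE),
    pos = sample.int(5e6, 500),
    delta = runif(500, -1, 1)
  )
  got <- window_scan(fuzz)
  want <- oracle_window_means(fuzz)
  expect_equal(as.data.frame(got), want, ignore_attr = TRUE)

  shuffled <- fuzz[sample.int(nrow(fuzz)), ]
  expect_equal(window_scan(shuffled), got)
})

test_that("sliding windows are supported and bad geometry is rejected", {
  rows <- tibble::tibble(chrom = "chr1", pos = c(100, 1100, 2100),
                         delta = c(0.1, 0.3, 0.5))
  w <- window_scan(rows, window_size = 2000, step = 1000)
  expect_equal(w$start, c(1, 1001, 2001))
  expect_equal(w$mean_delta, c(mean(c(0.1, 0.3)), mean(c(0.3, 0.5)), 0.5))
  expect_error(window_scan(rows, window_size = 0), "positive")
  expect_error(window_scan(rows, step = -1), "positive")
})

test_that("null-band thresholds are reproducible and shrink as data improve", {
  b1 <- null_band(25, 25, n_reps = 5000, seed = 99)
  b2 <- null_band(25, 25, n_reps = 5000, seed = 99)
  expect_identical(b1$thresholds, b2$thresholds)
  expect_gte(b1$thresholds[["0.99"]], b1$thresholds[["0.95"]])
  expect_gt(b1$thresholds[["0.95"]], 0)

  # monotone in depth (fixed seeds, well-separated Monte-Carlo error)
  t10 <- null_band(25, 10, n_reps = 1e4, seed = 1)$thresholds[["0.95"]]
  t25 <- null_band(25, 25, n_reps = 1e4, seed = 2)$thresholds[["0.95"]]
  t100 <- null_band(25, 100, n_reps = 1e4, seed = 3)$thresholds[["0.95"]]
  expect_gt(t10, t25)
  expect_gt(t25, t100)

  # huge bulks and depth: the null delta degenerates towards zero
  tiny <- null_band(2500, 2500, n_reps = 500, seed = 4)$thresholds[["0.95"]]
  expect_lt(tiny, 0.05)
  expect_lt(tiny, t100 / 4)

  expect_error(null_band(0, 25), "bulk_size")
  expect_error(null_band(25, 25, n_reps = 50), "n_reps")
})

test_that("fresh null draws exceed the 95% threshold about 5% of the time", {
  band <- null_band(25, 25, n_sites = 1, n_reps = 1e4, seed = 7)
  set.seed(8)
  fresh <- mutmapr:::null_window_deltas(25, 25, n_sites = 1, n_reps = 1e4,
                                        min_depth = 7)
  rate <- mean(fresh > band$thresholds[["0.95"]])
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("region calling merges threshold-exceeding window runs", {
  win <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(1, 1e6 + 1, 2e6 + 1, 3e6 + 1, 1),
    end = c(1e6, 2e6, 3e6, 4e6, 1e6),
    n_snps = 5L,
    mean_delta = c(0.5, 0.6, 0.05, 0.4, 0.02)
  )
  r <- call_regions(win, band = 0.3)
  expect_equal(nrow(r), 2L)  # the gap at window 3 splits the chr1 run
  expect_equal(r$start, c(1, 3e6 + 1))
  expect_equal(r$end, c(2e6, 4e6))
  expect_equal(r$peak_start[1], 1e6 + 1)

  expect_equal(nrow(call_regions(win, band = 0.99)), 0L)
  all_hot <- call_regions(win, band = -0.5)
  expect_equal(nrow(all_hot), 2L)  # one region per chromosome
  expect_equal(all_hot$chrom, c("chr1", "chr2"))

  band <- null_band(25, 25, n_reps = 500, seed = 1)
  expect_error(call_regions(win, band, level = 0.5), "level")
})
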