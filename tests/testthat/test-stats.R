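test_that("spike_data validates its invariants", {
  expect_error(spike_data(list(c(3, 2, 1)), 10), "increasing")
  expect_error(spike_data(list(c(0, 11)), 10), "duration")
  s <- spike_data(list(c(0, 5), numeric(0)), 10)
  expect_equal(s$n_neurons, 2)
})

test_that("firing rates are counts over duration in Hz", {
  s <- spike_data(list(seq(0, 59999, by = 2000), numeric(0)), 60000)
  fr <- firing_rates(s)
  expect_equal(fr$values, c(0.5, 0))
  # Poisson counting statistics at rate lambda
  lam <- 8
  p <- make_poisson_trains(200, lam, 60000, seed = 5)
  est <- mean(firing_rates(p)$values)
  expect_lt(abs(est - lam), 3 * sqrt(lam / 60 / 200))
})

test_that("LV separates regular from irregular trains", {
  reg <- make_regular_trains(5, period = 100, duration = 60000)
  expect_true(all(local_variation(reg)$values == 0))
  # hand-evaluated two-ISI example: ISIs 10 and 30
  s <- spike_data(list(c(0, 10, 40)), 100)
  expect_equal(local_variation(s)$values, 0.75)
  # Poisson trains: expectation 1
  p <- make_poisson_trains(250, 5, 60000, seed = 6)   # ~300 spikes each
  lv <- local_variation(p)
  expect_equal(mean(lv$values), 1, tolerance = 0.05)
  # exclusion accounting
  few <- spike_data(list(c(1, 2), c(1, 5, 9)), 20)
  out <- local_variation(few)
  expect_equal(out$excluded, 1L)
  expect_length(out$values, 1)
  expect_warning(local_variation(spike_data(list(c(1, 2)), 10)), "excluded")
})

test_that("pairwise correlation behaves at its fixed points", {
  # identical trains correlate at exactly 1
  tr <- c(1, 7, 20, 33, 41, 58, 77, 90)
  s <- spike_data(list(tr, tr), 100)
  expect_equal(pairwise_correlation(s, bin_ms = 2)$values, 1)
  # perfectly linearly related binned counts
  a <- c(0.5, 4.5, 5.5, 6.5)          # bins (2 ms): 1,0,2,1
  b <- c(0.5, 1.2, 4.1, 4.5, 5.2, 5.7, 6.1, 6.6)  # bins: 2,0,4,2
  s2 <- spike_data(list(a, b), 8)
  expect_equal(pairwise_correlation(s2, bin_ms = 2)$values, 1)
  # independent Poisson trains decorrelate
  p <- make_poisson_trains(50, 20, 60000, seed = 8)   # 1225 pairs
  cc <- pairwise_correlation(p)
  expect_equal(mean(cc$values), 0, tolerance = 0.01)
  # zero-variance trains are excluded and counted
  s3 <- spike_data(list(tr, tr, numeric(0)), 100)
  out <- pairwise_correlation(s3)
  expect_equal(out$excluded, 2L)      # the two pairs involving the silent one
  expect_length(out$values, 1)
})

test_that("Cohen's d matches hand evaluation and Monte-Carlo", {
  expect_identical(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_identical(abs(cohens_d(c(3, 4, 5), c(1, 2, 3))), 2)
  # antisymmetry on arbitrary samples
  set.seed(4)
  x <- rnorm(50); y <- rnorm(70, 0.3)
  expect_identical(cohens_d(x, y), -cohens_d(y, x))
  # large-sample effect size recovers the true standardized difference
  set.seed(5)
  d <- cohens_d(rnorm(20000), rnorm(20000, 0.5))
  expect_equal(abs(d), 0.5, tolerance = 0.05)
  # degenerate variance
  expect_identical(cohens_d(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_identical(cohens_d(c(2, 2), c(1, 1)), Inf)
  expect_error(cohens_d(1, c(1, 2)), "size")
})

test_that("comparing a recording with itself gives zero effect sizes", {
  p <- make_poisson_trains(30, 10, 20000, seed = 11)
  cmp <- compare_spike_data(p, p)
  expect_identical(unname(cmp$d), c(0, 0, 0))
  # histograms of identical distributions agree bin for bin
  for (m in cmp$measures) {
    expect_length(m$histogram$counts_a, 70)
    expect_identical(m$histogram$counts_a, m$histogram$counts_b)
  }
  expect_error(compare_spike_data(p, make_poisson_trains(10, 10, 20000, 1)),
               "differ")
})

test_that("the three measures probe independent aspects of the dynamics", {
  # matched rates, different regularity: FR agrees while LV separates
  duration <- 60000
  reg <- make_regular_trains(100, period = 100, duration = duration)
  poi <- make_poisson_trains(100, 10, duration, seed = 13)
  cmp <- compare_spike_data(reg, poi)
  expect_lt(abs(cmp$d[["FR"]]), 0.35)
  expect_gt(abs(cmp$d[["LV"]]), 2)
})

test_that("state summaries aggregate effect sizes across reports", {
  p1 <- make_poisson_trains(20, 10, 10000, seed = 1)
  p2 <- make_poisson_trains(20, 10, 10000, seed = 2)
  p3 <- make_poisson_trains(20, 10, 10000, seed = 3)
  reps <- list(compare_spike_data(p1, p2), compare_spike_data(p1, p3))
  sm <- summarize_states(reps)
  expect_identical(sm$measure, c("FR", "LV", "CC"))
  expect_true(all(is.finite(sm$mean_d)))
  expect_true(all(sm$mean_abs_d >= 0))
})
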