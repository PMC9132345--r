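test_that("ISI histograms use 0.2 ms linear and 0.1 ln(ms) log bins", {
  h <- isi_histogram(rep(0.020, 60), "log")
  occupied <- h$centers[h$counts > 0]
  expect_length(occupied, 1)
  expect_lt(abs(occupied - log(20)), 0.05)
  hl <- isi_histogram(c(0.001, 0.001, 0.003), "linear")
  expect_equal(sum(hl$counts), 3)
  expect_equal(hl$counts[abs(hl$centers - 1.1) < 1e-9], 2)
  expect_equal(hl$counts[abs(hl$centers - 3.1) < 1e-9], 1)
  expect_equal(sum(isi_histogram(numeric(0), "log")$counts), 0)
  expect_error(isi_histogram(c(0.01, -0.01)), "> 0")
})

test_that("isi_peak reads the truncated log histogram and enforces 50 intervals", {
  set.seed(11)
  isi <- rexp(5000, 50)
  expect_equal(isi_peak(isi_histogram(isi, "log")), 20, tolerance = 0.25)
  burst <- rep(0.0013, 200)
  expect_equal(isi_peak(isi_histogram(burst, "log")), 1.3, tolerance = 0.1)
  expect_error(isi_peak(isi_histogram(rexp(40, 50), "log")), "insufficient")
  # intervals beyond 80 ms never win
  mix <- c(rep(0.005, 60), rep(0.5, 500))
  expect_lt(isi_peak(isi_histogram(mix, "log")), 80)
})

test_that("refractory period is the first bin above 1/200 of peak", {
  h <- isi_histogram(c(rep(0.00045, 5), rep(0.0006, 100), rep(0.01, 30)),
                     "linear")
  # counts 5 in the 0.4-0.6 ms bin qualify (5 > 100/200)
  expect_equal(refractory_period(h), 0.0004)
  h2 <- isi_histogram(rep(c(0.0001, 0.0005, 0.001), 20), "linear")
  expect_equal(refractory_period(h2), 0)
})

test_that("log_isi_drop hits its analytic extremes and flags bursting", {
  expect_equal(log_isi_drop(rep(0.002, 100)), 1, tolerance = 1e-6)
  expect_equal(log_isi_drop(rep(0.012, 100)), -1, tolerance = 1e-6)
  set.seed(12)
  pois <- rexp(2000, 40)
  expect_lt(log_isi_drop(pois), 0.2)
  burst <- c(rep(0.0013, 300), rexp(300, 10))
  expect_gt(log_isi_drop(burst), 0.5)
  expect_error(log_isi_drop(rep(0.002, 30)), "insufficient")
})

test_that("autocorrelogram equals brute-force pair counting and respects segments", {
  expect_equal(
    autocorrelogram(c(0.010, 0.0111))$counts[6], 1)  # 1.1 ms lag -> [1.0,1.2)
  set.seed(13)
  trains <- lapply(1:3, function(i) sort(runif(80, 0, 0.5)))
  ac <- autocorrelogram(trains)
  bf <- Reduce(`+`, lapply(trains, bf_autocorr_counts,
                           breaks_ms = ac$breaks, lag_max = 0.08))
  expect_equal(ac$counts, bf)
  # no pairs across segments: two single-spike segments yield nothing
  expect_equal(sum(autocorrelogram(list(0.01, 0.011))$counts), 0)
})

test_that("autocorrelogram metric contrasts short and long lags", {
  ac <- autocorrelogram(c(0, 0.001, 0.002, 0.0025))
  expect_equal(autocorrelogram_metric(ac), 1)
  flat <- structure(list(
    breaks = seq(0, 80, 0.2),
    centers = seq(0.1, 79.9, 0.2),
    counts = rep(5L, 400)), class = "autocorrelogram")
  expect_equal(autocorrelogram_metric(flat), 0)
  late <- flat; late$counts <- ifelse(late$centers >= 35, 10L, 0L)
  expect_equal(autocorrelogram_metric(late), -1)
  # invariant to uniform count rescaling
  doubled <- flat; doubled$counts <- flat$counts * 7L
  expect_equal(autocorrelogram_metric(doubled), autocorrelogram_metric(flat))
  empty <- flat; empty$counts <- rep(0L, 400)
  expect_true(is.na(autocorrelogram_metric(empty)))
})

test_that("intraburst frequency inverts the linear ISI peak", {
  expect_equal(intraburst_frequency(isi_histogram(rep(0.0013, 60), "linear")),
               1000 / 1.3, tolerance = 0.06)
  expect_equal(intraburst_frequency(isi_histogram(rep(0.0019, 60), "linear")),
               1000 / 1.9, tolerance = 0.06)
  expect_equal(intraburst_frequency(isi_histogram(rep(0.0099, 60), "linear")),
               100, tolerance = 0.02)
})

test_that("burst statistics count run lengths in spikes and normalize by Poisson", {
  bs <- burst_stats(c(1, 1, 50, 1, 1, 1) / 1000, isi_peak_ms = 1)
  expect_equal(bs$max_burst_len, 4)
  expect_equal(bs$mean_burst_len, 3.5)
  # perfectly periodic: consecutive-ISI ratio is constant 0.5
  per <- burst_stats(rep(0.01, 100), isi_peak_ms = 10)
  expect_equal(per$regularity, 0)
  set.seed(14)
  pois <- rexp(20000, 30)
  bp <- burst_stats(pois, isi_peak_ms = 1000 / 30)
  expect_equal(bp$pct_normalized, 1, tolerance = 0.05)
  expect_error(burst_stats(0.01, 1), "at least 2")
})

test_that("dip statistic matches closed-form anchors and calibrates on the null", {
  expect_equal(spiketypes:::dip_stat_cpp(seq(0, 1, length.out = 200)),
               1 / 400, tolerance = 1e-8)
  expect_equal(spiketypes:::dip_stat_cpp(rep(c(0, 1), each = 100)), 0.25)
  set.seed(15)
  u <- dip_test(runif(500), n_boot = 500, seed = 21)
  expect_gt(u$p_value, 0.05)
  bi <- dip_test(c(rnorm(250), rnorm(250, 6)), n_boot = 500, seed = 21)
  expect_lt(bi$p_value, 0.01)
  expect_error(dip_test(rnorm(5)), "at least 10")
})
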