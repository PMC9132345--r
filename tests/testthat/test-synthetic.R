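test_that("SAM envelope has 100% depth with the stated phase convention", {
  env <- sam_envelope(2, 0.5)
  expect_equal(env$amplitude[env$t == 0], 0)
  expect_equal(env$amplitude[which.min(abs(env$t - 0.25))], 1, tolerance = 1e-6)
  full <- sam_envelope(4, 1.0)
  expect_equal(mean(full$amplitude[full$t < 1.0]), 0.5, tolerance = 1e-3)
})

test_that("duration/ramp envelopes are flat-topped with linear onsets", {
  envs <- duration_and_ramp_envelopes()
  expect_length(envs, 6)  # 12.5 .. 400 ms
  e <- duration_and_ramp_envelopes(0.4, 0.005)[[1]]
  expect_true(all(e$amplitude[e$t >= 0.005 & e$t < 0.4] == 1))
  expect_equal(e$amplitude[e$t == 0.002][1], 0.4, tolerance = 1e-6)
  expect_error(duration_and_ramp_envelopes(0.025, 0.05), "ramp_time")
})

test_that("vocalization envelopes are seeded and trill mode peaks near 30 Hz", {
  a <- vocalization_envelope(4, 0.8, seed = 9)
  b <- vocalization_envelope(4, 0.8, seed = 9)
  expect_identical(a$amplitude, b$amplitude)
  one <- vocalization_envelope(1, 0.5, seed = 3)
  expect_equal(sum(diff(one$amplitude > 0.5 * max(one$amplitude)) == 1), 1)
  tr <- vocalization_envelope(12, 2.0, trill = TRUE, seed = 5)
  amp <- tr$amplitude - mean(tr$amplitude)
  spec <- Mod(fft(amp))[seq_len(length(amp) %/% 2)]
  freqs <- (seq_along(spec) - 1) / (length(tr$amplitude) * 0.001)
  band <- freqs > 5
  expect_lt(abs(freqs[band][which.max(spec[band])] - 30), 3)
})

test_that("poisson_train matches Poisson count and ISI laws", {
  n <- length(poisson_train(50, c(0, 100), seed = 1))
  expect_lt(abs(n - 5000), 3 * sqrt(5000))
  expect_length(poisson_train(0, c(0, 10), seed = 1), 0)
  isi <- diff(poisson_train(50, c(0, 2100), seed = 2))
  expect_gt(length(isi), 1e5)
  expect_lt(abs(mean(isi) - 1 / 50) / (1 / 50), 0.01)
  # mode of ln(ISI in ms) sits near ln(1000/rate) = 3 for 50 spk/s
  h <- isi_histogram(isi, "log")
  expect_lt(abs(h$centers[which.max(h$counts)] - 3), 0.2)
})

test_that("inhomogeneous thinning tracks the target rate", {
  rate <- function(t) 40 * (1 + sin(2 * pi * 0.5 * t)) / 2
  tr <- poisson_train(rate, c(0, 200), seed = 3)
  expect_lt(abs(length(tr) - 4000), 3 * sqrt(4000))
  # spikes concentrate where the rate is high
  ph <- (tr * 0.5) %% 1
  expect_gt(mean(ph > 0 & ph < 0.5), 0.75)
})

test_that("bursting trains carry the intraburst signature", {
  phen <- unit_phenotype("Bu1")
  tr <- bursting_train(8, phen, c(0, 300), seed = 4)
  isi <- diff(tr)
  h <- isi_histogram(isi, "linear")
  peak <- h$centers[which.max(h$counts)]
  expect_gte(peak, 1.2); expect_lte(peak, 1.4)
  # burst_prob = 0 collapses to a Poisson-like ISI law (KS on long intervals)
  phen0 <- phen; phen0$burst_prob <- 0
  t1 <- bursting_train(8, phen0, c(0, 400), seed = 5)
  t2 <- poisson_train(8, c(0, 400), refractory = phen$intraburst_interval * 2,
                      seed = 6)
  ks <- suppressWarnings(stats::ks.test(diff(t1), diff(t2)))
  expect_gt(ks$p.value, 0.01)
  # prestimulus-only activity still satisfies the bursting label definition
  segs <- lapply(1:300, function(i) {
    bursting_train(phen$spontaneous_rate, phen, c(0, 0.2),
                   seed = child_seed(401, i))
  })
  isis <- unlist(lapply(segs, diff))
  expect_gt(length(isis), 50)
  expect_gt(log_isi_drop(isis), 0.3)
})

test_that("synthetic waveforms honor the requested width and are seeded", {
  wf <- synth_waveform(0.0004, 10, noise_sd = 0, seed = 1)
  avg <- align_and_average(wf$snippets, wf$sample_rate_hz)
  wm <- width_metrics(avg)
  expect_equal(wm$t_ttp_s, 0.0004, tolerance = 0.05)
  wf2 <- synth_waveform(0.0004, 10, noise_sd = 0, seed = 1)
  expect_identical(wf$snippets, wf2$snippets)
  # narrower templates roll off at higher frequency
  f50s <- vapply(c(0.0003, 0.0005, 0.0007), function(ttp) {
    w <- synth_waveform(ttp, 8, noise_sd = 0, seed = 2)
    spectral_f50(align_and_average(w$snippets, w$sample_rate_hz))
  }, 0)
  expect_true(all(diff(f50s) < 0))
})

test_that("benchmark sessions are deterministic and carry ground truth", {
  a <- generate_benchmark_session(c(RS = 1, Bu1 = 1), protocols = "tuning",
                                  seed = 77)
  b <- generate_benchmark_session(c(RS = 1, Bu1 = 1), protocols = "tuning",
                                  seed = 77)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$waveforms, b$waveforms)
  expect_equal(a$units$truth_type, c("RS", "Bu1"))
  expect_error(generate_benchmark_session(c(RS = 1), protocols = "nope"),
               "unknown protocol")
  ses <- tiny_session()
  expect_equal(nrow(ses$units), 8)
  expect_setequal(unique(ses$spikes$protocol), "tuning")
})
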