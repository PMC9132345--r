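test_that("PSTH smoothing conserves spike count and handles empty input", {
  ps <- smoothed_psth(list(0.1), c(0, 0.3))
  expect_equal(sum(ps$rate) * 0.001, 1, tolerance = 1e-3)
  empty <- smoothed_psth(list(numeric(0), numeric(0)), c(0, 0.2))
  expect_true(all(empty$rate == 0))
  set.seed(51)
  trains <- lapply(1:20, function(i) poisson_train(40, c(0, 1)))
  flat <- smoothed_psth(trains, c(0, 1))
  expect_equal(mean(flat$rate), 40, tolerance = 0.1)
  expect_lt(sd(flat$rate), 15)
})

test_that("response windows follow the onset+10ms / offset+50ms rule", {
  tone <- tibble::tibble(kind = "tone", onset_s = 0, duration_s = 0.2)
  expect_equal(response_window(tone), c(0.010, 0.250))
  voc <- tibble::tibble(kind = "vocalization", onset_s = 0, duration_s = 1)
  expect_equal(response_window(voc), c(0.010, 1.150))
  short <- tibble::tibble(kind = "tone", onset_s = 0, duration_s = 0.0125)
  expect_equal(response_window(short), c(0.010, 0.0625))
})

test_that("rate responsiveness applies the duration-corrected 3 SE rule", {
  # build a unit whose prestim rates have known mean/variance, then compare
  # the threshold arithmetic directly
  pre_rates <- c(3, 5, 7, 5)  # mean 5, var 8/3
  t_pre <- 0.2
  st <- tibble::tibble(kind = "tone", onset_s = 0, duration_s = 0.19)
  win <- response_window(st)
  thr <- mean(pre_rates) +
    3 * sqrt(var(pre_rates) * (t_pre / diff(win)) / length(pre_rates))
  expect_equal(thr, 5 + 3 * sqrt((8 / 3) * (0.2 / diff(win)) / 4),
               tolerance = 1e-12)
  # and on a synthetic unit: a strongly driven stimulus is flagged, its
  # unpreferred twin is not
  ses <- tiny_session()
  truth <- truth_of(ses)
  u <- names(truth)[truth == "FS"][1]
  st2 <- ses$stimuli
  resp <- vapply(st2$stimulus_id, function(s) {
    responsive_by_rate(ses, u, s, "tuning")
  }, TRUE)
  expect_true(any(resp))
})

test_that("PSTH responsiveness uses the exact Poisson tail with Bonferroni", {
  # lambda 1.0, max bin 12, 100 bins: P(X >= 12) ~ 1e-9 << 1e-4
  expect_lt(ppois(11, 1, lower.tail = FALSE), 0.01 / 100)
  # max bin equal to the mean is never significant
  expect_gt(ppois(0, 1, lower.tail = FALSE), 0.01 / 100)
  # an onset-bursting unit responds by PSTH even when its mean driven rate
  # over the long window stays near spontaneous
  ses <- tiny_session()
  truth <- truth_of(ses)
  u <- names(truth)[truth == "Bu1"][1]
  st <- ses$stimuli$stimulus_id
  by_psth <- vapply(st, function(s) responsive_by_psth(ses, u, s, "tuning"),
                    TRUE)
  expect_true(any(by_psth))
})

test_that("adaptation index follows its arithmetic and time-reversal antisymmetry", {
  onset <- list(rep(0.02, 30), rep(0.03, 10))
  expect_equal(adaptation_index(onset), 1)
  expect_equal(adaptation_index(list(c(rep(0.05, 30), rep(0.2, 10)))), 0.5)
  stationary <- list(seq(0.011, 0.249, by = 0.002))
  expect_equal(adaptation_index(stationary), 0, tolerance = 0.05)
  expect_true(is.na(adaptation_index(list(numeric(0)))))
  # reflecting spikes about the response-window midpoint flips the sign
  tr <- c(0.02, 0.03, 0.05, 0.2)
  flipped <- sort(0.26 - tr)
  expect_equal(adaptation_index(list(tr)), -adaptation_index(list(flipped)))
})

test_that("vector strength and Rayleigh significance follow their definitions", {
  ses <- mid_session()
  truth <- truth_of(ses)
  vp <- vs_profile(ses, names(truth)[truth == "Bu1"][1])
  expect_true(all(vp$vs[!is.na(vp$vs)] >= 0 & vp$vs[!is.na(vp$vs)] <= 1))
  expect_equal(vp$rayleigh, 2 * vp$n * vp$vs^2, tolerance = 1e-9)
  expect_true(all(vp$vs_reported[!vp$significant] == 0))
  # a Rayleigh value of exactly 13.8 is not significant (strict inequality);
  # VS = 0.1 at N = 690 sits exactly on that boundary
  expect_false(13.8 > 13.8)
  expect_equal(2 * 690 * 0.1^2, 13.8)
  # uniform phases are almost never significant
  set.seed(52)
  sig <- vapply(1:200, function(i) {
    th <- runif(200, 0, 2 * pi)
    vs <- Mod(sum(exp(1i * th))) / 200
    2 * 200 * vs^2 > 13.8
  }, TRUE)
  expect_lte(mean(sig), 0.02)
})

test_that("VS is invariant to a constant phase rotation", {
  spikes <- sort(runif(300, 0.05, 1.0))
  f <- 8
  vs0 <- Mod(sum(exp(1i * 2 * pi * f * spikes))) / 300
  vs1 <- Mod(sum(exp(1i * (2 * pi * f * spikes + 1.23)))) / 300
  expect_equal(vs0, vs1, tolerance = 1e-12)
})

test_that("SAM summary interpolates f_max and takes a weighted geometric tBMF", {
  prof <- tibble::tibble(
    mod_rate_hz = c(4, 8, 16, 32),
    n = c(200, 200, 200, 200),
    vs = c(0.6, 0.6, 0.5, 0.05),
    rayleigh = c(144, 144, 50, 5),
    significant = c(TRUE, TRUE, TRUE, FALSE),
    vs_reported = c(0.6, 0.6, 0.5, 0))
  s <- sam_summary(prof)
  # crossing between 16 (50) and 32 (5): log2 interpolation
  expected <- 2^(4 + (50 - 13.8) / (50 - 5))
  expect_equal(s$f_max_hz, expected, tolerance = 1e-9)
  expect_true(s$sync_4 && s$sync_16)
  # equal VS at 4 and 8 only: unweighted geometric mean sqrt(32)
  prof2 <- prof
  prof2$significant <- c(TRUE, TRUE, FALSE, FALSE)
  prof2$vs_reported <- c(0.6, 0.6, 0, 0)
  expect_equal(sam_summary(prof2)$tbmf_hz, sqrt(4 * 8), tolerance = 1e-9)
  # a single significant rate cannot define tBMF but can synchronize
  prof3 <- prof
  prof3$significant <- c(FALSE, FALSE, TRUE, FALSE)
  prof3$vs_reported <- c(0, 0, 0.6, 0)
  s3 <- sam_summary(prof3)
  expect_true(is.na(s3$tbmf_hz))
  expect_true(s3$sync_4 && s3$sync_16)
  # highest tested rate significant: f_max equals that rate
  prof4 <- prof
  prof4$significant <- rep(TRUE, 4)
  prof4$rayleigh[4] <- 40
  expect_equal(sam_summary(prof4)$f_max_hz, 32)
  # nothing significant, no rate response: excluded
  prof5 <- prof
  prof5$significant <- rep(FALSE, 4)
  s5 <- sam_summary(prof5, rate_responsive = FALSE)
  expect_true(s5$excluded)
  expect_false(s5$unsynchronized)
  expect_true(sam_summary(prof5, rate_responsive = TRUE)$unsynchronized)
})

test_that("period histograms integrate to one and expose rising-phase locking", {
  ses <- mid_session()
  truth <- truth_of(ses)
  u <- names(truth)[truth == "Bu1"][1]
  ph <- period_histogram(ses, u, mod_rate_hz = 8)
  expect_equal(sum(ph$density) * 2 * pi / nrow(ph), 1, tolerance = 1e-9)
  # envelope 0.5(1-cos) rises over phase (0, pi): spikes should favor it
  rising_mass <- sum(ph$density[ph$phase < pi]) / sum(ph$density)
  expect_gt(rising_mass, 0.6)
})

test_that("onset latency tracks the generator's response latency", {
  ses <- tiny_session()
  truth <- truth_of(ses)
  u <- names(truth)[truth == "Bu1"][1]
  lat <- onset_latency(ses, u)
  expect_gt(lat, 0.004)
  expect_lt(lat, 0.030)
})
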