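test_that("vp_distance matches closed forms", {
  expect_equal(vp_distance(0.010, 0.015, 100), 0.5)  # min(2, q dt)
  expect_equal(vp_distance(0.010, 0.040, 100), 2)    # shift beyond 2/q
  expect_equal(vp_distance(c(1, 2, 3), c(1, 2, 3, 4, 5), 0), 2)
  expect_equal(vp_distance(numeric(0), c(1, 2), 10), 2)
  expect_equal(vp_distance(c(1, 2), c(1, 2), 50), 0)
  expect_error(vp_distance(1, 2, -1), ">= 0")
})

test_that("the dynamic program equals the exhaustive matching oracle", {
  set.seed(71)
  for (i in 1:300) {
    na <- sample(0:8, 1); nb <- sample(0:8, 1)
    a <- sort(runif(na, 0, 0.3)); b <- sort(runif(nb, 0, 0.3))
    q <- sample(c(0, 5, 20, 100, 1000), 1)
    expect_equal(vp_distance(a, b, q), bf_vp(a, b, q), tolerance = 1e-12)
  }
})

test_that("the metric axioms hold and the large-q limit is the spike count sum", {
  set.seed(72)
  for (i in 1:300) {
    tr <- lapply(1:3, function(j) sort(runif(sample(0:20, 1), 0, 0.5)))
    q <- runif(1, 0, 200)
    dab <- vp_distance(tr[[1]], tr[[2]], q)
    dba <- vp_distance(tr[[2]], tr[[1]], q)
    dac <- vp_distance(tr[[1]], tr[[3]], q)
    dbc <- vp_distance(tr[[2]], tr[[3]], q)
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_gte(dac + dbc + 1e-12, dab)
    expect_equal(vp_distance(tr[[1]], tr[[1]], q), 0)
  }
  a <- c(0.1, 0.2, 0.3); b <- c(0.15, 0.25)
  expect_equal(vp_distance(a, b, 1e9), 5)
  expect_lte(vp_distance(a, b, 37), 5)
})

test_that("crop_and_center centers segments on the response density peak", {
  trains <- list(S1 = list(c(0.29, 0.30, 0.31), c(0.295, 0.305)))
  out <- crop_and_center(trains, 0.2, c(S1 = 0.6))
  seg <- attr(out, "segments")$S1
  expect_equal(seg, c(0.2, 0.4), tolerance = 0.01)
  expect_equal(sum(lengths(out$S1)), 5)  # counts conserved inside the segment
  # a cluster near the edge clips the segment into the window
  trains2 <- list(S1 = list(c(0.04, 0.05, 0.06)))
  out2 <- crop_and_center(trains2, 0.2, c(S1 = 0.6))
  expect_equal(attr(out2, "segments")$S1[1], 0)
  # no spikes at all: anchored at stimulus onset
  out3 <- crop_and_center(list(S1 = list(numeric(0))), 0.2, c(S1 = 0.6))
  expect_equal(attr(out3, "segments")$S1, c(0, 0.2))
})

test_that("train classification is exact for separable responses and fair under ties", {
  trains <- c(lapply(1:5, function(i) 0.02 + i * 1e-4),
              lapply(1:5, function(i) 0.12 + i * 1e-4))
  labels <- rep(c("A", "B"), each = 5)
  cm <- classify_trains(trains, labels, q = 50)
  expect_equal(unclass(cm), matrix(c(5, 0, 0, 5), 2,
               dimnames = list(true = c("A", "B"), decoded = c("A", "B"))))
  # identical responses to both stimuli: uniform fractional tallies
  same <- rep(list(c(0.05, 0.1)), 6)
  cm2 <- classify_trains(same, rep(c("A", "B"), each = 3), q = 50)
  expect_equal(unclass(cm2),
               matrix(1.5, 2, 2, dimnames = dimnames(cm2)))
  # jittered two-stimulus toy decodes nearly perfectly
  set.seed(73)
  toy <- c(lapply(1:10, function(i) 0.020 + rnorm(1, 0, 0.002)),
           lapply(1:10, function(i) 0.120 + rnorm(1, 0, 0.002)))
  cmt <- classify_trains(toy, rep(c("A", "B"), each = 10), q = 50)
  expect_gt(sum(diag(cmt)) / sum(cmt), 0.95)
})

test_that("transmitted information matches closed forms and its bounds", {
  expect_equal(transmitted_information(diag(20)), log2(20), tolerance = 1e-9)
  cm <- matrix(c(9, 1, 1, 9), 2, byrow = TRUE)
  h <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(transmitted_information(cm), 1 - h(0.1), tolerance = 1e-9)
  expect_equal(transmitted_information(matrix(1, 4, 4)), 0)
  # invariant under simultaneous row/column permutation
  set.seed(74)
  m <- matrix(rpois(25, 4), 5)
  p <- sample(5)
  expect_equal(transmitted_information(m),
               transmitted_information(m[p, p]), tolerance = 1e-12)
})

test_that("q_sweep normalizes to its max and the shuffle null is centered at chance", {
  set.seed(75)
  trains <- c(lapply(1:8, function(i) sort(c(0.02 + rnorm(1, 0, 0.002),
                                             0.15 + rnorm(1, 0, 0.002)))),
              lapply(1:8, function(i) 0.08 + rnorm(1, 0, 0.002)))
  labels <- rep(c("A", "B"), each = 8)
  qs <- q_sweep(trains, labels, q_grid = c(0, 4, 16, 64), n_shuffles = 40,
                seed = 6)
  expect_equal(max(qs$sweep$h_norm), 1)
  expect_true(qs$include)
  # shuffling destroys the information
  null <- q_sweep(trains, sample(labels), q_grid = c(16), n_shuffles = 40,
                  seed = 7)
  expect_lt(max(null$sweep$h_bits), max(qs$sweep$h_bits))
})
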