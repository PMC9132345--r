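fv <- function(...) tibble::tibble(...)

test_that("bursting criteria need 3 of 3, leave 2 of 3 unclassified", {
  expect_equal(classify_bursting_criteria(
    fv(isi_peak_ms = 2, acm = 0.8, log_isi_drop = 0.9)), "Bu")
  expect_equal(classify_bursting_criteria(
    fv(isi_peak_ms = 2, acm = 0.8, log_isi_drop = 0.1)), "unclassified")
  expect_equal(classify_bursting_criteria(
    fv(isi_peak_ms = 30, acm = 0.1, log_isi_drop = 0)), "nonbursting")
  expect_equal(classify_bursting_criteria(
    fv(isi_peak_ms = NA, acm = 0.8, log_isi_drop = 0.9)), "unclassifiable")
  # boundaries are strict
  expect_equal(classify_bursting_criteria(
    fv(isi_peak_ms = 10, acm = 0.8, log_isi_drop = 0.9)), "unclassified")
})

test_that("PBu thresholds the prestimulus drop at 0.3", {
  expect_true(classify_pbu(fv(prestim_log_isi_drop = 0.86)))
  expect_false(classify_pbu(fv(prestim_log_isi_drop = 0.29)))
  expect_false(classify_pbu(fv(prestim_log_isi_drop = 0.30)))
  expect_true(is.na(classify_pbu(fv(prestim_log_isi_drop = NA))))
})

test_that("RS/FS rules need a 2-of-3 quorum and reject bursting units", {
  expect_equal(classify_rs_fs_criteria(
    fv(t_ttp_ms = 0.3, f50_hz = 3000, spontaneous_rate = 10)), "FS")
  expect_equal(classify_rs_fs_criteria(
    fv(t_ttp_ms = 0.7, f50_hz = 1500, spontaneous_rate = 1)), "RS")
  expect_equal(classify_rs_fs_criteria(
    fv(t_ttp_ms = 0.3, f50_hz = 1500, spontaneous_rate = 4)), "unclassified")
  expect_error(classify_rs_fs_criteria(
    fv(t_ttp_ms = 0.3, f50_hz = 3000, spontaneous_rate = 10), "Bu"),
    "bursting")
})

test_that("Bu1/Bu2 split thresholds intraburst frequency at 500 Hz", {
  f <- fv(intraburst_freq_hz = c(769, 500, 400),
          log_isi_drop = c(0.9, 0.8, 0.7), latency_ms = c(8, 12, 15))
  expect_equal(split_bu_subgroups(f, "criterion"), c("Bu1", "Bu2", "Bu2"))
  expect_error(split_bu_subgroups(f, "gmm"), "at least 6")
  # on a bimodal pool the unsupervised split agrees with the criterion split
  set.seed(31)
  pool <- fv(
    intraburst_freq_hz = c(rnorm(20, 750, 40), rnorm(20, 380, 40)),
    log_isi_drop = c(rnorm(20, 0.9, 0.05), rnorm(20, 0.7, 0.05)),
    latency_ms = c(rnorm(20, 8, 1.5), rnorm(20, 14, 2)))
  crit <- split_bu_subgroups(pool, "criterion")
  gmm <- split_bu_subgroups(pool, "gmm", seed = 4)
  expect_gte(mean(crit == gmm), 0.85)
})

test_that("feature matrix is standardized with the stated log-offset rule", {
  set.seed(32)
  base <- tibble::tibble(
    unit_id = sprintf("u%02d", 1:40),
    acm = rnorm(40), isi_peak_ms = runif(40, 1, 60),
    log_isi_drop = rnorm(40, 0, 0.3),
    pct_isi_lt_5ms = c(rexp(39, 0.05)^2, 0),  # heavy right skew, with a zero
    spontaneous_rate = runif(40, 0, 20), f50_hz = runif(40, 800, 3000),
    max_burst_len = pmax(1, rpois(40, 2)), max_firing_rate = runif(40, 5, 60))
  m <- build_feature_matrix(base)
  expect_equal(unname(colMeans(m)), rep(0, 8), tolerance = 1e-9)
  expect_equal(unname(apply(m, 2, sd)), rep(1, 8), tolerance = 1e-9)
  logged <- attr(m, "logged")
  expect_true(logged[match("pct_isi_lt_5ms", colnames(m))])
  # the offset applied before log is half the minimum positive value
  v <- base$pct_isi_lt_5ms
  off <- min(v[v > 0]) / 2
  recon <- scale(log(v + off))
  expect_equal(unname(m[, "pct_isi_lt_5ms"]), as.numeric(recon),
               tolerance = 1e-9)
  # symmetric columns stay untransformed; constant columns are an error
  expect_false(logged[match("acm", colnames(m))])
  cst <- base; cst$acm <- 1
  expect_error(build_feature_matrix(cst), "constant")
})

test_that("BIC and held-out likelihood recover the true component count", {
  set.seed(33)
  mu <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0))
  x <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(100 * 3), ncol = 3), 2, mu[i, ], "+")
  }))
  colnames(x) <- c("pc1", "pc2", "pc3")
  bic <- vapply(1:5, function(k) {
    spiketypes:::best_gmm(x, k, n_seeds = 10, seed = k)$bic
  }, 0)
  expect_equal(which.min(bic), 3L)
  cv <- vapply(c(3, 5), function(k) {
    spiketypes:::cv_nll_gmm(x, k, n_splits = 10, seed = 200 + k)
  }, 0)
  expect_gt(cv[2], cv[1])  # overfitting beyond the true k
  # a single Gaussian cloud selects one component
  y <- matrix(rnorm(300 * 3), ncol = 3)
  bic1 <- vapply(1:3, function(k) {
    spiketypes:::best_gmm(y, k, n_seeds = 10, seed = 50 + k)$bic
  }, 0)
  expect_equal(which.min(bic1), 1L)
})

test_that("posterior assignment demands a 2x margin and rows sum to one", {
  set.seed(34)
  mk <- function(n, acm, spont, f50) tibble::tibble(
    acm = rnorm(n, acm, 0.1), isi_peak_ms = runif(n, 1, 50),
    log_isi_drop = rnorm(n, acm, 0.2), pct_isi_lt_5ms = runif(n, 0, 60),
    spontaneous_rate = rnorm(n, spont, 1.5), f50_hz = rnorm(n, f50, 200),
    max_burst_len = runif(n, 1, 6), max_firing_rate = rnorm(n, 25, 6))
  fx <- dplyr::bind_rows(mk(16, 0.05, 2, 1200),   # RS-like
                         mk(12, 0.0, 14, 2500),   # FS-like
                         mk(12, 0.9, 3, 1700))    # Bu-like
  fx$unit_id <- sprintf("u%02d", seq_len(nrow(fx)))
  fm <- build_feature_matrix(fx)
  fit <- fit_pca_gmm(fm, k_range = 3, n_seeds = 8, n_splits = 2, seed = 9)
  g <- assign_types_gmm(fit, fm)
  post <- as.matrix(g[, c("posterior_rs", "posterior_fs", "posterior_bu")])
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-9)
  assigned <- g$label %in% c("RS", "FS", "Bu")
  margins <- apply(post, 1, function(p) {
    s <- sort(p, decreasing = TRUE); s[1] / s[2]
  })
  expect_true(all(margins[assigned] >= 2 - 1e-9))
  expect_true(all(margins[!assigned & !is.na(g$label)] < 2))
})

test_that("label agreement is scored over units labeled by both methods", {
  a <- tibble::tibble(unit_id = c("a", "b", "c", "d"),
                      label = c("RS", "FS", "Bu1", "unclassified"))
  b <- tibble::tibble(unit_id = c("a", "b", "c", "d"),
                      label = c("RS", "FS", "Bu", "RS"))
  expect_equal(agreement_matrix(a, b)$agreement, 1)
  b2 <- b; b2$label <- c("FS", "RS", "RS", "RS")
  expect_equal(agreement_matrix(a, b2)$agreement, 0)
  expect_error(agreement_matrix(a, tibble::tibble(unit_id = "z", label = "RS")),
               "share no units")
})

test_that("criteria labels are a pure function of the feature row", {
  ses <- tiny_session()
  fx <- unit_features(ses)
  labs <- classify_criteria(fx)
  shuffled <- classify_criteria(fx[rev(seq_len(nrow(fx))), ])
  merged <- merge(labs, shuffled, by = "unit_id")
  expect_equal(merged$label.x, merged$label.y)
})
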