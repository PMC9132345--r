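#' Criteria-based bursting classification
#'
#' A unit is bursting (Bu) when it satisfies all three of: ISI peak < 10 ms,
#' autocorrelogram metric > 0.5, logISIdrop > 0.2. With exactly 2 of 3 the
#' unit is left unclassified (ambiguous); with <= 1 it is nonbursting.
#'
#' @param features One-row data frame (or tibble row) with `isi_peak_ms`,
#'   `acm`, `log_isi_drop`.
#' @return `"Bu"`, `"unclassified"`, `"nonbursting"`, or `"unclassifiable"`
#'   when a feature is missing.
#' @export
classify_bursting_criteria <- function(features) {
  v <- c(features$isi_peak_ms, features$acm, features$log_isi_drop)
  if (length(v) < 3L || any(is.na(v))) return("unclassifiable")
  n_met <- (features$isi_peak_ms < 10) + (features$acm > 0.5) +
    (features$log_isi_drop > 0.2)
  if (n_met == 3) "Bu" else if (n_met == 2) "unclassified" else "nonbursting"
}

#' Prestimulus-only bursting label (PBu)
#'
#' `TRUE` when the logISIdrop computed from pooled prestimulus intervals
#' alone exceeds 0.3, identifying bursting from spontaneous activity with no
#' influence of driven bursts.
#'
#' @param features One-row data frame with `prestim_log_isi_drop`.
#' @return `TRUE`, `FALSE`, or `NA` when the prestimulus score could not be
#'   computed (fewer than 50 prestimulus intervals).
#' @export
classify_pbu <- function(features) {
  s <- features$prestim_log_isi_drop
  if (is.null(s) || is.na(s)) return(NA)
  s > 0.3
}

#' Criteria-based RS/FS classification of nonbursting units
#'
#' FS requires at least 2 of: t_TTP < 0.5 ms, f50 > 2 kHz, spontaneous
#' rate > 5 spk/s. RS requires at least 2 of: t_TTP > 0.5 ms, f50 < 2 kHz,
#' spontaneous rate < 3 spk/s. Units meeting both or neither quorum stay
#' unclassified.
#'
#' @param features One-row data frame with `t_ttp_ms`, `f50_hz`,
#'   `spontaneous_rate`.
#' @param bursting Label from [classify_bursting_criteria()]; calling this on
#'   a bursting unit is a contract violation.
#' @return `"RS"`, `"FS"` or `"unclassified"`.
#' @export
classify_rs_fs_criteria <- function(features, bursting = "nonbursting") {
  if (identical(bursting, "Bu")) {
    abort("classify_rs_fs_criteria called on a bursting unit")
  }
  fs <- sum(features$t_ttp_ms < 0.5, features$f50_hz > 2000,
            features$spontaneous_rate > 5, na.rm = TRUE)
  rs <- sum(features$t_ttp_ms > 0.5, features$f50_hz < 2000,
            features$spontaneous_rate < 3, na.rm = TRUE)
  if (fs >= 2 && rs < 2) "FS" else if (rs >= 2 && fs < 2) "RS"
  else "unclassified"
}

#' Split bursting units into Bu1 and Bu2
#'
#' Criterion mode thresholds the intraburst frequency at 500 Hz (> 500 Hz is
#' Bu1, <= 500 Hz Bu2). GMM mode fits a 2-component full-covariance mixture
#' to intraburst frequency, logISIdrop and latency and labels the component
#' with the higher mean intraburst frequency Bu1.
#'
#' @param features Tibble of bursting units with `intraburst_freq_hz`,
#'   `log_isi_drop`, `latency_ms`.
#' @param mode `"criterion"` or `"gmm"`.
#' @param seed Seed for GMM initialization.
#' @return Character vector of `"Bu1"`/`"Bu2"` labels.
#' @export
split_bu_subgroups <- function(features, mode = c("criterion", "gmm"),
                               seed = 1) {
  mode <- match.arg(mode)
  if (mode == "criterion") {
    return(ifelse(features$intraburst_freq_hz > 500, "Bu1", "Bu2"))
  }
  if (nrow(features) < 6L) abort("gmm split needs at least 6 bursting units")
  m <- scale(as.matrix(features[, c("intraburst_freq_hz", "log_isi_drop",
                                    "latency_ms")]))
  m[is.na(m)] <- 0
  fit <- best_gmm(m, k = 2, n_seeds = 20, seed = seed)
  mu_ibf <- fit$parameters$mean[1, ]
  bu1 <- which.max(mu_ibf)
  ifelse(mclust_map(fit) == bu1, "Bu1", "Bu2")
}

#' Full criteria-based classification of a feature table
#'
#' Applies the sequential criteria logic: bursting first (3-of-3 rule), then
#' prestimulus-only bursting (PBu, with Bu/PBu disagreement flagged
#' `bursting_ambiguous`), then RS/FS on the remaining nonbursting units, and
#' finally the Bu1/Bu2 intraburst-frequency split.
#'
#' @param features Tibble from [unit_features()].
#' @return Tibble `unit_id`, `label` (RS, FS, Bu1, Bu2, unclassified,
#'   bursting_ambiguous, unclassifiable), `bursting` (raw 3-criteria call),
#'   `pbu` (logical), `method = "criteria"`.
#' @export
classify_criteria <- function(features) {
  purrr::map_dfr(seq_len(nrow(features)), function(i) {
    fv <- features[i, ]
    b <- classify_bursting_criteria(fv)
    pbu <- classify_pbu(fv)
    label <- if (b == "Bu") {
      split_bu_subgroups(fv, "criterion")
    } else if (b %in% c("nonbursting", "unclassified") && isTRUE(pbu)) {
      "bursting_ambiguous"
    } else if (b == "nonbursting") {
      classify_rs_fs_criteria(fv, b)
    } else {
      "unclassified"
    }
    if (b == "unclassifiable") label <- "unclassifiable"
    tibble::tibble(unit_id = fv$unit_id, label = label, bursting = b,
                   pbu = pbu, method = "criteria")
  })
}

# ---- GMM route --------------------------------------------------------------

gmm_feature_names <- c("acm", "isi_peak_ms", "log_isi_drop", "pct_isi_lt_5ms",
                       "spontaneous_rate", "f50_hz", "max_burst_len",
                       "max_firing_rate")

#' Standardized (optionally log-transformed) feature matrix
#'
#' Selects the 8 clustering features, log-transforms strongly skewed columns
#' (|sample skewness| > 2; zeros handled by adding half the minimum positive
#' value first), and standardizes every column to mean 0, SD 1. Rows with any
#' missing value are tracked via the `complete` attribute.
#'
#' @param features Tibble from [unit_features()].
#' @param skew_threshold Absolute skewness above which a column is
#'   log-transformed (default 2).
#' @return Numeric matrix with attributes `complete` (logical per row),
#'   `logged` (logical per column), `unit_id`.
#' @export
build_feature_matrix <- function(features, skew_threshold = 2) {
  m <- as.matrix(features[, gmm_feature_names])
  logged <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- !is.na(v)
    if (sd(v[ok]) == 0) {
      abort(sprintf("feature '%s' is constant", gmm_feature_names[j]))
    }
    g1 <- skewness(v[ok])
    if (is.finite(g1) && abs(g1) > skew_threshold) {
      off <- if (any(v[ok] <= 0)) {
        pos <- v[ok][v[ok] > 0]
        if (length(pos)) min(pos) * 0.5 else 1e-6
      } else {
        0
      }
      m[, j] <- log(v + off)
      logged[j] <- TRUE
      if (sd(m[ok, j]) == 0) {
        abort(sprintf("feature '%s' is constant after log",
                      gmm_feature_names[j]))
      }
    }
    m[, j] <- (m[, j] - mean(m[ok, j])) / sd(m[ok, j])
  }
  structure(m, complete = stats::complete.cases(m), logged = logged,
            unit_id = features$unit_id)
}

skewness <- function(x) {
  n <- length(x)
  s <- sd(x)
  if (s == 0 || n < 3) return(0)
  mean((x - mean(x))^3) / s^3
}

# Best-of-n_seeds full-covariance GMM via EM with random soft initializations;
# selection by AIC. Returns the mclust-style fit (or NULL if nothing
# converged).
best_gmm <- function(x, k, n_seeds = 20, seed = 1) {
  x <- as.matrix(x)
  best <- NULL; best_aic <- Inf
  for (s in seq_len(n_seeds + 1L)) {
    fit <- with_seed(child_seed(seed, s), {
      z <- if (s > n_seeds && k > 1 && nrow(x) > k) {
        # one deterministic k-means-seeded start alongside the random ones
        km <- tryCatch(stats::kmeans(x, k, nstart = 5), error = function(e) NULL)
        if (is.null(km)) NULL else mclust::unmap(km$cluster, groups = 1:k)
      } else {
        zr <- matrix(rexp(nrow(x) * k), nrow(x))
        zr / rowSums(zr)
      }
      if (is.null(z)) NULL else tryCatch(
        suppressWarnings(mclust::meVVV(data = x, z = z)),
        error = function(e) NULL)
    })
    if (is.null(fit) || is.na(fit$loglik)) next
    # reject degenerate fits: a component carrying fewer points than
    # dimensions cannot support a full covariance
    if (min(colSums(fit$z)) < ncol(x) + 1) next
    df <- mclust::nMclustParams("VVV", d = ncol(x), G = k)
    aic <- -2 * fit$loglik + 2 * df
    if (aic < best_aic) {
      best <- fit; best$aic <- aic
      best$bic <- -2 * fit$loglik + log(nrow(x)) * df
      best_aic <- aic
    }
  }
  best
}

mclust_map <- function(fit) apply(fit$z, 1, which.max)

#' PCA + Gaussian-mixture model selection
#'
#' Projects complete rows of the standardized feature matrix onto the first
#' `n_pc` principal components and, for each candidate number of components,
#' fits a full-covariance GMM taking the best of `n_seeds` random EM
#' initializations by AIC. Model-selection diagnostics are AIC, BIC and a
#' held-out mean negative log-likelihood from repeated half/half
#' train/test splits.
#'
#' @param fmatrix Matrix from [build_feature_matrix()].
#' @param k_range Candidate component counts (default 1:7).
#' @param n_seeds Random EM starts per k (default 20).
#' @param n_splits Cross-validation splits (default 50).
#' @param n_pc Number of principal components (default 3).
#' @param seed Integer seed.
#' @return Object of class `pca_gmm`: list with `pca`, `scores`, `fits`
#'   (per k), `selection` tibble (`k`, `aic`, `bic`, `cv_nll`), `best_k`
#'   (argmin BIC), `complete`, `unit_id`.
#' @export
fit_pca_gmm <- function(fmatrix, k_range = 1:7, n_seeds = 20, n_splits = 50,
                        n_pc = 3, seed = 1) {
  complete <- attr(fmatrix, "complete")
  x <- fmatrix[complete, , drop = FALSE]
  if (nrow(x) < 10L) abort("need at least 10 complete rows")
  pca <- prcomp(x, center = FALSE, scale. = FALSE)
  scores <- pca$x[, seq_len(n_pc), drop = FALSE]
  fits <- list(); sel <- list()
  for (k in k_range) {
    fit <- best_gmm(scores, k, n_seeds = n_seeds, seed = child_seed(seed, k))
    if (is.null(fit)) next
    cv <- cv_nll_gmm(scores, k, n_splits = n_splits,
                     seed = child_seed(seed, 1000 + k))
    fits[[as.character(k)]] <- fit
    sel[[length(sel) + 1L]] <- tibble::tibble(
      k = k, aic = fit$aic, bic = fit$bic, cv_nll = cv)
  }
  selection <- dplyr::bind_rows(sel)
  structure(
    list(pca = pca, scores = scores, fits = fits, selection = selection,
         best_k = selection$k[which.min(selection$bic)],
         complete = complete, unit_id = attr(fmatrix, "unit_id")),
    class = "pca_gmm")
}

# Mean held-out negative log-likelihood per observation over repeated
# half/half splits (fewer EM restarts per split keep this affordable).
cv_nll_gmm <- function(scores, k, n_splits, seed) {
  n <- nrow(scores)
  vals <- vapply(seq_len(n_splits), function(s) {
    with_seed(child_seed(seed, s), {
      idx <- sample.int(n, floor(n / 2))
      fit <- best_gmm(scores[idx, , drop = FALSE], k, n_seeds = 3,
                      seed = child_seed(seed, 500 + s))
      if (is.null(fit)) return(NA_real_)
      test <- scores[-idx, , drop = FALSE]
      ll <- tryCatch({
        cd <- suppressWarnings(mclust::cdensVVV(
          data = test, logarithm = TRUE, parameters = fit$parameters))
        cd <- sweep(as.matrix(cd), 2, log(fit$parameters$pro), "+")
        mx <- apply(cd, 1, max)
        mx + log(rowSums(exp(cd - mx)))
      }, error = function(e) NA_real_)
      -mean(ll)
    })
  }, 0)
  mean(vals, na.rm = TRUE)
}

#' Map GMM components to unit types and assign labels
#'
#' Components of the 3-component model are mapped to types by their feature
#' centroids in the original standardized feature space: the component with
#' the highest mean autocorrelogram metric is Bu; of the remaining two, the
#' one with the higher mean spontaneous rate is FS, the other RS. A unit is
#' assigned to its maximum-posterior component only when that posterior is at
#' least twice each other component's posterior; otherwise it stays
#' unclassified.
#'
#' @param fit A `pca_gmm` object with a 3-component fit.
#' @param fmatrix The matrix from [build_feature_matrix()] used for the fit.
#' @return Tibble: `unit_id`, `label` (RS/FS/Bu/unclassified; `NA` for rows
#'   not projected), `posterior_rs`, `posterior_fs`, `posterior_bu`,
#'   `method = "gmm"`.
#' @export
assign_types_gmm <- function(fit, fmatrix) {
  g <- fit$fits[["3"]]
  if (is.null(g)) abort("no converged 3-component fit")
  z <- g$z
  comp <- mclust_map(g)
  complete <- fit$complete
  x <- fmatrix[complete, , drop = FALSE]
  centroids <- vapply(1:3, function(c3) colMeans(x[comp == c3, , drop = FALSE]),
                      numeric(ncol(x)))
  acm_row <- match("acm", gmm_feature_names)
  spont_row <- match("spontaneous_rate", gmm_feature_names)
  bu <- which.max(centroids[acm_row, ])
  rest <- setdiff(1:3, bu)
  fs <- rest[which.max(centroids[spont_row, rest])]
  rs <- setdiff(rest, fs)
  if (anyDuplicated(c(bu, fs, rs))) abort("unmappable component centroids")
  type_of <- character(3)
  type_of[c(bu, fs, rs)] <- c("Bu", "FS", "RS")
  lab <- vapply(seq_len(nrow(z)), function(i) {
    ord <- order(z[i, ], decreasing = TRUE)
    if (z[i, ord[1]] >= 2 * z[i, ord[2]]) type_of[ord[1]] else "unclassified"
  }, "")
  out <- tibble::tibble(
    unit_id = attr(fmatrix, "unit_id"),
    label = NA_character_,
    posterior_rs = NA_real_, posterior_fs = NA_real_, posterior_bu = NA_real_,
    method = "gmm")
  out$label[complete] <- lab
  out$posterior_rs[complete] <- z[, rs]
  out$posterior_fs[complete] <- z[, fs]
  out$posterior_bu[complete] <- z[, bu]
  out
}

#' Agreement between two label assignments
#'
#' Computed over units labeled by BOTH methods (neither unclassified, missing
#' nor ambiguous). Bu1/Bu2 sublabels are collapsed to Bu for comparison with
#' the 3-class GMM labels.
#'
#' @param labels_a,labels_b Tibbles with `unit_id` and `label`.
#' @return List with `table` (confusion matrix a x b) and `agreement`
#'   (fraction of the diagonal).
#' @export
agreement_matrix <- function(labels_a, labels_b) {
  collapse <- function(x) ifelse(x %in% c("Bu1", "Bu2"), "Bu", x)
  a <- labels_a; b <- labels_b
  a$lab <- collapse(a$label); b$lab <- collapse(b$label)
  keep_lab <- c("RS", "FS", "Bu")
  m <- dplyr::inner_join(a[, c("unit_id", "lab")], b[, c("unit_id", "lab")],
                         by = "unit_id", suffix = c("_a", "_b"))
  if (nrow(m) == 0L) abort("label sets share no units")
  m <- m[m$lab_a %in% keep_lab & m$lab_b %in% keep_lab, ]
  if (nrow(m) == 0L) abort("no units labeled by both methods")
  tab <- table(factor(m$lab_a, keep_lab), factor(m$lab_b, keep_lab))
  list(table = tab, agreement = sum(diag(tab)) / sum(tab))
}
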