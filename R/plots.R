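#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_tile labs scale_x_log10 theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a smoothed PSTH
#' @param object A `psth`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psth <- function(object, ...) {
  ggplot(object, aes(x = .data$t, y = .data$rate)) +
    geom_line(color = "steelblue") +
    labs(x = "time from stimulus onset (s)", y = "rate (spk/s)") +
    theme_minimal()
}

#' Plot a vector-strength profile across modulation rates
#' @param object A `vs_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vs_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$mod_rate_hz, y = .data$vs_reported)) +
    geom_line() + geom_point(aes(shape = .data$significant)) +
    scale_x_log10() +
    labs(x = "modulation rate (Hz)", y = "vector strength (reported)") +
    theme_minimal()
}

#' Plot a correlation-index curve against coincidence window
#' @param object A `sac_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sac_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$window_s * 1000, y = .data$ci)) +
    geom_line() + geom_point() + scale_x_log10() +
    labs(x = "coincidence window (ms)", y = "correlation index") +
    theme_minimal()
}

#' Heatmap of a decoding confusion matrix
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("true", "decoded", "n")
  ggplot(df, aes(x = .data$decoded, y = .data$true, fill = .data$n)) +
    geom_tile() +
    labs(x = "decoded stimulus", y = "true stimulus", fill = "tally") +
    theme_minimal()
}

#' Model-selection curves of a PCA+GMM fit
#' @param object A `pca_gmm`.
#' @param ... Unused.
#' @return A ggplot of AIC/BIC versus number of components.
#' @export
autoplot.pca_gmm <- function(object, ...) {
  df <- tidyr::pivot_longer(object$selection, c("aic", "bic"),
                            names_to = "criterion", values_to = "value")
  ggplot(df, aes(x = .data$k, y = .data$value,
                 color = .data$criterion)) +
    geom_line() + geom_point() +
    labs(x = "number of mixture components", y = "information criterion") +
    theme_minimal()
}

#' Tidy the per-k model-selection table of a PCA+GMM fit
#' @param x A `pca_gmm`.
#' @param ... Unused.
#' @return Tibble with `k`, `aic`, `bic`, `cv_nll`.
#' @export
tidy.pca_gmm <- function(x, ...) x$selection

#' One-row summary of a PCA+GMM fit
#' @param x A `pca_gmm`.
#' @param ... Unused.
#' @return Tibble with `best_k`, `n_complete`, `pc_var_3` (variance fraction
#'   captured by the first 3 components).
#' @export
glance.pca_gmm <- function(x, ...) {
  v <- x$pca$sdev^2
  tibble::tibble(best_k = x$best_k, n_complete = sum(x$complete),
                 pc_var_3 = sum(v[1:3]) / sum(v))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
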