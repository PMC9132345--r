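#' Interspike-interval histogram
#'
#' Linear histograms use 0.2 ms bins on the ISI in milliseconds; log
#' histograms use 0.1-wide bins on the *natural* log of the ISI in
#' milliseconds (so a Poisson unit at 50 spk/s peaks near ln(20) = 3, and one
#' at 1 spk/s near ln(1000) = 6.9).
#'
#' @param intervals Numeric vector of ISIs in seconds (all > 0).
#' @param scale `"linear"` or `"log"`.
#' @return An object of class `isi_histogram`: a list with `breaks` (bin
#'   edges), `centers`, `counts` (bins are half-open `[left, right)`), `scale`
#'   and `n_intervals`. Units are ms (linear) or ln(ms) (log).
#' @export
isi_histogram <- function(intervals, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (any(intervals <= 0)) abort("intervals must be > 0")
  if (scale == "linear") {
    v <- intervals * 1000
    top <- if (length(v)) max(v) else 1
    breaks <- seq(0, (floor(top / 0.2) + 1) * 0.2, by = 0.2)
  } else {
    v <- log(intervals * 1000)
    lo <- min(-2, if (length(v)) floor(min(v) * 10) / 10 else 0)
    hi <- max(7.5, if (length(v)) ceiling(max(v) * 10) / 10 + 0.1 else 0)
    breaks <- seq(lo, hi, by = 0.1)
  }
  counts <- if (length(v)) {
    tabulate(findInterval(v, breaks, rightmost.closed = FALSE),
             nbins = length(breaks) - 1L)
  } else {
    integer(length(breaks) - 1L)
  }
  structure(
    list(breaks = breaks, centers = (head(breaks, -1) + tail(breaks, -1)) / 2,
         counts = counts, scale = scale, n_intervals = length(v)),
    class = "isi_histogram")
}

require_intervals <- function(h, n = 50L) {
  if (h$n_intervals < n) {
    abort(sprintf("insufficient data: %d ISI intervals, need >= %d",
                  h$n_intervals, n))
  }
}

#' ISI peak from the log-ISI histogram
#'
#' The peak is located on the log-ISI histogram truncated below 80 ms, which
#' avoids the spurious long-interval peak created by the log transform and by
#' the trial repetition period. Ties break toward the shorter interval.
#'
#' @param h An `isi_histogram` on the log scale (>= 50 intervals required).
#' @return Peak location in milliseconds.
#' @export
isi_peak <- function(h) {
  stopifnot(inherits(h, "isi_histogram"), h$scale == "log")
  require_intervals(h)
  keep <- h$centers < log(80)
  exp(h$centers[keep][which.max(h$counts[keep])])
}

#' Refractory period from the linear ISI histogram
#'
#' The left edge of the smallest ISI bin whose count exceeds 1/200 of the
#' histogram's peak height. For sparse low-rate units the histogram is noisy
#' at short intervals and a suspiciously large value can result.
#'
#' @param h An `isi_histogram` on the linear scale.
#' @return Refractory period in seconds, or `NA` if no bin qualifies.
#' @export
refractory_period <- function(h) {
  stopifnot(inherits(h, "isi_histogram"), h$scale == "linear")
  if (h$n_intervals == 0L) abort("empty histogram")
  idx <- which(h$counts > max(h$counts) / 200)
  if (!length(idx)) return(NA_real_)
  h$breaks[idx[1]] / 1000
}

#' Burst score from the drop-off of the smoothed log-ISI histogram
#'
#' Smooths the full log-ISI histogram with a Savitzky-Golay filter (span 5,
#' degree 3), takes the maximum of the smoothed counts over bins centered in
#' 1-5 ms, and contrasts it with the mean over the 5 bins spanning 10-16 ms:
#' `(max - mean) / (max + mean)`. Near +1 for units with a dominant
#' short-interval (burst) peak, negative when short intervals are rare. The
#' score normally lies in [-1, 1]; smoothing can push it slightly outside.
#'
#' @param intervals ISIs in seconds (>= 50 required).
#' @return Dimensionless score.
#' @export
log_isi_drop <- function(intervals) {
  h <- isi_histogram(intervals, "log")
  require_intervals(h)
  y <- signal::sgolayfilt(h$counts, p = 3, n = 5)
  peak_region <- h$centers >= log(1) & h$centers <= log(5)
  ref_region <- h$centers >= log(10) & h$centers <= log(16)
  mx <- max(y[peak_region])
  mn <- mean(y[ref_region])
  if (mx + mn == 0) return(NA_real_)
  (mx - mn) / (mx + mn)
}

#' Spike-train autocorrelogram
#'
#' Tallies positive lags between ordered spike pairs at 0.2 ms resolution,
#' excluding lag-0 self pairs, counting only pairs within the same contiguous
#' segment (never across trial boundaries).
#'
#' @param trains List of sorted spike-time vectors (seconds), one per segment.
#' @param lag_max Maximum lag in seconds (default 0.08).
#' @return Object of class `autocorrelogram`: list with `breaks`, `centers`
#'   (ms) and `counts`.
#' @export
autocorrelogram <- function(trains, lag_max = 0.08) {
  if (is.numeric(trains)) trains <- list(trains)
  lags <- unlist(lapply(trains, function(tt) {
    n <- length(tt)
    if (n < 2L) return(numeric(0))
    unlist(lapply(seq_len(n - 1L), function(i) {
      d <- tt[(i + 1L):n] - tt[i]
      d[d <= lag_max]
    }))
  }), use.names = FALSE)
  breaks <- seq(0, lag_max * 1000, by = 0.2)
  counts <- tabulate(findInterval(lags * 1000, breaks,
                                  rightmost.closed = FALSE),
                     nbins = length(breaks) - 1L)
  structure(
    list(breaks = breaks, centers = (head(breaks, -1) + tail(breaks, -1)) / 2,
         counts = counts),
    class = "autocorrelogram")
}

#' Autocorrelogram short-lag contrast metric
#'
#' `(R(0,8) - R(35,80)) / (R(0,8) + R(35,80))` where `R(a,b)` is the mean
#' autocorrelogram count over lag bins in `[a, b)` ms. Near +1 when short-lag
#' (burst) structure dominates, 0 for a flat autocorrelogram. The 35-80 ms
#' reference band sits above any gamma-band peak.
#'
#' @param ac An [autocorrelogram()].
#' @return Dimensionless value in `[-1, 1]`, or `NA` when both band means
#'   are zero.
#' @export
autocorrelogram_metric <- function(ac) {
  stopifnot(inherits(ac, "autocorrelogram"))
  short <- mean(ac$counts[ac$centers >= 0 & ac$centers < 8])
  long <- mean(ac$counts[ac$centers >= 35 & ac$centers < 80])
  if (short + long == 0) return(NA_real_)
  (short - long) / (short + long)
}

#' Intraburst frequency
#'
#' Inverse of the linear (non-log) ISI histogram peak at 0.2 ms resolution;
#' 1.3 ms bins give 769 Hz, and 500 Hz (2 ms) is the Bu1/Bu2 boundary.
#'
#' @param h An `isi_histogram` on the linear scale (>= 50 intervals).
#' @return Frequency in Hz.
#' @export
intraburst_frequency <- function(h) {
  stopifnot(inherits(h, "isi_histogram"), h$scale == "linear")
  require_intervals(h)
  peak_ms <- h$centers[which.max(h$counts)]
  1000 / peak_ms
}

#' Burst-run and regularity statistics
#'
#' A burst is a maximal run of consecutive ISIs falling between 0.5 and 1.5
#' times the ISI peak; a run of one ISI is a 2-spike burst. Runs never cross
#' segment boundaries. `pct_isi_lt_5ms` is the percentage of ISIs under 5 ms,
#' and `pct_normalized` divides it by the percentage expected from a Poisson
#' process with the same mean rate (estimated as 1/mean(ISI)), so Poisson-like
#' units score near 1. `regularity` is the variance of the ratio
#' `ISI_n / (ISI_n + ISI_{n+1})` over consecutive interval pairs (0 for a
#' perfectly periodic train).
#'
#' @param intervals ISIs in seconds: a numeric vector (one segment) or a list
#'   of per-segment vectors.
#' @param isi_peak_ms ISI peak in milliseconds (see [isi_peak()]).
#' @return Tibble with `mean_burst_len`, `max_burst_len` (spikes),
#'   `pct_isi_lt_5ms`, `pct_normalized`, `regularity`.
#' @export
burst_stats <- function(intervals, isi_peak_ms) {
  segs <- if (is.list(intervals)) intervals else list(intervals)
  all_isi <- unlist(segs, use.names = FALSE)
  if (length(all_isi) < 2L) abort("need at least 2 intervals")
  band <- c(0.5, 1.5) * isi_peak_ms / 1000
  run_lengths <- unlist(lapply(segs, function(v) {
    inb <- v >= band[1] & v <= band[2]
    r <- rle(inb)
    r$lengths[r$values]
  }), use.names = FALSE)
  burst_spikes <- if (length(run_lengths)) run_lengths + 1L else 1L
  pct <- 100 * mean(all_isi < 0.005)
  r <- 1 / mean(all_isi)
  expected <- 100 * (1 - exp(-r * 0.005))
  ratios <- unlist(lapply(segs, function(v) {
    if (length(v) < 2L) return(numeric(0))
    v[-length(v)] / (v[-length(v)] + v[-1])
  }), use.names = FALSE)
  tibble::tibble(
    mean_burst_len = mean(burst_spikes),
    max_burst_len = max(burst_spikes),
    pct_isi_lt_5ms = pct,
    pct_normalized = pct / expected,
    regularity = if (length(ratios) >= 2L) var(ratios) else 0)
}

#' Hartigans' dip test of unimodality
#'
#' Computes the dip statistic (half the sup-norm distance from the empirical
#' cdf to the nearest unimodal cdf) and a p-value from a seeded bootstrap of
#' uniform null samples of the same size, the conventional conservative null.
#'
#' @param values Numeric vector (>= 10 values).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return Tibble with columns `dip` and `p_value`.
#' @export
dip_test <- function(values, n_boot = 2000, seed = 1) {
  values <- values[is.finite(values)]
  if (length(values) < 10L) abort("dip test needs at least 10 values")
  d <- dip_stat_cpp(values)
  null <- with_seed(seed, vapply(
    seq_len(n_boot),
    function(i) dip_stat_cpp(runif(length(values))), 0))
  tibble::tibble(dip = d, p_value = (1 + sum(null >= d)) / (1 + n_boot))
}
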