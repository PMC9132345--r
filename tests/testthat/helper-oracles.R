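# Independent oracles, deliberately naive.

# Victor-Purpura cost by exhaustive recursion over all monotone matchings:
# either delete the first spike of `a`, or match it to some spike j of `b`
# (deleting the b-spikes that precede j). Cost grows with the number of
# matchings, so keep trains at <= 8 spikes.
bf_vp <- function(a, b, q) {
  if (length(a) == 0L) return(length(b))
  if (length(b) == 0L) return(length(a))
  best <- 1 + bf_vp(a[-1], b, q)
  for (j in seq_along(b)) {
    cost <- q * abs(a[1] - b[j]) + (j - 1) +
      bf_vp(a[-1], if (j < length(b)) b[(j + 1):length(b)] else numeric(0), q)
    if (cost < best) best <- cost
  }
  best
}

# All positive-lag spike pairs of a single segment, counted pair by pair.
bf_autocorr_counts <- function(times, breaks_ms, lag_max) {
  lags <- c()
  for (i in seq_along(times)) {
    for (j in seq_along(times)) {
      d <- times[j] - times[i]
      if (j != i && d > 0 && d <= lag_max) lags <- c(lags, d * 1000)
    }
  }
  tabulate(findInterval(lags, breaks_ms, rightmost.closed = FALSE),
           nbins = length(breaks_ms) - 1L)
}

# Ordered cross-trial coincidences, quadratic in spikes.
bf_coincidences <- function(trains, w) {
  total <- 0
  m <- length(trains)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    for (a in trains[[i]]) total <- total + sum(abs(trains[[j]] - a) <= w / 2)
  }
  total
}

# Ordered cross-trial differences within +/- lag_max.
bf_cross_diffs <- function(trains, lag_max) {
  out <- c()
  m <- length(trains)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    for (a in trains[[i]]) {
      d <- trains[[j]] - a
      out <- c(out, d[abs(d) <= lag_max])
    }
  }
  out
}
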