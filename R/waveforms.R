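#' Zero-phase broadband filtering of waveform snippets
#'
#' Applies a 256th-order FIR bandpass (default 1 Hz - 10 kHz, truncated at
#' Nyquist) forward and in reverse so the net group delay is zero: an impulse
#' comes back as a symmetric response centered on the original sample.
#'
#' @param snippets Samples x spikes matrix.
#' @param sample_rate_hz Sampling rate.
#' @param band Length-2 passband in Hz.
#' @param order FIR order (default 256).
#' @return Filtered matrix of the same dimensions.
#' @export
zero_phase_filter <- function(snippets, sample_rate_hz,
                              band = c(1, 10000), order = 256) {
  snippets <- as.matrix(snippets)
  if (nrow(snippets) <= order) {
    abort(sprintf("snippet length %d does not cover the %d-sample filter warm-up",
                  nrow(snippets), order))
  }
  nyq <- sample_rate_hz / 2
  band[2] <- min(band[2], nyq * 0.99)
  h <- signal::fir1(order, band / nyq, type = "pass")
  n <- nrow(snippets)
  apply(snippets, 2, function(x) {
    # reflect-pad, filter forward then in reverse (the one-sided convolution
    # delays cancel exactly), unpad: zero net phase
    pad <- c(rev(x[seq_len(order)]), x, rev(x[(n - order + 1):n]))
    f1 <- stats::filter(pad, h, method = "convolution", sides = 1)
    f1[is.na(f1)] <- 0
    f2 <- rev(stats::filter(rev(as.numeric(f1)), h,
                            method = "convolution", sides = 1))
    f2[is.na(f2)] <- 0
    as.numeric(f2)[(order + 1):(order + n)]
  })
}

#' Select spikes that occur in isolation
#'
#' For averaging, a spike qualifies if no other spike falls from 5 ms before
#' to 6 ms after it; for spectral analysis the pre-window extends to 10 ms so
#' a baseline segment fits. `purpose = "illustrate"` allows closely *following*
#' spikes (only the pre-window is enforced), the convention used to display
#' burst "spikelets" in averages.
#'
#' @param times Sorted spike times in seconds.
#' @param purpose `"average"`, `"spectrum"` or `"illustrate"`.
#' @return Integer indices of isolated spikes.
#' @export
select_isolated_spikes <- function(times,
                                   purpose = c("average", "spectrum",
                                               "illustrate")) {
  purpose <- match.arg(purpose)
  pre <- if (purpose == "average") 0.005 else 0.010
  post <- 0.006
  n <- length(times)
  if (n == 0L) return(integer(0))
  gap_before <- c(Inf, diff(times))
  gap_after <- c(diff(times), Inf)
  ok <- gap_before > pre
  if (purpose != "illustrate") ok <- ok & gap_after > post
  which(ok)
}

#' Align snippets on the largest voltage change and average them
#'
#' Each snippet is shifted so that the sample of maximum absolute first
#' difference (up or down sweep, whichever is larger; ties to the earliest
#' sample) lands on a common index, then the mean across snippets is taken.
#' Idempotent on already-aligned snippets.
#'
#' @param snippets Samples x spikes matrix (>= 5 snippets).
#' @param sample_rate_hz Sampling rate.
#' @return Object of class `average_waveform`: list with `samples` (numeric),
#'   `sample_rate_hz`, `n_spikes`, `align_index`.
#' @export
align_and_average <- function(snippets, sample_rate_hz) {
  snippets <- as.matrix(snippets)
  if (ncol(snippets) < 5L) {
    abort(sprintf("insufficient data: %d snippets, need >= 5", ncol(snippets)))
  }
  marks <- apply(snippets, 2, function(x) which.max(abs(diff(x))))
  target <- round(stats::median(marks))
  aligned <- vapply(seq_len(ncol(snippets)), function(j) {
    shift <- target - marks[j]
    x <- snippets[, j]
    if (shift > 0) c(rep(x[1], shift), head(x, -shift))
    else if (shift < 0) c(tail(x, shift), rep(x[length(x)], -shift))
    else x
  }, numeric(nrow(snippets)))
  structure(
    list(samples = rowMeans(aligned), sample_rate_hz = sample_rate_hz,
         n_spikes = ncol(snippets), align_index = target),
    class = "average_waveform")
}

#' Trough-to-peak and half-amplitude width of an average waveform
#'
#' `t_ttp` is the time from the largest downward peak to the next upward peak.
#' `half_amp_dur` is the width of the trough at 50% of its depth relative to
#' the pre-spike baseline (the mean over a 1 ms window ending 0.5 ms before
#' the trough), measured on a cubic-spline interpolation at 10x resolution.
#'
#' @param w An `average_waveform`.
#' @return Tibble with `t_ttp_s` and `half_amp_s` (`NA` if no post-trough
#'   peak exists within the snippet).
#' @export
width_metrics <- function(w) {
  x <- w$samples
  fs <- w$sample_rate_hz
  trough <- which.min(x)
  post <- x[trough:length(x)]
  if (length(post) < 3L) {
    return(tibble::tibble(t_ttp_s = NA_real_, half_amp_s = NA_real_))
  }
  peak_rel <- which.max(post)
  if (peak_rel == length(post)) {
    return(tibble::tibble(t_ttp_s = NA_real_, half_amp_s = NA_real_))
  }
  t_ttp <- (peak_rel - 1) / fs
  # 10x cubic-spline interpolation for the half-amplitude width
  n <- length(x)
  fine <- stats::spline(seq_len(n), x, n = (n - 1) * 10 + 1)
  base_lo <- trough - round(0.0015 * fs)
  base_hi <- trough - round(0.0005 * fs)
  baseline <- if (base_lo >= 1) mean(x[base_lo:base_hi]) else 0
  half <- baseline + (min(x) - baseline) / 2
  below <- fine$y < half
  tr_fine <- which.min(fine$y)
  left <- which(!below[seq_len(tr_fine)])
  right <- which(!below[tr_fine:length(below)])
  if (!length(left) || !length(right)) {
    half_amp <- NA_real_
  } else {
    i0 <- max(left); i1 <- tr_fine + min(right) - 1L
    half_amp <- (fine$x[i1] - fine$x[i0]) / fs
  }
  tibble::tibble(t_ttp_s = t_ttp, half_amp_s = half_amp)
}

amplitude_spectrum <- function(seg, fs, nfft = 1024) {
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(seg)))  # Hann
  seg <- (seg - mean(seg)) * w
  pad <- c(seg, rep(0, nfft - length(seg)))
  amp <- Mod(fft(pad))[seq_len(nfft / 2)]
  tibble::tibble(freq_hz = (seq_len(nfft / 2) - 1) * fs / nfft, amp = amp)
}

#' Spectral width of the average spike (f50)
#'
#' Subtracts the amplitude spectrum of a pre-spike baseline segment from that
#' of an equal-length segment spanning the spike, finds the spectral peak
#' above 400 Hz, and returns the high-side frequency where the spectrum rolls
#' off to 50% of that peak (linear interpolation between bins). Narrow spikes
#' give high f50; 2 kHz is the conventional narrow/broad boundary.
#'
#' @param w An `average_waveform` (trough must sit late enough that a 5 ms
#'   baseline and 5 ms spike segment fit).
#' @param segment_s Segment length in seconds (default 0.005).
#' @return f50 in Hz, or `NA` when no 50% crossing exists above the peak.
#' @export
spectral_f50 <- function(w, segment_s = 0.005) {
  x <- w$samples
  fs <- w$sample_rate_hz
  if (max(x) == min(x)) return(NA_real_)  # flat: spike equals baseline
  nseg <- round(segment_s * fs)
  trough <- which.min(x)
  sp0 <- trough - round(0.001 * fs)
  if (sp0 < nseg + 1 || sp0 + nseg - 1 > length(x)) {
    abort("waveform too short for the spike and baseline spectral segments")
  }
  spike_seg <- x[sp0:(sp0 + nseg - 1)]
  base_seg <- x[(sp0 - nseg):(sp0 - 1)]
  sp <- amplitude_spectrum(spike_seg, fs)
  ba <- amplitude_spectrum(base_seg, fs)
  diff_amp <- sp$amp - ba$amp
  above <- which(sp$freq_hz >= 400)
  pk_rel <- which.max(diff_amp[above])
  pk <- above[pk_rel]
  target <- diff_amp[pk] / 2
  if (diff_amp[pk] <= 0) return(NA_real_)
  j <- pk
  while (j < length(diff_amp) && diff_amp[j] > target) j <- j + 1L
  if (diff_amp[j] > target) return(NA_real_)  # never crossed: undefined
  # linear interpolation between bins j-1 and j
  f0 <- sp$freq_hz[j - 1]; f1 <- sp$freq_hz[j]
  y0 <- diff_amp[j - 1]; y1 <- diff_amp[j]
  f0 + (y0 - target) / (y0 - y1) * (f1 - f0)
}
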