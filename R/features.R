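#' Per-unit feature table for unit-type classification
#'
#' Computes, for every unit in the session, the spike-timing and waveform
#' features consumed by the criteria and GMM classifiers. Spike-timing
#' features use the standardized tuning protocol (entire trials, stimulated
#' and unstimulated periods, intervals never crossing trial boundaries);
#' prestimulus features pool the 200 ms prestimulus segments across all
#' protocols. Features that cannot be computed (too few intervals, too few
#' snippets) are `NA`.
#'
#' @param session A [spike_session()].
#' @param protocol Protocol used for the spike-timing features (default
#'   `"tuning"`).
#' @param min_intervals Minimum ISI count for histogram-based features
#'   (default 50).
#' @return Tibble with one row per unit: `unit_id`, `acm`, `isi_peak_ms`,
#'   `log_isi_drop`, `pct_isi_lt_5ms`, `pct_normalized`, `spontaneous_rate`,
#'   `f50_hz`, `mean_burst_len`, `max_burst_len`, `max_firing_rate`,
#'   `regularity`, `t_ttp_ms`, `half_amp_ms`, `prestim_log_isi_drop`,
#'   `intraburst_freq_hz`, `refractory_ms`, `latency_ms`, `truth_type`.
#' @export
unit_features <- function(session, protocol = "tuning", min_intervals = 50) {
  purrr::map_dfr(session$units$unit_id, function(u) {
    tr <- unit_trains(session, u, protocol = protocol)
    segs <- lapply(tr$times, function(tt) diff(sort(tt)))
    isis <- unlist(segs, use.names = FALSE)
    have <- length(isis) >= min_intervals
    hlin <- if (length(isis)) isi_histogram(isis, "linear") else NULL
    hlog <- if (length(isis)) isi_histogram(isis, "log") else NULL
    peak_ms <- if (have) isi_peak(hlog) else NA_real_
    drop <- if (have) log_isi_drop(isis) else NA_real_
    ibf <- if (have) intraburst_frequency(hlin) else NA_real_
    refr <- if (have) refractory_period(hlin) * 1000 else NA_real_
    ac <- autocorrelogram(tr$times)
    acm <- if (sum(ac$counts) > 0) autocorrelogram_metric(ac) else NA_real_
    bs <- if (have) burst_stats(segs, peak_ms) else NULL
    pre_isis <- pool_prestim_intervals(session, u)
    pre_drop <- if (length(pre_isis) >= min_intervals) {
      log_isi_drop(pre_isis)
    } else {
      NA_real_
    }
    spont <- mean(prestim_rates(session, u))
    mfr <- max_driven_rate(session, u)
    wfb <- session$waveforms[[u]]
    if (!is.null(wfb) && ncol(wfb$snippets) >= 5L) {
      filt <- zero_phase_filter(wfb$snippets, wfb$sample_rate_hz)
      avg <- align_and_average(filt, wfb$sample_rate_hz)
      wm <- width_metrics(avg)
      f50 <- tryCatch(spectral_f50(avg), error = function(e) NA_real_)
      ttp_ms <- wm$t_ttp_s * 1000
      half_ms <- wm$half_amp_s * 1000
    } else {
      f50 <- NA_real_; ttp_ms <- NA_real_; half_ms <- NA_real_
    }
    lat <- tryCatch(onset_latency(session, u, protocol) * 1000,
                    error = function(e) NA_real_)
    tibble::tibble(
      unit_id = u, acm = acm, isi_peak_ms = peak_ms, log_isi_drop = drop,
      pct_isi_lt_5ms = bs$pct_isi_lt_5ms %||% NA_real_,
      pct_normalized = bs$pct_normalized %||% NA_real_,
      spontaneous_rate = spont, f50_hz = f50,
      mean_burst_len = bs$mean_burst_len %||% NA_real_,
      max_burst_len = bs$max_burst_len %||% NA_real_,
      max_firing_rate = mfr, regularity = bs$regularity %||% NA_real_,
      t_ttp_ms = ttp_ms, half_amp_ms = half_ms,
      prestim_log_isi_drop = pre_drop, intraburst_freq_hz = ibf,
      refractory_ms = refr,
      latency_ms = if (length(lat)) lat else NA_real_,
      truth_type = session$units$truth_type[
        match(u, session$units$unit_id)])
  })
}

# Max over stimuli of the mean driven rate in the response window.
max_driven_rate <- function(session, unit_id) {
  st <- session$stimuli
  rates <- vapply(seq_len(nrow(st)), function(i) {
    win <- response_window(st[i, ])
    tr <- unit_trains(session, unit_id, protocol = st$protocol[i],
                      stimulus_id = st$stimulus_id[i])
    if (nrow(tr) == 0L) return(0)
    mean(vapply(tr$times, function(tt) sum(in_window(tt, win[1], win[2])),
                0)) / diff(win)
  }, 0)
  if (length(rates)) max(rates) else NA_real_
}
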