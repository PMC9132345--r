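#' Smoothed peristimulus time histogram
#'
#' Spikes are tallied in 1 ms bins across repetitions, converted to spk/s, and
#' convolved with a Gaussian kernel (sigma = 5 ms). At the window edges the
#' truncated kernel is renormalized so smoothing conserves the integrated
#' count.
#'
#' @param trains List of spike-time vectors (seconds), one per repetition.
#' @param window Length-2 numeric, the PSTH window `[t0, t1)`.
#' @param sigma_s Gaussian smoothing SD in seconds (default 0.005).
#' @return Object of class `psth`: tibble with `t` (bin centers), `count`
#'   (summed over reps), `rate` (smoothed spk/s); attributes `n_reps`,
#'   `window`, `bin_s`.
#' @export
smoothed_psth <- function(trains, window, sigma_s = 0.005) {
  if (length(trains) == 0L) abort("need at least one train")
  bin <- 0.001
  breaks <- seq(window[1], window[2], by = bin)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  spikes <- unlist(trains, use.names = FALSE)
  spikes <- spikes[in_window(spikes, window[1], window[2])]
  counts <- tabulate(findInterval(spikes, breaks, rightmost.closed = FALSE),
                     nbins = length(centers))
  n_reps <- length(trains)
  rate <- counts / (n_reps * bin)
  kern <- dnorm(seq(-4 * sigma_s, 4 * sigma_s, by = bin), sd = sigma_s)
  kern <- kern / sum(kern)
  nk <- length(kern)
  padded <- c(rep(0, nk), rate, rep(0, nk))
  sm <- stats::filter(padded, kern, sides = 2)
  sm <- as.numeric(sm)[nk + seq_along(rate)]
  # renormalize at the edges where the kernel is truncated
  ones <- c(rep(0, nk), rep(1, length(rate)), rep(0, nk))
  norm <- as.numeric(stats::filter(ones, kern, sides = 2))[nk + seq_along(rate)]
  sm <- sm / norm
  out <- tibble::tibble(t = centers, count = counts, rate = sm)
  structure(out, class = c("psth", class(out)),
            n_reps = n_reps, window = window, bin_s = bin)
}

#' Response analysis window for a stimulus
#'
#' From 10 ms after stimulus onset to 50 ms after offset; extended to 150 ms
#' after offset for vocalizations.
#'
#' @param stimulus One row of a session's stimulus table.
#' @return Length-2 numeric `[t0, t1)`.
#' @export
response_window <- function(stimulus) {
  post <- if (stimulus$kind == "vocalization") 0.150 else 0.050
  c(stimulus$onset_s + 0.010, stimulus$onset_s + stimulus$duration_s + post)
}

# Per-trial prestimulus rates pooled across all stimuli/repetitions/protocols
# for one unit.
prestim_rates <- function(session, unit_id) {
  pre <- session$units$prestim_s[match(unit_id, session$units$unit_id)]
  tr <- unit_trains(session, unit_id)
  counts <- vapply(tr$times, function(tt) sum(in_window(tt, -pre, 0)), 0)
  counts / pre
}

#' Excitatory responsiveness by mean driven rate
#'
#' The driven rate over the response window must exceed the prestimulus mean
#' plus 3 standard errors. The prestimulus variance is scaled by
#' `T_pre / T_resp` (rate variance scales inversely with window duration) and
#' divided by the number of averaged repetitions. Suppression is not flagged.
#'
#' @param session A [spike_session()].
#' @param unit_id,stimulus_id Unit and stimulus of interest.
#' @param protocol Protocol containing the stimulus.
#' @return Logical.
#' @export
responsive_by_rate <- function(session, unit_id, stimulus_id, protocol) {
  st <- session$stimuli[session$stimuli$stimulus_id == stimulus_id &
                          session$stimuli$protocol == protocol, ]
  if (nrow(st) != 1L) abort("stimulus not found")
  pre_rates <- prestim_rates(session, unit_id)
  if (!length(pre_rates)) abort("no prestimulus data")
  win <- response_window(st)
  t_resp <- diff(win)
  t_pre <- session$units$prestim_s[match(unit_id, session$units$unit_id)]
  tr <- unit_trains(session, unit_id, protocol = protocol,
                    stimulus_id = stimulus_id)
  n_reps <- nrow(tr)
  driven <- mean(vapply(tr$times,
                        function(tt) sum(in_window(tt, win[1], win[2])), 0)) /
    t_resp
  thr <- mean(pre_rates) +
    3 * sqrt(var(pre_rates) * (t_pre / t_resp) / n_reps)
  driven > thr
}

#' Excitatory responsiveness by peak PSTH bin
#'
#' Counts in 5 ms bins are aggregated across repetitions; the spontaneous
#' (prestimulus) bin counts are fit by a Poisson distribution whose tail
#' probability at the maximum response bin, Bonferroni-corrected for the
#' number of response bins, decides significance (p < 0.01 / n_bins). With
#' zero spontaneous spikes the Poisson mean is floored at 0.5 expected counts
#' to avoid degenerate p-values. Catches phase-locked or onset units whose
#' mean rate barely changes.
#'
#' @inheritParams responsive_by_rate
#' @return Logical.
#' @export
responsive_by_psth <- function(session, unit_id, stimulus_id, protocol) {
  st <- session$stimuli[session$stimuli$stimulus_id == stimulus_id &
                          session$stimuli$protocol == protocol, ]
  if (nrow(st) != 1L) abort("stimulus not found")
  pre <- session$units$prestim_s[match(unit_id, session$units$unit_id)]
  bin <- 0.005
  tr_all <- unit_trains(session, unit_id)
  spont_counts <- unlist(lapply(tr_all$times, function(tt) {
    tabulate(findInterval(tt[in_window(tt, -pre, 0)],
                          seq(-pre, 0, by = bin), rightmost.closed = FALSE),
             nbins = round(pre / bin))
  }), use.names = FALSE)
  # aggregate across repetitions: expected counts per bin summed over reps
  tr <- unit_trains(session, unit_id, protocol = protocol,
                    stimulus_id = stimulus_id)
  n_reps <- nrow(tr)
  lambda <- max(mean(spont_counts) * n_reps, 0.5)
  win <- response_window(st)
  breaks <- seq(win[1], win[2], by = bin)
  n_bins <- length(breaks) - 1L
  if (n_bins < 1L) return(FALSE)
  resp <- unlist(tr$times, use.names = FALSE)
  resp <- resp[in_window(resp, win[1], breaks[n_bins + 1L])]
  counts <- tabulate(findInterval(resp, breaks, rightmost.closed = FALSE),
                     nbins = n_bins)
  p <- ppois(max(counts) - 1L, lambda, lower.tail = FALSE)
  p < 0.01 / n_bins
}

#' Adaptation index over a 200 ms response
#'
#' `AI = (r_early - r_late) / (r_early + r_late)` where early is the first
#' 100 ms of the response (offset 10 ms from stimulus onset) and late the last
#' 100 ms; 0 means no adaptation, 1 complete adaptation, negative values
#' facilitation.
#'
#' @param trains List of spike-time vectors, one per repetition.
#' @param duration_s Stimulus duration (must be >= 0.2 s; the standard
#'   stimulus is 200 ms).
#' @return AI in `[-1, 1]`, or `NA` when both rates are zero.
#' @export
adaptation_index <- function(trains, duration_s = 0.2) {
  if (duration_s < 0.2) abort("adaptation index needs a >= 200 ms response")
  early <- c(0.010, 0.110)
  late <- c(duration_s + 0.050 - 0.100, duration_s + 0.050)
  spikes <- unlist(trains, use.names = FALSE)
  r_early <- sum(in_window(spikes, early[1], early[2]))
  r_late <- sum(in_window(spikes, late[1], late[2]))
  if (r_early + r_late == 0) return(NA_real_)
  (r_early - r_late) / (r_early + r_late)
}

#' Vector-strength profile over SAM modulation rates
#'
#' For each SAM stimulus, spike phases `theta = 2 pi f t` are taken over the
#' response window excluding the first 50 ms (a pure onset response is not
#' synchronized). `VS = |sum exp(i theta)| / N`; the Rayleigh statistic is
#' `2 N VS^2`, significant when strictly greater than 13.8 (p < 0.001);
#' nonsignificant VS values are reported as 0 to suppress noise.
#'
#' @param session A [spike_session()].
#' @param unit_id Unit of interest.
#' @param protocol SAM protocol name (default `"sam_series"`).
#' @return Object of class `vs_profile`: tibble with `mod_rate_hz`, `n`,
#'   `vs`, `rayleigh`, `significant`, `vs_reported`.
#' @export
vs_profile <- function(session, unit_id, protocol = "sam_series") {
  st <- session$stimuli[session$stimuli$protocol == protocol, ]
  if (nrow(st) == 0L) abort("no SAM stimuli in this protocol")
  rows <- lapply(seq_len(nrow(st)), function(i) {
    f <- st$mod_rate_hz[i]
    win <- response_window(st[i, ])
    win[1] <- max(win[1], st$onset_s[i] + 0.050)
    tr <- unit_trains(session, unit_id, protocol = protocol,
                      stimulus_id = st$stimulus_id[i])
    spikes <- unlist(tr$times, use.names = FALSE)
    spikes <- spikes[in_window(spikes, win[1], win[2])]
    n <- length(spikes)
    if (n == 0L) {
      return(tibble::tibble(mod_rate_hz = f, n = 0L, vs = NA_real_,
                            rayleigh = NA_real_, significant = FALSE,
                            vs_reported = 0))
    }
    theta <- 2 * pi * f * spikes
    vs <- Mod(sum(exp(1i * theta))) / n
    rayleigh <- 2 * n * vs^2
    sig <- rayleigh > 13.8
    tibble::tibble(mod_rate_hz = f, n = n, vs = vs, rayleigh = rayleigh,
                   significant = sig, vs_reported = if (sig) vs else 0)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$mod_rate_hz)
  structure(out, class = c("vs_profile", class(out)))
}

#' Summary synchrony metrics from a VS profile
#'
#' `f_max` interpolates the Rayleigh statistic (against log2 frequency, the
#' tested rates being octave spaced) between the highest significant rate and
#' the next tested rate, and reports the frequency where it crosses 13.8 (the
#' highest tested rate itself if that rate is significant). `tbmf` is the
#' VS-weighted geometric mean of the peak-VS rate and its significant
#' immediate neighbors (requires >= 2 significant rates). A unit is
#' synchronized (`sync_4`/`sync_16`) if some rate in 4-512 / 16-512 Hz has
#' significant Rayleigh and VS > 0.1; it is `unsynchronized` if no rate
#' qualifies at all but some SAM stimulus drives a significant rate response.
#'
#' @param profile A [vs_profile()].
#' @param rate_responsive Logical: does the unit have a significant rate
#'   response to at least one SAM stimulus? Used only for the
#'   `unsynchronized` label.
#' @return Tibble with `f_max_hz`, `tbmf_hz`, `sync_4`, `sync_16`,
#'   `unsynchronized`, `excluded`.
#' @export
sam_summary <- function(profile, rate_responsive = TRUE) {
  p <- profile[order(profile$mod_rate_hz), ]
  sig <- which(p$significant)
  f_max <- NA_real_
  if (length(sig)) {
    hi <- max(sig)
    if (hi == nrow(p)) {
      f_max <- p$mod_rate_hz[hi]
    } else {
      x0 <- log2(p$mod_rate_hz[hi]); x1 <- log2(p$mod_rate_hz[hi + 1])
      y0 <- p$rayleigh[hi]; y1 <- p$rayleigh[hi + 1]
      if (is.na(y1)) y1 <- 0
      f_max <- 2^(x0 + (y0 - 13.8) / (y0 - y1) * (x1 - x0))
    }
  }
  tbmf <- NA_real_
  if (length(sig) >= 2L) {
    pk <- sig[which.max(p$vs_reported[sig])]
    idx <- pk
    if (pk - 1L >= 1L && p$significant[pk - 1L]) idx <- c(pk - 1L, idx)
    if (pk + 1L <= nrow(p) && p$significant[pk + 1L]) idx <- c(idx, pk + 1L)
    w <- p$vs_reported[idx]
    tbmf <- exp(sum(w * log(p$mod_rate_hz[idx])) / sum(w))
  }
  qual_4 <- any(p$significant & p$vs > 0.1 &
                  p$mod_rate_hz >= 4 & p$mod_rate_hz <= 512, na.rm = TRUE)
  qual_16 <- any(p$significant & p$vs > 0.1 &
                   p$mod_rate_hz >= 16 & p$mod_rate_hz <= 512, na.rm = TRUE)
  none <- !any(p$significant)
  tibble::tibble(
    f_max_hz = f_max, tbmf_hz = tbmf, sync_4 = qual_4, sync_16 = qual_16,
    unsynchronized = none && rate_responsive,
    excluded = none && !rate_responsive)
}

#' Period histogram of spike phases over one modulation cycle
#'
#' @param session A [spike_session()].
#' @param unit_id Unit of interest.
#' @param mod_rate_hz Modulation rate whose SAM stimulus to fold.
#' @param n_bins Number of phase bins (default 32).
#' @param protocol SAM protocol name.
#' @return Tibble with `phase` (bin centers, radians in `[0, 2 pi)`) and
#'   `density` (normalized to unit area over the cycle).
#' @export
period_histogram <- function(session, unit_id, mod_rate_hz, n_bins = 32,
                             protocol = "sam_series") {
  st <- session$stimuli[session$stimuli$protocol == protocol &
                          session$stimuli$mod_rate_hz == mod_rate_hz, ]
  if (nrow(st) != 1L) abort("no unique SAM stimulus at that rate")
  win <- response_window(st)
  win[1] <- max(win[1], st$onset_s + 0.050)
  tr <- unit_trains(session, unit_id, protocol = protocol,
                    stimulus_id = st$stimulus_id)
  spikes <- unlist(tr$times, use.names = FALSE)
  spikes <- spikes[in_window(spikes, win[1], win[2])]
  breaks <- seq(0, 2 * pi, length.out = n_bins + 1L)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  if (!length(spikes)) {
    return(tibble::tibble(phase = centers, density = rep(0, n_bins)))
  }
  phase <- (2 * pi * mod_rate_hz * spikes) %% (2 * pi)
  counts <- tabulate(findInterval(phase, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  tibble::tibble(phase = centers,
                 density = counts / sum(counts) / (2 * pi / n_bins))
}

#' Minimum onset latency across responsive stimuli
#'
#' For each responsive stimulus, the latency is the first time at or after
#' stimulus onset where the smoothed PSTH exceeds the spontaneous mean plus 3
#' spontaneous SDs; the unit's latency is the minimum across stimuli.
#'
#' @param session A [spike_session()].
#' @param unit_id Unit of interest.
#' @param protocol Protocol to scan (default `"tuning"`).
#' @return Latency in seconds, or `NA` if no stimulus is responsive.
#' @export
onset_latency <- function(session, unit_id, protocol = "tuning") {
  st <- session$stimuli[session$stimuli$protocol == protocol, ]
  pre <- session$units$prestim_s[match(unit_id, session$units$unit_id)]
  lats <- vapply(seq_len(nrow(st)), function(i) {
    if (!responsive_by_psth(session, unit_id, st$stimulus_id[i], protocol)) {
      return(NA_real_)
    }
    win <- response_window(st[i, ])
    tr <- unit_trains(session, unit_id, protocol = protocol,
                      stimulus_id = st$stimulus_id[i])
    ps <- smoothed_psth(tr$times, c(-pre, win[2]))
    spont <- ps$rate[ps$t < 0]
    thr <- mean(spont) + 3 * sd(spont)
    idx <- which(ps$t >= 0 & ps$rate > thr)
    if (!length(idx)) NA_real_ else ps$t[idx[1]]
  }, 0)
  if (all(is.na(lats))) NA_real_ else min(lats, na.rm = TRUE)
}

#' Null quantile of the Rayleigh statistic under uniform phases
#'
#' Draws `n_draws` spike trains of `n_spikes` uniform phases and returns the
#' requested quantile of `2 N VS^2`. Asymptotically the statistic is
#' exponential with mean 2, so the 0.999 quantile is `-2 ln(0.001) = 13.8`,
#' the conventional significance cutoff.
#'
#' @param n_spikes Spikes per draw.
#' @param n_draws Monte-Carlo draws.
#' @param p Quantile (default 0.999).
#' @param seed Integer seed.
#' @return The Monte-Carlo quantile of the Rayleigh statistic.
#' @export
rayleigh_null_quantile <- function(n_spikes, n_draws = 1e6, p = 0.999,
                                   seed = 1) {
  with_seed(seed, {
    chunk <- max(1L, floor(2e6 / n_spikes))
    stats <- numeric(n_draws)
    done <- 0L
    while (done < n_draws) {
      m <- min(chunk, n_draws - done)
      th <- matrix(runif(n_spikes * m, 0, 2 * pi), n_spikes, m)
      r2 <- colSums(cos(th))^2 + colSums(sin(th))^2
      stats[done + seq_len(m)] <- 2 * r2 / n_spikes
      done <- done + m
    }
    as.numeric(quantile(stats, p, type = 7))
  })
}
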