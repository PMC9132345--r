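#' Unit phenotype parameter sets
#'
#' Returns the generator parameters for one of the four emulated unit classes.
#' The defaults are chosen so that generated units satisfy the class
#' definitions used by the criteria classifier: regular-spiking (RS) units are
#' broad-spiking, low-spontaneous-rate and stimulus selective; fast-spiking
#' (FS) units are narrow-spiking with high spontaneous and driven rates and
#' near-Poisson timing; bursting units fire 2-3 spike bursts at short
#' intraburst intervals both spontaneously and when driven, split into Bu1
#' (intraburst frequency > 500 Hz, onset-dominated, locked to rising
#' amplitude) and Bu2 (<= 500 Hz, mixed sustain).
#'
#' @param type One of `"RS"`, `"FS"`, `"Bu1"`, `"Bu2"`.
#' @return A list of class `unit_phenotype`.
#' @export
unit_phenotype <- function(type = c("RS", "FS", "Bu1", "Bu2")) {
  type <- match.arg(type)
  p <- switch(type,
    RS = list(
      spontaneous_rate = 1.8, driven_rate = 45, adaptation_tau = 0.25,
      adapt_floor = 0.45, burst_prob = 0, intraburst_interval = NA_real_,
      burst_length_dist = NULL, drive = "amplitude", drive_smooth_s = 0.008,
      onset_kick = 0.3, selectivity = 2.5, jitter_sd = 0.015,
      waveform_ttp = 0.0007, latency_s = 0.016),
    FS = list(
      spontaneous_rate = 12, driven_rate = 45, adaptation_tau = 0.5,
      adapt_floor = 0.8, burst_prob = 0, intraburst_interval = NA_real_,
      burst_length_dist = NULL, drive = "amplitude", drive_smooth_s = 0.005,
      onset_kick = 0.10, selectivity = 0.6, jitter_sd = 0.008,
      waveform_ttp = 0.0003, latency_s = 0.011),
    Bu1 = list(
      spontaneous_rate = 2.2, driven_rate = 250, adaptation_tau = 0.150,
      adapt_floor = 0.5, burst_prob = 0.85, intraburst_interval = 0.0013,
      burst_length_dist = c(`2` = 0.55, `3` = 0.35, `4` = 0.10),
      drive = "rising", drive_smooth_s = 0.002,
      onset_kick = 0, selectivity = 0.8, jitter_sd = 0.0015, waveform_ttp = 0.00048,
      latency_s = 0.009),
    Bu2 = list(
      spontaneous_rate = 1.8, driven_rate = 60, adaptation_tau = 0.120,
      adapt_floor = 0.25, burst_prob = 0.75, intraburst_interval = 0.0026,
      burst_length_dist = c(`2` = 0.6, `3` = 0.3, `4` = 0.1),
      drive = "mixed", drive_smooth_s = 0.004,
      onset_kick = 0, selectivity = 0.9, jitter_sd = 0.004, waveform_ttp = 0.00052,
      latency_s = 0.014)
  )
  p$type <- type
  stopifnot(p$spontaneous_rate >= 0, p$driven_rate >= 0,
            is.na(p$intraburst_interval) ||
              p$intraburst_interval > REFRACTORY_S,
            p$burst_prob >= 0, p$burst_prob <= 1)
  structure(p, class = "unit_phenotype")
}

# Homogeneous Poisson event times on [t0, t1) by exponential waiting times.
homogeneous_poisson <- function(rate, t0, t1) {
  if (rate <= 0) return(numeric(0))
  out <- numeric(0)
  t <- t0
  repeat {
    n <- max(64L, ceiling((t1 - t) * rate * 1.5))
    tt <- t + cumsum(rexp(n, rate))
    out <- c(out, tt[tt < t1])
    t <- tt[n]
    if (t >= t1) break
  }
  out
}

apply_dead_time <- function(times, refractory) {
  if (refractory <= 0 || length(times) < 2L) return(times)
  times <- sort(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Simulate a (possibly inhomogeneous) Poisson spike train
#'
#' Inhomogeneous rates are realized by thinning a homogeneous process at the
#' peak rate; an optional dead time then removes spikes closer than
#' `refractory` to the previous accepted spike.
#'
#' @param rate A non-negative number (spk/s) or a function of time returning
#'   the instantaneous rate.
#' @param span Length-2 numeric, the half-open time window `[t0, t1)`.
#' @param refractory Dead time in seconds (default 0: a pure Poisson process).
#' @param seed Integer seed for reproducibility.
#' @return Sorted numeric vector of spike times.
#' @examples
#' length(poisson_train(50, c(0, 10), seed = 1))
#' @export
poisson_train <- function(rate, span, refractory = 0, seed = NULL) {
  t0 <- span[1]; t1 <- span[2]
  with_seed(seed, {
    if (is.function(rate)) {
      grid <- seq(t0, t1, by = 0.001)
      rmax <- max(rate(grid), 0)
      if (rmax <= 0) return(numeric(0))
      cand <- homogeneous_poisson(rmax, t0, t1)
      keep <- runif(length(cand)) < rate(cand) / rmax
      apply_dead_time(cand[keep], refractory)
    } else {
      apply_dead_time(homogeneous_poisson(rate, t0, t1), refractory)
    }
  })
}

#' Simulate an intrinsically bursting spike train
#'
#' A two-stage process: burst *events* are drawn as an inhomogeneous Poisson
#' process from `event_rate`, and each event expands (with probability
#' `phenotype$burst_prob`) into a burst of k spikes (k drawn from
#' `phenotype$burst_length_dist`) spaced at the intraburst interval with a
#' small timing jitter; otherwise the event yields a single spike. An absolute
#' refractory period is enforced within and between bursts, and bursting is
#' present wherever the event rate is positive -- including prestimulus
#' epochs, since the spontaneous event floor is part of `event_rate`.
#'
#' @param event_rate Number or function of time: burst-event rate (events/s).
#' @param phenotype A [unit_phenotype()] with `burst_prob > 0`.
#' @inheritParams poisson_train
#' @return Sorted numeric vector of spike times.
#' @export
bursting_train <- function(event_rate, phenotype, span, seed = NULL) {
  with_seed(seed, {
    events <- poisson_train(event_rate, span,
                            refractory = phenotype$intraburst_interval * 2)
    if (length(events) == 0L) return(numeric(0))
    lens <- rep(1L, length(events))
    burst <- runif(length(events)) < phenotype$burst_prob
    if (any(burst)) {
      ks <- as.integer(names(phenotype$burst_length_dist))
      lens[burst] <- sample(ks, sum(burst), replace = TRUE,
                            prob = phenotype$burst_length_dist)
    }
    spikes <- unlist(lapply(seq_along(events), function(i) {
      k <- lens[i]
      gaps <- phenotype$intraburst_interval *
        pmax(rnorm(k - 1L, 1, 0.05), REFRACTORY_S / phenotype$intraburst_interval)
      events[i] + c(0, cumsum(gaps))
    }), use.names = FALSE)
    spikes <- apply_dead_time(spikes, REFRACTORY_S)
    sort(spikes[in_window(spikes, span[1], span[2])])
  })
}

#' Synthesize biphasic extracellular waveform snippets
#'
#' Builds a biphasic template (negative trough followed by a positive peak)
#' with the requested trough-to-peak time, then draws noisy snippets around
#' it. Narrower templates carry more high-frequency energy, so trough-to-peak
#' time and spectral width move inversely across the waveform family.
#'
#' @param ttp_s Trough-to-peak time in seconds.
#' @param n_spikes Number of snippets (columns).
#' @param sample_rate_hz Sampling rate (default 24414 Hz).
#' @param noise_sd Additive white-noise SD relative to unit trough depth.
#' @param seed Integer seed.
#' @return List with `snippets` (samples x spikes matrix, trough near sample
#'   `trough_index`), `sample_rate_hz`, `trough_index`.
#' @export
synth_waveform <- function(ttp_s, n_spikes, sample_rate_hz = 24414,
                           noise_sd = 0.02, seed = NULL) {
  if (n_spikes < 1) abort("n_spikes must be >= 1")
  n_samples <- 400L
  trough_index <- 281L
  tt <- (seq_len(n_samples) - trough_index) / sample_rate_hz
  sig_t <- 0.22 * ttp_s
  sig_p <- 0.45 * ttp_s
  template <- -exp(-tt^2 / (2 * sig_t^2)) +
    0.45 * exp(-(tt - ttp_s)^2 / (2 * sig_p^2))
  with_seed(seed, {
    snippets <- matrix(template, n_samples, n_spikes) +
      matrix(rnorm(n_samples * n_spikes, 0, noise_sd), n_samples)
    list(snippets = snippets, sample_rate_hz = sample_rate_hz,
         trough_index = trough_index)
  })
}

# ---- benchmark session ------------------------------------------------------

default_protocols <- c("tuning", "duration_series", "ramp_series",
                       "sam_series", "vocal_list")

# Stimulus tables (and envelopes) for each protocol. Envelopes are part of the
# session's ground truth: fixed per stimulus, shared by all units.
build_protocols <- function(protocols, seed, prestim = 0.2, posttrial = 0.35) {
  bad <- setdiff(protocols, default_protocols)
  if (length(bad)) {
    abort(sprintf("unknown protocol name(s): %s", paste(bad, collapse = ", ")))
  }
  rows <- list(); envs <- list()
  add <- function(proto, id, kind, dur, mod = NA_real_, ramp = NA_real_, env) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      stimulus_id = id, protocol = proto, kind = kind, onset_s = 0,
      duration_s = dur, mod_rate_hz = mod, ramp_s = ramp,
      t_min_s = -prestim, t_max_s = dur + posttrial)
    envs[[paste(proto, id)]] <<- env
  }
  if ("tuning" %in% protocols) {
    for (i in 1:5) {
      add("tuning", paste0("T", i), "tone", 0.2,
          env = duration_and_ramp_envelopes(0.2, 0.005)[[1]])
    }
  }
  if ("duration_series" %in% protocols) {
    durs <- c(12.5, 25, 50, 100, 200, 400) / 1000
    es <- duration_and_ramp_envelopes(durs, 0.005)
    for (i in seq_along(durs)) {
      add("duration_series", sprintf("D%02.0f", durs[i] * 1000),
          "duration_series", durs[i], ramp = 0.005, env = es[[i]])
    }
  }
  if ("ramp_series" %in% protocols) {
    ramps <- c(0.005, 0.02, 0.05, 0.1)
    es <- duration_and_ramp_envelopes(rep(0.2, length(ramps)), ramps)
    for (i in seq_along(ramps)) {
      add("ramp_series", sprintf("R%03.0f", ramps[i] * 1000), "ramp", 0.2,
          ramp = ramps[i], env = es[[i]])
    }
  }
  if ("sam_series" %in% protocols) {
    rates <- 2^(1:9)  # 2..512 Hz, octave spaced
    for (f in rates) {
      add("sam_series", sprintf("S%03d", f), "SAM", 1.0, mod = f,
          env = sam_envelope(f, 1.0))
    }
  }
  if ("vocal_list" %in% protocols) {
    # 5 call-type families x 4 exemplars: exemplars of a family share an
    # event skeleton (onsets jittered ~8 ms, peaks rescaled), as same-type
    # vocalization tokens do
    i <- 0L
    for (fam in 1:5) {
      skel <- with_seed(child_seed(seed, 200 + fam), {
        dur <- round(runif(1, 0.3, 1.0), 2)
        n_ev <- sample(3:8, 1)
        list(dur = dur, trill = fam == 5,
             onsets = sort(runif(n_ev, 0, max(dur - 0.08, 0))),
             peaks = runif(n_ev, 0.6, 1))
      })
      for (ex in 1:4) {
        i <- i + 1L
        # exemplars of a call type differ mostly in event timing (~12 ms),
        # only slightly in event level
        env <- with_seed(child_seed(seed, 300 + 10 * fam + ex),
          envelope_from_events(
            pmax(skel$onsets + rnorm(length(skel$onsets), 0, 0.012), 0),
            pmin(skel$peaks * exp(rnorm(length(skel$peaks), 0, 0.05)), 1),
            skel$dur, trill = skel$trill))
        add("vocal_list", sprintf("V%02d", i), "vocalization", skel$dur,
            env = env)
      }
    }
  }
  list(stimuli = dplyr::bind_rows(rows), envelopes = envs)
}

# Instantaneous drive for one phenotype and stimulus envelope: the envelope
# itself for RS/FS, its rectified derivative (normalized to peak 1 over the
# session) for Bu1, and an even mixture for Bu2; smoothed by the phenotype's
# integration time and multiplied by an exponential-decay adaptation profile.
drive_fn <- function(phen, env, gain_stim, mod_seed = NULL) {
  dt <- env$t[2] - env$t[1]
  base <- switch(phen$drive,
    amplitude = env$amplitude + phen$onset_kick * env$rising / 200,
    rising = env$rising / 200,
    mixed = 0.5 * env$amplitude + 0.5 * env$rising / 200)
  base <- pmin(base, 1.5)
  # unit-by-stimulus "response field": a smooth random gain over time so that
  # different units of a type emphasize different epochs or acoustic events
  if (!is.null(mod_seed)) {
    base <- base * response_field(env$t, mod_seed)
  }
  if (phen$drive_smooth_s > dt) {
    kern <- dnorm(seq(-4, 4, by = dt / phen$drive_smooth_s))
    kern <- kern / sum(kern)
    n <- length(base)
    pad <- c(rep(0, length(kern)), base, rep(0, length(kern)))
    sm <- stats::filter(pad, kern, sides = 2)
    base <- as.numeric(sm[length(kern) + seq_len(n)])
    base[is.na(base)] <- 0
  }
  adapt <- phen$adapt_floor +
    (1 - phen$adapt_floor) * exp(-pmax(env$t, 0) / phen$adaptation_tau)
  drive <- gain_stim * phen$driven_rate * base * adapt
  tgrid <- env$t + (phen$latency_s %||% 0)
  function(t) {
    y <- approx(tgrid, drive, xout = t, yleft = 0, yright = 0)$y
    ifelse(is.na(y), 0, y)
  }
}

# Smooth random temporal gain in [0.1, 3] with mean ~1: log-normal control
# points every ~80 ms, linearly interpolated.
response_field <- function(t, seed) {
  with_seed(seed, {
    k <- max(3L, ceiling((max(t) - min(t)) / 0.08) + 1L)
    ctrl <- exp(rnorm(k, 0, 0.7))
    g <- approx(seq(min(t), max(t), length.out = k), ctrl, xout = t)$y
    g <- g / mean(g)
    pmin(pmax(g, 0.1), 3)
  })
}

# Per-stimulus gain profile of one unit: selectivity controls how steeply
# gains fall away from the unit's (randomly chosen) preferred stimulus.
# SAM, duration and ramp protocols are delivered at the unit's best frequency,
# level and bandwidth, so tuning selectivity does not apply there (gain 1).
stim_gains <- function(phen, proto, stim_ids, seed) {
  if (proto %in% c("sam_series", "duration_series", "ramp_series")) {
    return(setNames(rep(1, length(stim_ids)), stim_ids))
  }
  with_seed(seed, {
    if (proto == "vocal_list") {
      # selectivity operates at the call-type family level (4 exemplars each)
      fam <- (seq_along(stim_ids) - 1L) %/% 4L + 1L
      n <- max(fam)
      pref <- sample.int(n, 1)
      d <- abs(fam - pref) / max(1, n - 1)
    } else {
      n <- length(stim_ids)
      pref <- sample.int(n, 1)
      d <- abs(seq_len(n) - pref) / max(1, n - 1)
    }
    g <- exp(-phen$selectivity * 3 * d)
    setNames(pmax(g, 0.02), stim_ids)
  })
}

#' Generate a labeled synthetic benchmark session
#'
#' Draws a full multi-protocol session of synthetic units whose spike timing
#' and waveforms reproduce the statistical structure of the four emulated unit
#' classes (see [unit_phenotype()]). Each unit carries its ground-truth type in
#' `units$truth_type`, so classification and decoding stages can be scored in
#' closed loop. Deterministic given `seed`.
#'
#' @param n_units_by_type Named integer vector over `RS`, `FS`, `Bu1`, `Bu2`.
#' @param protocols Subset of `"tuning"`, `"duration_series"`, `"ramp_series"`,
#'   `"sam_series"`, `"vocal_list"`.
#' @param seed Integer seed.
#' @param n_reps Repetitions per stimulus (default 10, interleaved).
#' @param prestim Prestimulus epoch per trial in seconds (default 0.2).
#' @param n_waveform_spikes Snippets per unit (default 60).
#' @return A [spike_session()].
#' @export
generate_benchmark_session <- function(n_units_by_type = c(RS = 16, FS = 10,
                                                           Bu1 = 7, Bu2 = 9),
                                       protocols = default_protocols,
                                       seed = 1, n_reps = 10, prestim = 0.2,
                                       n_waveform_spikes = 60) {
  pr <- build_protocols(protocols, seed, prestim = prestim)
  stimuli <- pr$stimuli
  types <- rep(names(n_units_by_type), n_units_by_type)
  unit_ids <- sprintf("u%03d", seq_along(types))
  spike_rows <- vector("list", length(types))
  waveforms <- list()
  for (ui in seq_along(types)) {
    phen <- unit_phenotype(types[ui])
    useed <- child_seed(seed, ui)
    # per-unit heterogeneity: lognormal scatter of rates and time constants
    # within a type, keeping each unit inside its class definition
    phen <- with_seed(child_seed(useed, 3), {
      phen$spontaneous_rate <- phen$spontaneous_rate * exp(rnorm(1, 0, 0.2))
      phen$driven_rate <- phen$driven_rate * exp(rnorm(1, 0, 0.25))
      phen$adaptation_tau <- phen$adaptation_tau * exp(rnorm(1, 0, 0.2))
      phen$latency_s <- phen$latency_s * exp(rnorm(1, 0, 0.35))
      if (!is.na(phen$intraburst_interval)) {
        phen$intraburst_interval <-
          phen$intraburst_interval * exp(rnorm(1, 0, 0.07))
      }
      phen
    })
    ttp <- with_seed(child_seed(useed, 1),
                     max(phen$waveform_ttp + rnorm(1, 0, 0.00004), 0.00015))
    wf <- synth_waveform(ttp, n_waveform_spikes,
                         seed = child_seed(useed, 2))
    waveforms[[unit_ids[ui]]] <- wf[c("snippets", "sample_rate_hz")]
    per_proto <- lapply(unique(stimuli$protocol), function(proto) {
      st <- stimuli[stimuli$protocol == proto, ]
      gains <- stim_gains(phen, proto, st$stimulus_id,
                          child_seed(useed, 10 + match(proto,
                                                       default_protocols)))
      rows <- list()
      for (si in seq_len(nrow(st))) {
        env <- pr$envelopes[[paste(proto, st$stimulus_id[si])]]
        drv <- drive_fn(phen, env, gains[st$stimulus_id[si]],
                        mod_seed = child_seed(useed, 5000 +
                          1000 * match(proto, default_protocols) + si))
        span <- c(st$t_min_s[si], st$t_max_s[si])
        for (rep_i in seq_len(n_reps)) {
          tseed <- child_seed(useed, 1000 * si + rep_i +
                                1e5 * match(proto, default_protocols))
          trial_gain <- with_seed(child_seed(tseed, 9), exp(rnorm(1, 0, 0.3)))
          if (phen$burst_prob > 0) {
            ev_rate <- function(t) phen$spontaneous_rate + trial_gain * drv(t)
            times <- bursting_train(ev_rate, phen, span, seed = tseed)
            times <- jitter_events(times, phen, tseed)
          } else {
            rate <- function(t) phen$spontaneous_rate + trial_gain * drv(t)
            times <- poisson_train(rate, span, refractory = REFRACTORY_S,
                                   seed = tseed)
          }
          times <- sort(times[in_window(times, span[1], span[2])])
          if (length(times)) {
            rows[[length(rows) + 1L]] <- tibble::tibble(
              unit_id = unit_ids[ui], protocol = proto,
              stimulus_id = st$stimulus_id[si], repetition = rep_i,
              time_s = times)
          }
        }
      }
      dplyr::bind_rows(rows)
    })
    spike_rows[[ui]] <- dplyr::bind_rows(per_proto)
  }
  units <- tibble::tibble(unit_id = unit_ids, prestim_s = prestim,
                          truth_type = types)
  spike_session(dplyr::bind_rows(spike_rows), stimuli, units, waveforms)
}

# Event-level timing jitter for driven bursting spikes: shifts whole bursts
# (spikes closer than 2x the intraburst interval move together) so intraburst
# structure is preserved.
jitter_events <- function(times, phen, seed) {
  if (length(times) == 0L || phen$jitter_sd <= 0) return(times)
  with_seed(child_seed(seed, 77), {
    gap <- c(Inf, diff(times))
    burst_id <- cumsum(gap > 2.5 * phen$intraburst_interval)
    shift <- rnorm(max(burst_id), 0, phen$jitter_sd)
    sort(times + shift[burst_id])
  })
}
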