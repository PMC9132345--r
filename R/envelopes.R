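#' Stimulus envelopes
#'
#' Envelopes are amplitude time-courses in `[0, 1]` on a uniform 1 ms grid;
#' they drive the inhomogeneous rate of the synthetic spike generators. The
#' rising-slope signal (positive part of the first derivative) is carried
#' along because bursting phenotypes preferentially fire on rising amplitude.
#'
#' @param mod_rate Modulation rate in Hz (> 0).
#' @param duration Envelope duration in seconds.
#' @param dt Grid step in seconds (default 1 ms).
#' @return A tibble of class `envelope` with columns `t`, `amplitude`,
#'   `rising` (rectified derivative, 1/s).
#' @examples
#' env <- sam_envelope(2, 0.5)
#' max(env$amplitude)
#' @name envelopes
NULL

new_envelope <- function(t, amplitude) {
  amplitude <- pmin(pmax(amplitude, 0), 1)
  dt <- t[2] - t[1]
  rising <- pmax(c(diff(amplitude) / dt, 0), 0)
  structure(tibble::tibble(t = t, amplitude = amplitude, rising = rising),
            class = c("envelope", "tbl_df", "tbl", "data.frame"))
}

#' @describeIn envelopes Sinusoidal amplitude modulation at 100% depth,
#'   `0.5 * (1 - cos(2 pi f t))`, so the envelope starts at 0 and the first
#'   crest of a 2 Hz envelope sits at 0.25 s.
#' @export
sam_envelope <- function(mod_rate, duration, dt = 0.001) {
  stopifnot_scalar_number(mod_rate, "mod_rate", min = .Machine$double.eps)
  t <- seq(0, duration, by = dt)
  new_envelope(t, 0.5 * (1 - cos(2 * pi * mod_rate * t)))
}

#' @describeIn envelopes Flat-topped envelope with a linear onset ramp of
#'   `ramp_time` seconds (default 5 ms); one envelope per requested duration.
#' @param durations Vector of stimulus durations in seconds.
#' @param ramp_times Vector of onset ramp times (recycled against durations).
#' @return For `duration_and_ramp_envelopes()`: a list of envelopes.
#' @export
duration_and_ramp_envelopes <- function(durations = c(12.5, 25, 50, 100, 200, 400) / 1000,
                                        ramp_times = 0.005) {
  if (any(durations <= 0)) abort("durations must be > 0")
  ramp_times <- rep_len(ramp_times, length(durations))
  if (any(ramp_times > durations)) {
    abort("ramp_time must not exceed stimulus duration")
  }
  purrr::map2(durations, ramp_times, function(d, r) {
    t <- seq(0, d, by = 0.001)
    amp <- if (r > 0) pmin(t / r, 1) else rep(1, length(t))
    amp[t >= d] <- 0
    new_envelope(t, amp)
  })
}

#' @describeIn envelopes Synthetic vocalization-like envelope: a seeded sum of
#'   randomly placed sharp-attack / exponential-decay events, optionally with
#'   a 30 Hz trill-like sub-modulation.
#' @param n_events Number of acoustic events (>= 1).
#' @param trill If `TRUE`, impose a 30 Hz sub-modulation on the event decays.
#' @param seed Integer seed; same seed, same envelope.
#' @export
vocalization_envelope <- function(n_events, duration, trill = FALSE,
                                  seed = NULL, dt = 0.001) {
  if (n_events < 1) abort("n_events must be >= 1")
  ev <- with_seed(seed, list(
    onsets = sort(runif(n_events, 0, max(duration - 0.08, 0))),
    peaks = runif(n_events, 0.6, 1)))
  envelope_from_events(ev$onsets, ev$peaks, duration, trill = trill, dt = dt)
}

# Assemble a vocalization-like envelope from explicit event onsets/peaks:
# 5 ms linear attack, 40 ms exponential decay per event.
envelope_from_events <- function(onsets, peaks, duration, trill = FALSE,
                                 dt = 0.001) {
  t <- seq(0, duration, by = dt)
  a <- numeric(length(t))
  for (i in seq_along(onsets)) {
    rel <- t - onsets[i]
    ev <- ifelse(rel < 0, 0,
                 ifelse(rel < 0.005, rel / 0.005, exp(-(rel - 0.005) / 0.04)))
    a <- pmax(a, peaks[i] * ev)
  }
  if (trill) a <- a * (0.1 + 0.9 * (0.5 * (1 - cos(2 * pi * 30 * t))))
  new_envelope(t, a)
}

# Linear interpolation of an envelope (amplitude or rising channel) at
# arbitrary times; zero outside the grid.
envelope_at <- function(env, times, channel = "amplitude") {
  approx(env$t, env[[channel]], xout = times, yleft = 0, yright = 0,
         rule = 1)$y |> (\(y) ifelse(is.na(y), 0, y))()
}
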