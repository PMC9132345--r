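#' Build a spike session container
#'
#' A `spike_session` bundles everything recorded (or simulated) for a set of
#' single units: a long table of spike times aligned to stimulus onset, a
#' stimulus descriptor table, a unit table, and optional per-unit waveform
#' snippet matrices. All downstream analyses consume this container.
#'
#' Spike times are in seconds with stimulus onset at 0; each trial spans
#' `[-prestim_s, duration_s + posttrim]` as recorded per stimulus in
#' `stimuli$t_min_s` / `stimuli$t_max_s`. All windows in the package are
#' half-open `[t0, t1)`.
#'
#' @param spikes Tibble with columns `unit_id`, `protocol`, `stimulus_id`,
#'   `repetition`, `time_s`.
#' @param stimuli Tibble with columns `stimulus_id`, `protocol`, `kind`
#'   (one of `"tone"`, `"bandpass"`, `"SAM"`, `"duration_series"`, `"ramp"`,
#'   `"vocalization"`), `onset_s`, `duration_s`, `mod_rate_hz`, `ramp_s`,
#'   `t_min_s`, `t_max_s`.
#' @param units Tibble with columns `unit_id`, `prestim_s` (default 0.2) and
#'   optionally `truth_type` (ground truth for synthetic units).
#' @param waveforms Named list (by `unit_id`) of lists with elements
#'   `snippets` (samples x spikes matrix) and `sample_rate_hz`.
#' @return An object of class `spike_session`.
#' @export
spike_session <- function(spikes, stimuli, units, waveforms = list()) {
  spikes <- tibble::as_tibble(spikes)
  stimuli <- tibble::as_tibble(stimuli)
  units <- tibble::as_tibble(units)
  if (!"truth_type" %in% names(units)) units$truth_type <- NA_character_
  if (!"mod_rate_hz" %in% names(stimuli)) stimuli$mod_rate_hz <- NA_real_
  if (!"ramp_s" %in% names(stimuli)) stimuli$ramp_s <- NA_real_
  ses <- structure(
    list(spikes = spikes, stimuli = stimuli, units = units,
         waveforms = waveforms),
    class = "spike_session"
  )
  validate_session(ses)
  ses
}

validate_session <- function(ses) {
  sp <- ses$spikes
  st <- ses$stimuli
  need <- c("unit_id", "protocol", "stimulus_id", "repetition", "time_s")
  if (!all(need %in% names(sp))) {
    abort(paste0("spikes table must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (any(st$duration_s <= 0)) abort("stimulus duration_s must be > 0")
  if (any(st$kind == "SAM" & !(st$mod_rate_hz > 0), na.rm = TRUE)) {
    abort("SAM stimuli require mod_rate_hz > 0")
  }
  key <- paste(sp$protocol, sp$stimulus_id)
  known <- paste(st$protocol, st$stimulus_id)
  bad <- setdiff(unique(key), known)
  if (length(bad)) {
    abort(sprintf(
      "integrity error: spike trains reference unknown stimuli: %s",
      paste(bad, collapse = "; ")))
  }
  invisible(ses)
}

#' @export
print.spike_session <- function(x, ...) {
  cat(sprintf(
    "<spike_session> %d units, %d stimuli, %d spikes, %d waveform blocks\n",
    nrow(x$units), nrow(x$stimuli), nrow(x$spikes), length(x$waveforms)))
  invisible(x)
}

#' Restrict spike times to a half-open window
#'
#' @param times Numeric vector of spike times (seconds), sorted.
#' @param t0,t1 Window start and end; spikes with `t0 <= t < t1` are kept.
#' @return Numeric vector of the retained times.
#' @examples
#' slice_epoch(c(0.005, 0.05, 0.3), 0.01, 0.25)
#' @export
slice_epoch <- function(times, t0, t1) {
  if (!(t0 < t1 || t0 == t1)) abort("window must satisfy t0 <= t1")
  times[in_window(times, t0, t1)]
}

#' Pool prestimulus interspike intervals for one unit
#'
#' Intervals are computed only within each trial's prestimulus segment
#' `[-prestim_s, 0)` -- never across segment boundaries -- and pooled over all
#' stimuli, repetitions and protocols, so that very sparsely firing units can
#' still accumulate enough intervals.
#'
#' @param session A [spike_session()].
#' @param unit_id Unit to pool.
#' @return Numeric vector of ISIs in seconds (possibly empty).
#' @export
pool_prestim_intervals <- function(session, unit_id) {
  pre <- session$units$prestim_s[match(unit_id, session$units$unit_id)]
  if (is.na(pre)) abort(sprintf("unknown unit '%s'", unit_id))
  sp <- session$spikes[session$spikes$unit_id == unit_id, ]
  sp <- sp[in_window(sp$time_s, -pre, 0), ]
  if (nrow(sp) == 0L) return(numeric(0))
  grp <- paste(sp$protocol, sp$stimulus_id, sp$repetition)
  unlist(lapply(split(sp$time_s, grp), function(tt) diff(sort(tt))),
         use.names = FALSE)
}

#' Extract per-trial spike trains for one unit
#'
#' @param session A [spike_session()].
#' @param unit_id Unit of interest.
#' @param protocol Optional protocol filter.
#' @param stimulus_id Optional stimulus filter.
#' @return Tibble with one row per recorded trial (`protocol`, `stimulus_id`,
#'   `repetition`) and a list-column `times` of sorted spike times; trials with
#'   no spikes appear with an empty vector.
#' @export
unit_trains <- function(session, unit_id, protocol = NULL, stimulus_id = NULL) {
  st <- session$stimuli
  if (!is.null(protocol)) st <- st[st$protocol %in% protocol, ]
  if (!is.null(stimulus_id)) st <- st[st$stimulus_id %in% stimulus_id, ]
  sp <- session$spikes[session$spikes$unit_id == unit_id, ]
  reps <- sort(unique(session$spikes$repetition))
  if (length(reps) == 0L) reps <- 1L
  grid <- tidyr::expand_grid(
    protocol = unique(st$protocol), repetition = reps) |>
    dplyr::inner_join(st[, c("protocol", "stimulus_id")], by = "protocol",
                      relationship = "many-to-many")
  key_sp <- paste(sp$protocol, sp$stimulus_id, sp$repetition)
  times <- split(sp$time_s, factor(key_sp,
    levels = paste(grid$protocol, grid$stimulus_id, grid$repetition)))
  grid$times <- lapply(times, sort)
  tibble::as_tibble(grid[, c("protocol", "stimulus_id", "repetition", "times")])
}

quantize_us <- function(x) round(x * 1e6) / 1e6

#' Write a session to disk as plain-text files
#'
#' Emits `manifest.json`, `spikes.csv`, `stimuli.csv` and one
#' `waveforms_<unit>.csv` per unit with snippets (rows = samples). Spike times
#' are quantized to 1 microsecond so that [read_session()] inverts the write
#' bit-exactly.
#'
#' @param session A [spike_session()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create '%s'", out_dir))
  sp <- session$spikes
  sp$time_s <- sprintf("%.6f", quantize_us(sp$time_s))
  utils::write.csv(sp, file.path(out_dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(session$stimuli, file.path(out_dir, "stimuli.csv"),
                   row.names = FALSE)
  wf_meta <- lapply(names(session$waveforms), function(u) {
    f <- paste0("waveforms_", u, ".csv")
    utils::write.table(
      session$waveforms[[u]]$snippets, file.path(out_dir, f),
      sep = ",", row.names = FALSE, col.names = FALSE)
    list(unit_id = u, file = f,
         sample_rate_hz = session$waveforms[[u]]$sample_rate_hz)
  })
  manifest <- list(
    format = "spiketypes-session/1",
    spikes = "spikes.csv",
    stimuli = "stimuli.csv",
    units = lapply(seq_len(nrow(session$units)), function(i) {
      u <- session$units[i, ]
      list(unit_id = u$unit_id, prestim_s = u$prestim_s,
           truth_type = if (is.na(u$truth_type)) NULL else u$truth_type)
    }),
    waveforms = wf_meta
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param manifest_path Path to `manifest.json`.
#' @return A [spike_session()]. Units whose waveform file is missing get an
#'   empty waveform block rather than failing.
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest '%s' does not exist", manifest_path))
  }
  man <- tryCatch(jsonlite::read_json(manifest_path),
                  error = function(e) abort(sprintf(
                    "malformed manifest '%s': %s", manifest_path,
                    conditionMessage(e))))
  for (f in c("spikes", "stimuli", "units")) {
    if (is.null(man[[f]])) {
      abort(sprintf("malformed manifest '%s': missing field '%s'",
                    manifest_path, f))
    }
  }
  dir <- dirname(manifest_path)
  spikes <- tibble::as_tibble(utils::read.csv(
    file.path(dir, man$spikes),
    colClasses = c(time_s = "character")))
  spikes$time_s <- as.numeric(spikes$time_s)
  spikes$unit_id <- as.character(spikes$unit_id)
  spikes$stimulus_id <- as.character(spikes$stimulus_id)
  stimuli <- tibble::as_tibble(utils::read.csv(file.path(dir, man$stimuli)))
  stimuli$stimulus_id <- as.character(stimuli$stimulus_id)
  units <- tibble::tibble(
    unit_id = vapply(man$units, function(u) as.character(u$unit_id), ""),
    prestim_s = vapply(man$units, function(u) as.numeric(u$prestim_s), 0),
    truth_type = vapply(man$units,
                        function(u) u$truth_type %||% NA_character_, ""))
  waveforms <- list()
  for (w in man$waveforms %||% list()) {
    f <- file.path(dir, w$file)
    if (!file.exists(f)) next
    m <- as.matrix(utils::read.csv(f, header = FALSE))
    dimnames(m) <- NULL
    waveforms[[as.character(w$unit_id)]] <-
      list(snippets = m, sample_rate_hz = as.numeric(w$sample_rate_hz))
  }
  spike_session(spikes, stimuli, units, waveforms)
}
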