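# Shared fixtures, generated once per test run.

# A compact session for unit-level checks: tuning protocol only.
tiny_session <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- generate_benchmark_session(
      c(RS = 2, FS = 2, Bu1 = 2, Bu2 = 2),
      protocols = c("tuning"), seed = 301)
  }
  .fixture_env$tiny
}

# A session with SAM and vocalizations for response/decoding checks.
mid_session <- function() {
  if (is.null(.fixture_env$mid)) {
    .fixture_env$mid <- generate_benchmark_session(
      c(RS = 3, FS = 2, Bu1 = 3, Bu2 = 2),
      protocols = c("tuning", "sam_series", "vocal_list"), seed = 302)
  }
  .fixture_env$mid
}

.fixture_env <- new.env(parent = emptyenv())
.fixture_env$tiny <- NULL
.fixture_env$mid <- NULL

truth_of <- function(ses) setNames(ses$units$truth_type, ses$units$unit_id)
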