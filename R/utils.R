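#' Evaluate an expression under a local, restored RNG state
#'
#' All stochastic functions in the package funnel their seed through this
#' helper so that a call never disturbs the caller's RNG stream and the same
#' seed always yields the same result.
#'
#' @param seed Integer seed, or `NULL` to use (and advance) the global stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, staying inside
# 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629L)
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s", name, format(min)))
  }
  invisible(x)
}

# Half-open membership t0 <= x < t1, the window convention used throughout.
in_window <- function(x, t0, t1) x >= t0 & x < t1
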