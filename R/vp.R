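#' Victor-Purpura spike-train distance
#'
#' Minimum cost of editing one spike train into another, where inserting or
#' deleting a spike costs 1 and shifting a spike by `dt` costs `q * |dt|`
#' (`q` in 1/s). At `q = 0` the distance is the difference in spike counts; a
#' shift beyond `2/q` is never worthwhile (delete and reinsert is cheaper).
#' Exact dynamic program.
#'
#' @param a,b Sorted numeric vectors of spike times (seconds).
#' @param q Cost parameter in 1/s (>= 0).
#' @return The distance (dimensionless cost).
#' @examples
#' vp_distance(0.010, 0.015, q = 100)  # min(2, 100 * 0.005) = 0.5
#' @export
vp_distance <- function(a, b, q) {
  if (q < 0) abort("q must be >= 0")
  vp_distance_cpp(sort(a), sort(b), q)
}

#' Pairwise Victor-Purpura distances for a set of trains
#'
#' @param trains List of sorted spike-time vectors.
#' @inheritParams vp_distance
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
vp_distance_matrix <- function(trains, q) {
  if (q < 0) abort("q must be >= 0")
  vp_distance_matrix_cpp(lapply(trains, sort), q)
}

#' Crop responses to a common segment centered on the response density peak
#'
#' Stimuli of very different lengths make decoding trivially sensitive to
#' total spike count; to remove that artifact, each stimulus's response is
#' cropped to a segment of the shortest stimulus's duration, centered on the
#' peak of a Gaussian kernel density estimate (sigma = 20 ms) of the pooled
#' response, clipped to start no earlier than the stimulus window. Stimuli
#' with no spikes anchor the segment at stimulus onset. Cropped trains are
#' re-referenced to the segment start.
#'
#' @param trains_by_stimulus Named list: per stimulus, a list of per-repetition
#'   spike-time vectors (seconds from stimulus onset).
#' @param target_len_s Segment length (the shortest stimulus duration).
#' @param stim_durations_s Named vector of stimulus durations (for clipping).
#' @param kde_sigma_s KDE bandwidth (default 0.020).
#' @return List of the same shape with cropped, re-referenced trains;
#'   attribute `segments` records each chosen `[t0, t1)`.
#' @export
crop_and_center <- function(trains_by_stimulus, target_len_s,
                            stim_durations_s, kde_sigma_s = 0.020) {
  segs <- list()
  out <- lapply(names(trains_by_stimulus), function(sid) {
    trains <- trains_by_stimulus[[sid]]
    pooled <- unlist(trains, use.names = FALSE)
    dur <- stim_durations_s[[sid]]
    hi_limit <- max(dur, target_len_s)
    if (length(pooled) == 0L) {
      t0 <- 0
    } else {
      grid <- seq(0, hi_limit, by = 0.001)
      dens <- vapply(grid, function(g) {
        sum(dnorm(pooled - g, sd = kde_sigma_s))
      }, 0)
      peak <- grid[which.max(dens)]
      t0 <- min(max(peak - target_len_s / 2, 0), hi_limit - target_len_s)
    }
    segs[[sid]] <<- c(t0, t0 + target_len_s)
    lapply(trains, function(tt) {
      sort(tt[in_window(tt, t0, t0 + target_len_s)]) - t0
    })
  })
  names(out) <- names(trains_by_stimulus)
  attr(out, "segments") <- segs
  out
}

#' Classify spike trains by nearest-stimulus Victor-Purpura distance
#'
#' Leave-one-out template matching: each train is compared with every other
#' train; its distance to a stimulus is the power mean (exponent `z = -3`,
#' which emphasizes small distances) of its distances to that stimulus's
#' other repetitions; the train is assigned to the stimulus with minimal
#' average distance, ties tallied as `1/k`. Any zero distance forces that
#' stimulus's average to 0 (the power transform maps any set containing 0 to
#' 0, a known distortion).
#'
#' @param trains List of sorted spike-time vectors.
#' @param labels Stimulus label per train (>= 2 repetitions per stimulus).
#' @param q Cost parameter (1/s).
#' @param z Power-mean exponent (default -3).
#' @param dmat Optional precomputed distance matrix.
#' @return Object of class `confusion_matrix`: stimulus x decoded-stimulus
#'   matrix of (possibly fractional) tallies.
#' @export
classify_trains <- function(trains, labels, q, z = -3, dmat = NULL) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L) abort("need at least 2 stimuli")
  if (any(tab < 2L)) {
    drop <- names(tab)[tab < 2L]
    warn(sprintf("excluding stimuli with a single repetition: %s",
                 paste(drop, collapse = ", ")))
    keep <- !(labels %in% drop)
    trains <- trains[keep]
    if (!is.null(dmat)) dmat <- dmat[keep, keep, drop = FALSE]
    labels <- labels[keep]
  }
  stims <- sort(unique(labels))
  if (is.null(dmat)) dmat <- vp_distance_matrix(trains, q)
  n <- length(trains)
  cm <- matrix(0, length(stims), length(stims),
               dimnames = list(true = stims, decoded = stims))
  for (i in seq_len(n)) {
    avg <- vapply(stims, function(s) {
      js <- setdiff(which(labels == s), i)
      if (!length(js)) return(Inf)
      d <- dmat[i, js]
      if (any(d == 0)) return(0)
      mean(d^z)^(1 / z)
    }, 0)
    winners <- which(avg == min(avg))
    cm[labels[i], winners] <- cm[labels[i], winners] + 1 / length(winners)
  }
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Transmitted information of a confusion matrix
#'
#' Mutual information (bits) between true and decoded stimulus under the
#' joint distribution `p(s, s_hat) = cm / sum(cm)`, with `0 log 0 = 0`.
#' Bounded by `log2(S)` for `S` stimuli.
#'
#' @param cm Confusion matrix (tallies, possibly fractional).
#' @return Information in bits.
#' @export
transmitted_information <- function(cm) {
  total <- sum(cm)
  if (total <= 0) abort("confusion matrix is empty")
  p <- cm / total
  ps <- rowSums(p)
  pd <- colSums(p)
  terms <- p * log2(p / outer(ps, pd))
  sum(terms[is.finite(terms)])
}

#' Information-versus-cost sweep with a shuffle null
#'
#' Runs [classify_trains()] across a grid of cost parameters, reports the
#' transmitted information `H(q)`, its max-normalized curve, and a z-score of
#' the best `H` against a null built by shuffling stimulus labels
#' (`n_shuffles` times, seeded) at the best q. Units whose z-score exceeds
#' `z_thresh` are conventionally pooled for population summaries.
#'
#' @param trains List of sorted (cropped) spike-time vectors.
#' @param labels Stimulus label per train.
#' @param q_grid Cost grid in 1/s (default 0 and octave steps 1..4096).
#' @param n_shuffles Label shuffles for the null (default 100).
#' @param z_thresh Inclusion threshold (default 3).
#' @param seed Integer seed for the shuffles.
#' @return List with `sweep` (tibble: `q`, `h_bits`, `h_norm`), `best_q`,
#'   `z`, `include`.
#' @export
q_sweep <- function(trains, labels, q_grid = c(0, 2^(0:12)),
                    n_shuffles = 100, z_thresh = 3, seed = 1) {
  if (all(lengths(trains) == 0L)) abort("all trains empty: unit excluded")
  h <- vapply(q_grid, function(q) {
    transmitted_information(classify_trains(trains, labels, q))
  }, 0)
  best <- which.max(h)
  null_h <- with_seed(seed, {
    dmat <- vp_distance_matrix(trains, q_grid[best])
    vapply(seq_len(n_shuffles), function(i) {
      transmitted_information(
        classify_trains(trains, sample(labels), q_grid[best], dmat = dmat))
    }, 0)
  })
  z <- (h[best] - mean(null_h)) / sd(null_h)
  list(
    sweep = tibble::tibble(q = q_grid, h_bits = h, h_norm = h / max(h)),
    best_q = q_grid[best], z = z, include = z > z_thresh)
}
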