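#' Time-binned response tensor for population decoding
#'
#' Counts spikes per half-open time bin over the cropped window (shortest
#' stimulus duration plus 300 ms, so short stimuli contribute poststimulus
#' bins, akin to zero-padding).
#'
#' @param session A [spike_session()].
#' @param unit_ids Units to include (default all).
#' @param protocol Protocol with the repeated stimulus set (default
#'   `"vocal_list"`).
#' @param bin_width_s Bin width (default 0.010).
#' @return 4-d array `unit x stimulus x repetition x bin` with dimnames, plus
#'   attribute `crop_s`.
#' @export
bin_responses <- function(session, unit_ids = NULL, protocol = "vocal_list",
                          bin_width_s = 0.010) {
  st <- session$stimuli[session$stimuli$protocol == protocol, ]
  if (nrow(st) == 0L) abort(sprintf("no stimuli in protocol '%s'", protocol))
  unit_ids <- sort(unit_ids %||% session$units$unit_id)
  crop <- min(st$duration_s) + 0.300
  breaks <- seq(0, crop, by = bin_width_s)
  n_bins <- length(breaks) - 1L
  reps <- sort(unique(session$spikes$repetition[
    session$spikes$protocol == protocol]))
  arr <- array(
    0L, dim = c(length(unit_ids), nrow(st), length(reps), n_bins),
    dimnames = list(unit = unit_ids, stimulus = st$stimulus_id,
                    repetition = reps, bin = NULL))
  sp <- session$spikes[session$spikes$protocol == protocol &
                         session$spikes$unit_id %in% unit_ids, ]
  sp <- sp[in_window(sp$time_s, 0, breaks[n_bins + 1L]), ]
  if (nrow(sp)) {
    bin_idx <- findInterval(sp$time_s, breaks, rightmost.closed = FALSE)
    tab <- table(factor(sp$unit_id, unit_ids),
                 factor(sp$stimulus_id, st$stimulus_id),
                 factor(sp$repetition, reps),
                 factor(bin_idx, seq_len(n_bins)))
    arr <- array(as.integer(tab), dim = dim(arr), dimnames = dimnames(arr))
  }
  attr(arr, "crop_s") <- crop
  arr
}

#' Sample a pseudopopulation and per-unit left-out test trials
#'
#' Units are drawn without replacement from the pool; `"mixture"` draws RS
#' and Bu units at a configurable prevalence ratio (default 2:1, reflecting
#' the typical preponderance of RS over bursting units). Each unit
#' independently gets one randomly chosen left-out repetition per draw.
#'
#' @param pool Tibble with `unit_id` and `label` columns (pool units should
#'   each be responsive to at least one stimulus).
#' @param n_units Number of units to draw.
#' @param composition `"Bu"`, `"RS"` or `"mixture"`.
#' @param n_reps Repetitions available per stimulus (default 10).
#' @param rs_bu_ratio Length-2 prevalence weights for mixture (default
#'   `c(2, 1)`).
#' @param seed Integer seed.
#' @return List with `unit_id` (sorted draw) and `test_rep` (named integer,
#'   one left-out repetition per unit).
#' @export
sample_pseudopopulation <- function(pool, n_units,
                                    composition = c("mixture", "Bu", "RS"),
                                    n_reps = 10, rs_bu_ratio = c(2, 1),
                                    seed = 1) {
  composition <- match.arg(composition)
  is_bu <- pool$label %in% c("Bu", "Bu1", "Bu2")
  with_seed(seed, {
    ids <- if (composition == "Bu") {
      pool$unit_id[is_bu]
    } else if (composition == "RS") {
      pool$unit_id[pool$label == "RS"]
    } else {
      n_rs <- round(n_units * rs_bu_ratio[1] / sum(rs_bu_ratio))
      n_bu <- n_units - n_rs
      if (n_rs > sum(!is_bu) || n_bu > sum(is_bu)) {
        abort("n_units exceeds pool size for the requested composition")
      }
      c(sample(pool$unit_id[pool$label == "RS"], n_rs),
        sample(pool$unit_id[is_bu], n_bu))
    }
    if (composition != "mixture") {
      if (n_units > length(ids)) abort("n_units exceeds pool size")
      ids <- sample(ids, n_units)
    }
    ids <- sort(ids)
    list(unit_id = ids,
         test_rep = setNames(sample.int(n_reps, length(ids), replace = TRUE),
                             ids))
  })
}

#' Maximum-correlation-coefficient decoding
#'
#' Builds one mean template vector per stimulus from training trials and
#' assigns the test vector to the template with the highest Pearson
#' correlation; ties (and zero-variance test vectors, with a warning) are
#' broken uniformly at random using the supplied seed.
#'
#' @param templates Stimulus x feature matrix of class means.
#' @param test Numeric feature vector.
#' @param seed Seed for tie breaking.
#' @return Decoded stimulus name.
#' @export
mcc_decode <- function(templates, test, seed = 1) {
  if (sd(test) == 0) {
    warn("zero-variance test vector: decoding at chance")
    return(with_seed(seed, sample(rownames(templates), 1)))
  }
  r <- apply(templates, 1, function(tp) {
    if (sd(tp) == 0) return(-Inf)
    cor(tp, test)
  })
  winners <- which(r == max(r))
  if (length(winners) == 1L) {
    names(winners)
  } else {
    with_seed(seed, sample(names(winners), 1))
  }
}

#' Shrinkage-regularized linear discriminant decoding
#'
#' LDA with a uniform class prior; the pooled within-class covariance is
#' shrunk toward its diagonal, `(1 - gamma) * S + gamma * diag(diag(S))`,
#' which keeps the discriminant well conditioned when features outnumber
#' training trials.
#'
#' @param train Trial x feature matrix of training trials.
#' @param train_labels Class label per training trial.
#' @param test Numeric feature vector.
#' @param gamma Shrinkage intensity in `[0, 1]` (default 0.5).
#' @return Decoded class name.
#' @export
lda_decode <- function(train, train_labels, test, gamma = 0.5) {
  classes <- sort(unique(train_labels))
  if (any(table(train_labels) < 2L)) {
    abort("lda needs >= 2 training trials per class")
  }
  mu <- t(vapply(classes, function(cl) {
    colMeans(train[train_labels == cl, , drop = FALSE])
  }, numeric(ncol(train))))
  centered <- train - mu[match(train_labels, classes), , drop = FALSE]
  s <- crossprod(centered) / (nrow(train) - length(classes))
  s <- (1 - gamma) * s + gamma * diag(diag(s), ncol(s))
  diag(s) <- diag(s) + 1e-8 * mean(diag(s))  # numerical floor
  ch <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(ch)) abort("covariance singular even after shrinkage")
  # discriminant: x' S^-1 mu_k - 0.5 mu_k' S^-1 mu_k (uniform prior)
  si_mu <- backsolve(ch, forwardsolve(t(ch), t(mu)))
  scores <- as.numeric(test %*% si_mu) - 0.5 * colSums(t(mu) * si_mu)
  classes[which.max(scores)]
}

#' Pseudopopulation decoding experiment
#'
#' Repeats, `n_samples` times: draw a pseudopopulation, pick one left-out
#' repetition per unit, assemble the test response for every stimulus and the
#' per-unit training templates from the remaining repetitions, optionally
#' collapse the feature tensor (`avg_time`: mean over bins, leaving one rate
#' per unit; `avg_units`: mean over units, leaving the population time
#' course), and decode each stimulus's test trial. Tallies a confusion matrix;
#' accuracy is its diagonal mass fraction.
#'
#' @param session A [spike_session()].
#' @param pool Tibble `unit_id`, `label` of candidate units.
#' @param n_units Pseudopopulation size.
#' @param composition `"mixture"`, `"Bu"` or `"RS"`.
#' @param manipulation `"none"`, `"avg_time"` or `"avg_units"`.
#' @param bin_width_s Time-bin width (default 0.010).
#' @param decoder `"mcc"` or `"lda"`.
#' @param n_samples Pseudopopulation draws (default 50).
#' @param protocol Stimulus protocol (default `"vocal_list"`).
#' @param seed Integer seed.
#' @return List with `confusion` (a `confusion_matrix`), `accuracy`, and the
#'   call settings.
#' @export
decoding_experiment <- function(session, pool, n_units,
                                composition = c("mixture", "Bu", "RS"),
                                manipulation = c("none", "avg_time",
                                                 "avg_units"),
                                bin_width_s = 0.010,
                                decoder = c("mcc", "lda"),
                                n_samples = 50, protocol = "vocal_list",
                                seed = 1) {
  composition <- match.arg(composition)
  manipulation <- match.arg(manipulation)
  decoder <- match.arg(decoder)
  if (nrow(pool) == 0L) abort("empty unit pool")
  arr <- bin_responses(session, unit_ids = pool$unit_id, protocol = protocol,
                       bin_width_s = bin_width_s)
  stims <- dimnames(arr)$stimulus
  n_reps <- dim(arr)[3]
  cm <- matrix(0, length(stims), length(stims),
               dimnames = list(true = stims, decoded = stims))
  featurize <- function(m) {
    # m: unit x bin matrix for one pseudo-trial
    switch(manipulation,
           none = as.numeric(m),
           avg_time = rowMeans(m),
           avg_units = colMeans(m))
  }
  for (s in seq_len(n_samples)) {
    draw <- sample_pseudopopulation(pool, n_units, composition,
                                    n_reps = n_reps,
                                    seed = child_seed(seed, s))
    ui <- match(draw$unit_id, dimnames(arr)$unit)
    test_rep <- draw$test_rep
    for (si in seq_along(stims)) {
      test_m <- vapply(seq_along(ui), function(k) {
        arr[ui[k], si, test_rep[k], ]
      }, numeric(dim(arr)[4]))
      test_vec <- featurize(t(test_m))
      if (decoder == "mcc") {
        templates <- t(vapply(seq_along(stims), function(sj) {
          tm <- vapply(seq_along(ui), function(k) {
            reps_bins <- arr[ui[k], sj, -test_rep[k], , drop = FALSE]
            colMeans(array(reps_bins, dim = dim(reps_bins)[3:4]))
          }, numeric(dim(arr)[4]))
          featurize(t(tm))
        }, numeric(length(test_vec))))
        rownames(templates) <- stims
        decoded <- mcc_decode(templates, test_vec,
                              seed = child_seed(seed, 7777 + s * 100 + si))
      } else {
        train <- list(); tl <- character(0)
        for (sj in seq_along(stims)) {
          for (r in seq_len(n_reps - 1L)) {
            tm <- vapply(seq_along(ui), function(k) {
              reps_avail <- setdiff(seq_len(n_reps), test_rep[k])
              arr[ui[k], sj, reps_avail[r], ]
            }, numeric(dim(arr)[4]))
            train[[length(train) + 1L]] <- featurize(t(tm))
            tl <- c(tl, stims[sj])
          }
        }
        decoded <- lda_decode(do.call(rbind, train), tl, test_vec)
      }
      cm[stims[si], decoded] <- cm[stims[si], decoded] + 1
    }
  }
  list(confusion = structure(cm, class = c("confusion_matrix", "matrix",
                                           "array")),
       accuracy = sum(diag(cm)) / sum(cm),
       n_units = n_units, composition = composition,
       manipulation = manipulation, bin_width_s = bin_width_s,
       decoder = decoder, n_samples = n_samples)
}
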