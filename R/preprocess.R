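#' Zero-phase band-pass filter
#'
#' Spectral (FFT-domain) band-pass: frequency bins outside `[low, high]` are
#' zeroed and the signal reconstructed by the inverse transform. The filter
#' is exactly zero-phase, rejects DC completely, and is exactly idempotent -
#' properties a recursive (e.g. Butterworth) design only approximates,
#' because its transition bands and the slow edge transients of a 1 Hz
#' corner would otherwise bleed through. Used with a 1-35 Hz band to
#' restrict state inference to sub-gamma activity.
#'
#' @param ts a [parcel_ts()].
#' @param low,high band edges in Hz; `0 < low < high < fs/2`.
#' @return a filtered [parcel_ts()] with unchanged segments.
#' @export
bandpass <- function(ts, low, high) {
  if (low <= 0 || high <= low) abort("need 0 < low < high")
  if (high >= ts$fs / 2) abort("high band edge must be below the Nyquist frequency")
  n <- nrow(ts$data)
  # demean (exact DC rejection), then zero-pad to a highly composite length:
  # R's mixed-radix FFT degrades badly when n has large prime factors
  m <- stats::nextn(n, c(2, 3, 5))
  k <- 0:(m - 1)
  f <- pmin(k, m - k) * ts$fs / m # two-sided frequency of each bin
  mask <- f >= low & f <= high
  out <- apply(ts$data, 2, function(x) {
    xp <- c(x - mean(x), numeric(m - n))
    Re(fft(fft(xp) * mask, inverse = TRUE) / m)[seq_len(n)]
  })
  parcel_ts(out, ts$fs, ts$subject_id, ts$segments)
}

#' Extract trial baselines, stripping the first second
#'
#' Restricts a task recording's segment table to the pre-stimulus baseline of
#' each trial, with the first `strip_seconds` removed: the initial part of
#' the inter-trial interval is assumed to carry activity related to the
#' previous trial's button press. Baselines shorter than `strip_seconds` are
#' dropped with a warning.
#'
#' @param ts a [parcel_ts()] from a task session.
#' @param events tibble with `trial_id`, `baseline_onset_s`, `stim_onset_s`
#'   (seconds from recording start).
#' @param strip_seconds seconds removed from the start of each baseline.
#' @return `ts` with `segments` replaced by the usable baseline intervals
#'   (label `"baseline"`, ending exactly at stimulus onset).
#' @export
extract_baselines <- function(ts, events, strip_seconds = 1) {
  if (strip_seconds < 0) abort("strip_seconds must be >= 0")
  start <- round(events$baseline_onset_s * ts$fs) + 1L + round(strip_seconds * ts$fs)
  end <- round(events$stim_onset_s * ts$fs) + 1L
  keep <- start < end
  if (any(!keep)) {
    warn(sprintf("dropping %d baseline(s) shorter than strip_seconds", sum(!keep)))
  }
  segs <- tibble(start = start[keep], end = end[keep], label = "baseline",
                 trial_id = events$trial_id[keep])
  parcel_ts(ts$data, ts$fs, ts$subject_id, segs)
}

#' Standardise per subject and concatenate in time
#'
#' Pools each subject's segment samples, z-scores every parcel with that
#' subject's pooled mean and SD (so within-subject amplitude dynamics are
#' preserved), and stacks all subjects' segments along the time axis. The
#' returned index maps every concatenated sample back to its subject, segment
#' and trial.
#'
#' @param ts_list list of [parcel_ts()] sharing `fs` and parcel count; each
#'   contributes the samples covered by its segment table.
#' @return a [concat_data()].
#' @export
zscore_concatenate <- function(ts_list) {
  fs <- unique(vapply(ts_list, function(t) t$fs, numeric(1)))
  np <- unique(vapply(ts_list, n_parcels, numeric(1)))
  if (length(fs) != 1 || length(np) != 1) {
    abort("all inputs must share the sampling rate and parcel count")
  }
  blocks <- list()
  index <- list()
  seg_counter <- 0L
  for (ts in ts_list) {
    rows <- unlist(lapply(seq_len(nrow(ts$segments)),
                          function(i) segment_rows(ts$segments[i, ])))
    x <- ts$data[rows, , drop = FALSE]
    mu <- colMeans(x)
    sdv <- apply(x, 2, sd)
    if (any(sdv == 0)) {
      abort(sprintf("zero-variance parcel(s) %s for subject %s",
                    paste(which(sdv == 0), collapse = ","), ts$subject_id))
    }
    x <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    blocks[[length(blocks) + 1]] <- x
    lens <- ts$segments$end - ts$segments$start
    index[[length(index) + 1]] <- tibble(
      subject = ts$subject_id,
      segment = rep(seg_counter + seq_along(lens), lens),
      trial_id = rep(ts$segments[["trial_id"]] %||% rep(NA_integer_, length(lens)), lens),
      pos = unlist(lapply(lens, seq_len)),
      rev_pos = unlist(lapply(lens, function(l) rev(seq_len(l)))),
      orig = rows
    )
    seg_counter <- seg_counter + length(lens)
  }
  concat_data(do.call(rbind, blocks), dplyr::bind_rows(index), fs)
}

# stack of lagged cross-covariance matrices for one recording
lagged_cov_stack <- function(x, lags) {
  n <- nrow(x)
  xc <- scale(x, scale = FALSE)
  vapply(lags, function(l) {
    a <- xc[seq_len(n - abs(l)), , drop = FALSE]
    b <- xc[seq_len(n - abs(l)) + abs(l), , drop = FALSE]
    if (l < 0) crossprod(b, a) / (n - abs(l)) else crossprod(a, b) / (n - abs(l))
  }, matrix(0, ncol(x), ncol(x)))
}

flip_stack <- function(stack, flips) {
  for (l in seq_len(dim(stack)[3])) {
    stack[, , l] <- stack[, , l] * tcrossprod(flips)
  }
  stack
}

sign_objective <- function(stacks) {
  S <- length(stacks)
  v <- lapply(stacks, as.vector)
  total <- 0
  for (a in seq_len(S - 1)) {
    for (b in seq.int(a + 1, S)) total <- total + cor(v[[a]], v[[b]])
  }
  total
}

#' Align parcel signs across subjects
#'
#' Beamformed parcel time courses have arbitrary sign per subject and parcel.
#' This routine chooses per-(subject, parcel) sign flips maximising the sum
#' over subject pairs of the Pearson correlation between vectorised lagged
#' cross-covariance stacks (lags matching the embedding window), by greedy
#' single-flip ascent to convergence. The result never scores below the
#' all-`+1` assignment, and is invariant to a global sign inversion of the
#' whole cohort.
#'
#' @param ts_list list of [parcel_ts()] (>= 2 subjects).
#' @param lags integer lags of the covariance stack (default `-7:7`).
#' @param n_restarts greedy restarts from random sign assignments (the
#'   all-`+1` start is always included, so the result never scores below
#'   it); restarts guard against local optima of the flip landscape.
#' @param seed seed for the restart draws.
#' @return list with `flips` (subjects x parcels matrix of +/-1), `objective`
#'   (achieved value), and `flipped` (the sign-corrected recordings).
#' @export
align_signs <- function(ts_list, lags = -7:7, n_restarts = 10, seed = 1) {
  S <- length(ts_list)
  P <- n_parcels(ts_list[[1]])
  if (S < 2) {
    inform("single subject: sign alignment is the identity")
    return(list(flips = matrix(1, S, P), objective = NA_real_, flipped = ts_list))
  }
  base_stacks <- lapply(ts_list, function(t) lagged_cov_stack(t$data, lags))

  greedy <- function(flips) {
    stacks <- lapply(seq_len(S), function(s) flip_stack(base_stacks[[s]], flips[s, ]))
    obj <- sign_objective(stacks)
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (s in seq_len(S)) {
        for (p in seq_len(P)) {
          cand <- flips[s, ]
          cand[p] <- -cand[p]
          trial <- stacks
          trial[[s]] <- flip_stack(base_stacks[[s]], cand)
          val <- sign_objective(trial)
          if (val > obj + 1e-12) {
            flips[s, ] <- cand
            stacks <- trial
            obj <- val
            improved <- TRUE
          }
        }
      }
    }
    list(flips = flips, objective = obj)
  }

  best <- greedy(matrix(1, S, P))
  for (r in seq_len(n_restarts)) {
    start <- with_seed(derive_seed(seed, 71L, r),
                       matrix(sample(c(-1, 1), S * P, replace = TRUE), S, P))
    res <- greedy(start)
    if (res$objective > best$objective) best <- res
  }

  flipped <- lapply(seq_len(S), function(s) {
    t <- ts_list[[s]]
    parcel_ts(sweep(t$data, 2, best$flips[s, ], "*"), t$fs, t$subject_id, t$segments)
  })
  list(flips = best$flips, objective = best$objective, flipped = flipped)
}
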