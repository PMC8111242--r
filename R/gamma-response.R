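#' Sliding-window multitaper time-frequency power
#'
#' Estimates induced power around stimulus onset with the standard
#' high-gamma recipe: a 300 ms window moved in 50 ms steps, 2 Slepian
#' tapers, frequencies 40-100 Hz. Each window is tapered, Fourier
#' transformed, magnitude-squared and averaged over tapers; power is then
#' averaged across the ROI parcels. Windows are centred on their time stamp;
#' a window reaching past the trial's recorded samples is marked missing.
#'
#' @param ts a [parcel_ts()] task recording.
#' @param events tibble with `trial_id`, `baseline_onset_s`, `stim_onset_s`,
#'   `trial_end_s`.
#' @param roi parcel indices averaged (e.g. the cuneus stand-ins).
#' @param window_s,step_s window length and step, seconds.
#' @param n_tapers Slepian tapers (time-bandwidth `(n_tapers + 1)/2`).
#' @param freq_range retained frequencies, Hz.
#' @param times window centres in seconds relative to stimulus onset.
#' @return object of class `tf_rep`: `power` (trial x freq x time), `freqs`,
#'   `times`, `fs`, `normalized = FALSE`.
#' @export
tf_multitaper <- function(ts, events, roi, window_s = 0.3, step_s = 0.05,
                          n_tapers = 2, freq_range = c(40, 100),
                          times = seq(-0.5, 2, by = step_s)) {
  fs <- ts$fs
  if (fs < 2 * freq_range[2]) abort("sampling rate too low for the requested band")
  n_win <- round(window_s * fs)
  half_lo <- floor(n_win / 2)
  tapers <- dpss_tapers(n_win, (n_tapers + 1) / 2, n_tapers)
  freqs_all <- rfft_freqs(n_win, fs)
  fsel <- which(freqs_all >= freq_range[1] & freqs_all <= freq_range[2])
  nf <- length(fsel)
  nt <- length(times)
  n_tr <- nrow(events)
  pow <- array(NA_real_, dim = c(n_tr, nf, nt))

  for (i in seq_len(n_tr)) {
    stim <- round(events$stim_onset_s[i] * fs) + 1L
    lo_bound <- round(events$baseline_onset_s[i] * fs) + 1L
    hi_bound <- min(round(events$trial_end_s[i] * fs) + 1L, nrow(ts$data))
    for (j in seq_len(nt)) {
      start <- stim + round(times[j] * fs) - half_lo
      rows <- start + seq_len(n_win) - 1L
      if (rows[1] < lo_bound || rows[n_win] > hi_bound) next
      seg <- ts$data[rows, roi, drop = FALSE]
      pw <- matrix(0, nf, length(roi))
      for (r in seq_len(n_tapers)) {
        F <- stats::mvfft(seg * tapers[, r])[fsel, , drop = FALSE]
        pw <- pw + Mod(F)^2
      }
      pow[i, , j] <- rowMeans(pw) / n_tapers
    }
  }
  structure(list(power = pow, freqs = freqs_all[fsel], times = times, fs = fs,
                 roi = roi, subject_id = ts$subject_id,
                 trial_id = events$trial_id, normalized = FALSE),
            class = "tf_rep")
}

#' @export
print.tf_rep <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tf_rep>%s %d trials, %d frequencies (%.0f-%.0f Hz), %d time points (%.2f to %.2f s)\n",
              if (x$normalized) " [%-change]" else "", d[1], d[2],
              min(x$freqs), max(x$freqs), d[3], min(x$times), max(x$times)))
  invisible(x)
}

#' Percent-change baseline normalisation
#'
#' Expresses every trial's time-frequency power as percent change relative
#' to that trial's mean power in the pre-stimulus response baseline:
#' `100 * (P(t, f) - B(f)) / B(f)`, with `B(f)` averaged over the window
#' centres falling inside `baseline_window`. Invariant to any global
#' rescaling of the raw signal.
#'
#' @param tf a [tf_multitaper()] result.
#' @param baseline_window `c(lo, hi)` in seconds relative to stimulus onset.
#' @return a normalised `tf_rep`.
#' @export
baseline_normalize <- function(tf, baseline_window = c(-0.5, -0.2)) {
  bsel <- which(tf$times >= baseline_window[1] & tf$times <= baseline_window[2])
  if (!length(bsel)) abort("baseline window contains no time point")
  base <- apply(tf$power[, , bsel, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
  if (any(!is.na(base) & base == 0)) abort("zero baseline power")
  tf$power <- 100 * sweep(sweep(tf$power, c(1, 2), base), c(1, 2), base, "/")
  tf$normalized <- TRUE
  tf$baseline_window <- baseline_window
  tf
}

#' Individual gamma peak frequency
#'
#' Finds the frequency with the largest trial-averaged percent-change power
#' within the search band, averaged over the response window. Ties are
#' broken towards the lower frequency.
#'
#' @param tf a normalised `tf_rep`.
#' @param search_band `c(lo, hi)` Hz, the range of plausible individual
#'   peaks.
#' @param response_window `c(lo, hi)` seconds after stimulus onset.
#' @return peak frequency in Hz (a grid point).
#' @export
find_gamma_peak <- function(tf, search_band = c(42, 74),
                            response_window = c(0.6, 2)) {
  if (!tf$normalized) abort("normalise the TF representation first")
  fsel <- which(tf$freqs >= search_band[1] & tf$freqs <= search_band[2])
  tsel <- which(tf$times >= response_window[1] & tf$times <= response_window[2])
  if (!length(fsel) || !length(tsel)) abort("search band or window outside the grid")
  prof <- apply(tf$power[, fsel, tsel, drop = FALSE], 2, mean, na.rm = TRUE)
  if (all(prof == 0)) abort("flat response: supply the gamma peak manually")
  tf$freqs[fsel[which.max(prof)]]
}

#' Per-trial gamma amplitude
#'
#' Averages percent-change power over the individual gamma band (peak
#' +/- `half_bw`), the response window, and the ROI (already averaged during
#' TF estimation), yielding one amplitude per trial.
#'
#' @param tf a normalised `tf_rep`.
#' @param peak_freq individual peak frequency, Hz.
#' @param half_bw half band width, Hz.
#' @param response_window `c(lo, hi)` seconds after stimulus onset.
#' @return tibble with `trial_id`, `amplitude`, `peak_freq`.
#' @export
trial_amplitude <- function(tf, peak_freq, half_bw = 10,
                            response_window = c(0.6, 2)) {
  if (!tf$normalized) abort("normalise the TF representation first")
  fsel <- which(tf$freqs >= peak_freq - half_bw & tf$freqs <= peak_freq + half_bw)
  tsel <- which(tf$times >= response_window[1] & tf$times <= response_window[2])
  if (!length(fsel) || !length(tsel)) abort("empty averaging set")
  amp <- apply(tf$power[, fsel, tsel, drop = FALSE], 1, mean, na.rm = TRUE)
  tibble(trial_id = tf$trial_id, amplitude = amp, peak_freq = peak_freq)
}

#' Full gamma quantification for one subject
#'
#' Convenience wrapper: TF estimation, percent-change baselining, individual
#' peak detection, per-trial amplitude.
#'
#' @inheritParams tf_multitaper
#' @param search_band,response_window,baseline_window,half_bw see the
#'   underlying functions.
#' @return tibble `trial_id`, `amplitude`, `peak_freq`; the normalised
#'   `tf_rep` is attached as attribute `"tf"`.
#' @export
quantify_gamma <- function(ts, events, roi, search_band = c(42, 74),
                           response_window = c(0.6, 2),
                           baseline_window = c(-0.5, -0.2), half_bw = 10, ...) {
  tf <- tf_multitaper(ts, events, roi, ...)
  tf <- baseline_normalize(tf, baseline_window)
  pk <- find_gamma_peak(tf, search_band, response_window)
  out <- trial_amplitude(tf, pk, half_bw, response_window)
  attr(out, "tf") <- tf
  out
}

#' Plot a trial-averaged time-frequency representation
#'
#' @param tf a `tf_rep` (normalised or raw).
#' @return a ggplot object.
#' @export
plot_tf <- function(tf) {
  m <- apply(tf$power, c(2, 3), mean, na.rm = TRUE)
  df <- tibble(freq = rep(tf$freqs, length(tf$times)),
               time = rep(tf$times, each = length(tf$freqs)),
               power = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq, fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time from stimulus onset (s)", y = "frequency (Hz)",
                  fill = if (tf$normalized) "% change" else "power") +
    ggplot2::theme_minimal()
}
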