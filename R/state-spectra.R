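#' Normalised state weights
#'
#' Converts state posteriors into the weights used by the state-weighted
#' multitaper estimator: each state's posterior time course divided by its
#' time mean, `rho[t, k] = gamma[t, k] * T / sum_t gamma[t, k]`. Every
#' column of the result has time mean exactly 1.
#'
#' @param gamma T x K posterior matrix (or a `tde_hmm`).
#' @return T x K matrix of non-negative weights.
#' @export
compute_rho <- function(gamma) {
  if (inherits(gamma, "tde_hmm")) gamma <- gamma$gamma
  fo <- colMeans(gamma)
  if (any(fo <= 0)) {
    abort(sprintf("state(s) %s have zero total posterior mass",
                  paste(which(fo <= 0), collapse = ",")))
  }
  sweep(gamma, 2, fo, "/")
}

#' Named frequency bands
#'
#' The standard band set (delta 1-3, theta 4-7, alpha 8-12, beta 13-30,
#' gamma 60-90 Hz), or the `"feature"` preset in which delta spans 1-4 Hz
#' (the convention used for regional feature analyses).
#'
#' @param preset `"standard"` or `"feature"`.
#' @return named list of `c(lo, hi)` ranges in Hz.
#' @export
spectral_bands <- function(preset = c("standard", "feature")) {
  preset <- match.arg(preset)
  b <- list(delta = c(1, 3), theta = c(4, 7), alpha = c(8, 12),
            beta = c(13, 30), gamma = c(60, 90))
  if (preset == "feature") b$delta <- c(1, 4)
  b
}

#' State-weighted multitaper spectra
#'
#' Estimates per-state power (and optionally coherence) by weighting
#' sliding-window multitaper cross-spectra with the window-averaged state
#' weights `rho`. With `rho == 1` everywhere (e.g. a single all-ones state
#' column) the estimate reduces exactly to the ordinary multitaper spectrum,
#' and the FO-weighted average of the state spectra reproduces the
#' unweighted spectrum exactly - the per-window weights of the states sum
#' to 1 by construction.
#'
#' Windows are placed within segments only, with the given overlap, and
#' tapered with DPSS (Slepian) sequences.
#'
#' @param x a [concat_data()] or plain matrix (one segment).
#' @param gamma T x K posterior matrix aligned to the samples of `x`.
#' @param window_s window length in seconds.
#' @param overlap fractional window overlap (0 to <1).
#' @param n_tapers number of Slepian tapers (time-bandwidth
#'   `(n_tapers + 1)/2`).
#' @param freq_range frequencies retained, Hz.
#' @param compute_coherence also accumulate cross-spectra and coherence.
#' @param fs sampling rate; taken from `x` when it is a `concat_data`.
#' @return an object of class `state_spectra`: `power` (K x parcels x
#'   freqs), optionally `coherence` (K x parcels x parcels x freqs), `freqs`,
#'   `fo`, and taper parameters.
#' @export
weighted_multitaper <- function(x, gamma, window_s = 2, overlap = 0.5,
                                n_tapers = 3, freq_range = c(1, 45),
                                compute_coherence = FALSE, fs = NULL) {
  if (inherits(x, "concat_data")) {
    dat <- x$data
    fs <- x$fs
    starts <- concat_segment_starts(x)
  } else {
    dat <- as.matrix(x)
    if (is.null(fs)) abort("fs is required for matrix input")
    starts <- 1L
  }
  gamma <- as.matrix(gamma)
  if (nrow(gamma) != nrow(dat)) abort("gamma must align with the data samples")
  n_win <- round(window_s * fs)
  if (n_win < 2) abort("window too short")
  ends <- c(starts[-1] - 1L, nrow(dat))
  if (all(ends - starts + 1L < n_win)) abort("window longer than every segment")
  if (freq_range[2] > fs / 2) abort("freq_range must stay below the Nyquist frequency")

  step <- max(1L, round(n_win * (1 - overlap)))
  freqs_all <- rfft_freqs(n_win, fs)
  fsel <- which(freqs_all >= freq_range[1] & freqs_all <= freq_range[2])
  nf <- length(fsel)
  P <- ncol(dat)
  K <- ncol(gamma)
  tapers <- dpss_tapers(n_win, (n_tapers + 1) / 2, n_tapers)

  rho <- compute_rho(gamma)
  fo <- colMeans(gamma)

  pow_acc <- array(0, dim = c(K, P, nf))
  cross_acc <- if (compute_coherence) array(0i, dim = c(K, P, P, nf))
  n_windows <- 0L

  for (s in seq_along(starts)) {
    seg_len <- ends[s] - starts[s] + 1L
    if (seg_len < n_win) next
    offs <- seq.int(0L, seg_len - n_win, by = step)
    for (o in offs) {
      rows <- starts[s] + o + seq_len(n_win) - 1L
      w_k <- colMeans(rho[rows, , drop = FALSE])
      seg <- dat[rows, , drop = FALSE]
      pw <- matrix(0, nf, P)
      Xs <- vector("list", n_tapers)
      for (r in seq_len(n_tapers)) {
        F <- stats::mvfft(seg * tapers[, r])[fsel, , drop = FALSE]
        Xs[[r]] <- F
        pw <- pw + Mod(F)^2
      }
      pw <- pw / n_tapers
      for (k in seq_len(K)) {
        pow_acc[k, , ] <- pow_acc[k, , ] + w_k[k] * t(pw)
      }
      if (compute_coherence) {
        cw <- array(0i, dim = c(P, P, nf))
        for (r in seq_len(n_tapers)) {
          F <- Xs[[r]]
          for (p in seq_len(P)) {
            cw[p, , ] <- cw[p, , ] + t(Conj(F[, p]) * F)
          }
        }
        cw <- cw / n_tapers
        for (k in seq_len(K)) {
          cross_acc[k, , , ] <- cross_acc[k, , , ] + w_k[k] * cw
        }
      }
      n_windows <- n_windows + 1L
    }
  }
  if (n_windows == 0) abort("no window fits inside any segment")
  pow_acc <- pow_acc / n_windows

  coh <- NULL
  if (compute_coherence) {
    cross_acc <- cross_acc / n_windows
    coh <- array(0, dim = c(K, P, P, nf))
    for (k in seq_len(K)) {
      auto <- pow_acc[k, , , drop = FALSE]
      for (f in seq_len(nf)) {
        denom <- sqrt(outer(pow_acc[k, , f], pow_acc[k, , f]))
        coh[k, , , f] <- Mod(cross_acc[k, , , f])^2 / denom^2
      }
    }
  }

  structure(list(power = pow_acc, coherence = coh, freqs = freqs_all[fsel],
                 fo = fo, fs = fs, window_s = window_s, overlap = overlap,
                 n_tapers = n_tapers, n_windows = n_windows),
            class = "state_spectra")
}

#' @export
print.state_spectra <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<state_spectra> K = %d, %d parcels, %d frequencies (%.1f-%.1f Hz), %d windows, %d tapers%s\n",
              d[1], d[2], d[3], min(x$freqs), max(x$freqs), x$n_windows,
              x$n_tapers, if (is.null(x$coherence)) "" else ", with coherence"))
  invisible(x)
}

#' Band-limited state power maps
#'
#' Averages state spectra within named frequency bands and expresses each
#' state's band power both absolutely and relative to the mean over states:
#' `relative = (power - mean_states) / mean_states`, so relative values
#' average to zero across states for every parcel-band.
#'
#' @param spectra a [weighted_multitaper()] result.
#' @param bands named list of `c(lo, hi)` Hz ranges; see [spectral_bands()].
#' @return tibble with columns `state`, `parcel`, `band`, `power`,
#'   `relative`.
#' @export
band_maps <- function(spectra, bands = spectral_bands()) {
  K <- dim(spectra$power)[1]
  P <- dim(spectra$power)[2]
  out <- list()
  for (b in names(bands)) {
    sel <- which(spectra$freqs >= bands[[b]][1] & spectra$freqs <= bands[[b]][2])
    if (!length(sel)) abort(sprintf("band '%s' contains no frequency grid point", b))
    bp <- apply(spectra$power[, , sel, drop = FALSE], c(1, 2), mean)
    mn <- colMeans(bp)
    rel <- sweep(sweep(bp, 2, mn), 2, mn, "/")
    out[[b]] <- tibble(state = rep(seq_len(K), P),
                       parcel = rep(seq_len(P), each = K),
                       band = b, power = as.vector(bp), relative = as.vector(rel))
  }
  dplyr::bind_rows(out)
}

#' Mean coupling with all other parcels
#'
#' Per state, parcel and band: the average coherence between that parcel and
#' every other parcel, averaged over the band's frequencies.
#'
#' @param spectra a [weighted_multitaper()] result with coherence.
#' @param bands named list of Hz ranges.
#' @return tibble with columns `state`, `parcel`, `band`, `coupling`.
#' @export
mean_coupling <- function(spectra, bands = spectral_bands()) {
  if (is.null(spectra$coherence)) abort("spectra were computed without coherence")
  K <- dim(spectra$coherence)[1]
  P <- dim(spectra$coherence)[2]
  out <- list()
  for (b in names(bands)) {
    sel <- which(spectra$freqs >= bands[[b]][1] & spectra$freqs <= bands[[b]][2])
    if (!length(sel)) abort(sprintf("band '%s' contains no frequency grid point", b))
    for (k in seq_len(K)) {
      cmat <- apply(spectra$coherence[k, , , sel, drop = FALSE], c(2, 3), mean)
      cpl <- (rowSums(cmat) - diag(cmat)) / (P - 1)
      out[[length(out) + 1]] <- tibble(state = k, parcel = seq_len(P),
                                       band = b, coupling = cpl)
    }
  }
  dplyr::bind_rows(out)
}

#' Plot band-limited state power maps
#'
#' Tile map of relative band power per state, parcel and band - the tabular
#' analogue of state power topographies.
#'
#' @param maps a tibble from [band_maps()].
#' @return a ggplot object.
#' @export
plot_band_maps <- function(maps) {
  ggplot2::ggplot(maps, ggplot2::aes(x = .data$parcel, y = factor(.data$state),
                                     fill = .data$relative)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~band, ncol = 1) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b", mid = "white") +
    ggplot2::labs(x = "parcel", y = "state", fill = "relative\npower") +
    ggplot2::theme_minimal()
}
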