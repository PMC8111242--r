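#' Permutation test for a Spearman correlation
#'
#' Observed Spearman correlation between two subject-level vectors, with a
#' two-sided permutation p-value obtained by randomly permuting `y`:
#' `p = (1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)`.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param n_perm number of random permutations.
#' @param seed integer seed (optional).
#' @return tibble with `r`, `p`, `n`, `n_perm`.
#' @export
spearman_permutation <- function(x, y, n_perm = 10000, seed = NULL) {
  n <- length(x)
  if (length(y) != n || n < 3) abort("x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector")
  rx <- rank(x); ry <- rank(y)
  r_obs <- cor(rx, ry)
  with_seed(seed, {
    perms <- vapply(seq_len(n_perm), function(i) sample(ry), numeric(n))
    r_perm <- as.vector(cor(rx, perms))
    p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (1 + n_perm)
    tibble(r = r_obs, p = p, n = n, n_perm = n_perm)
  })
}

#' Per-trial posteriors from a fitted model
#'
#' Splits a concatenated posterior back into per-trial matrices using the
#' sample index, keeping only baseline segments attached to a trial.
#'
#' @param hmm a `tde_hmm` fitted on a [zscore_concatenate()] result whose
#'   index carries `subject` and `trial_id`.
#' @return list with `mats` (per-trial time x K posterior matrices, time
#'   ascending to the segment end = stimulus onset) and `meta` (tibble
#'   `subject`, `trial_id`).
#' @export
trial_posteriors <- function(hmm) {
  if (is.null(hmm$index)) abort("model was not fitted on indexed concatenated data")
  idx <- hmm$index
  keep <- !is.na(idx$trial_id)
  key <- paste(idx$subject[keep], idx$segment[keep])
  rows <- split(which(keep), factor(key, levels = unique(key)))
  mats <- lapply(rows, function(r) hmm$gamma[r, , drop = FALSE])
  meta <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble(subject = idx$subject[r[1]], trial_id = idx$trial_id[r[1]])
  }))
  list(mats = unname(mats), meta = meta)
}

#' Pre-stimulus state weights
#'
#' For every trial, the mean posterior probability of each state over the
#' immediate pre-stimulus window (default the last 106 ms before stimulus
#' onset - a duration of the order of one mean state lifetime; configure to
#' taste). Since each baseline segment ends at stimulus onset, the window is
#' the segment's last `floor(window_s * fs)` samples. Trials with shorter
#' baselines are dropped with a warning. Rows sum to 1.
#'
#' @param hmm a `tde_hmm` fitted on indexed concatenated baselines.
#' @param window_s window length before stimulus onset, seconds.
#' @return tibble `subject`, `trial_id`, `state`, `weight`.
#' @export
prestim_weights <- function(hmm, window_s = 0.106) {
  tp <- trial_posteriors(hmm)
  fs <- hmm$fs %||% abort("fitted object carries no sampling rate")
  n_w <- floor(window_s * fs)
  K <- ncol(hmm$gamma)
  keep <- vapply(tp$mats, nrow, integer(1)) >= n_w
  if (any(!keep)) {
    warn(sprintf("dropping %d trial(s) without full pre-stimulus coverage", sum(!keep)))
  }
  out <- lapply(which(keep), function(i) {
    m <- tp$mats[[i]]
    w <- colMeans(m[nrow(m) - n_w + seq_len(n_w), , drop = FALSE])
    tibble(subject = tp$meta$subject[i], trial_id = tp$meta$trial_id[i],
           state = seq_len(K), weight = w)
  })
  dplyr::bind_rows(out)
}

#' Soft-assigned trial averages per state
#'
#' Weighted mean gamma amplitude per subject and state, with the
#' pre-stimulus state probabilities as trial weights:
#' `sum_t w[t, k] a[t] / sum_t w[t, k]`. A state whose total weight is zero
#' for a subject yields a missing value.
#'
#' @param amplitudes tibble `subject`, `trial_id`, `amplitude`.
#' @param weights tibble `subject`, `trial_id`, `state`, `weight` from
#'   [prestim_weights()].
#' @return tibble `subject`, `state`, `weighted_mean`.
#' @export
weighted_trial_average <- function(amplitudes, weights) {
  joined <- dplyr::inner_join(weights, amplitudes, by = c("subject", "trial_id"))
  out <- joined |>
    dplyr::group_by(.data$subject, .data$state) |>
    dplyr::summarise(weighted_mean = {
      tw <- sum(.data$weight)
      if (tw > 0) sum(.data$weight * .data$amplitude) / tw else NA_real_
    }, .groups = "drop")
  if (any(is.na(out$weighted_mean))) warn("zero total weight: value(s) marked missing")
  out
}

#' Friedman omnibus test with post-hoc pairwise comparisons
#'
#' Tests whether the per-state weighted trial averages differ consistently
#' across subjects (Friedman test over K related samples), followed by all
#' pairwise comparisons with Bonferroni correction. The post-hoc test
#' defaults to the paired signed-rank variant - the compared values are
#' within-subject - with the unpaired rank-sum variant available.
#'
#' @param weighted_means tibble `subject`, `state`, `weighted_mean` (or a
#'   subjects x K matrix).
#' @param posthoc `"signed_rank"` (paired) or `"rank_sum"` (unpaired).
#' @return object of class `within_subject_result`: `friedman_p`,
#'   `friedman_chisq`, `pairwise_p` (K x K, Bonferroni-corrected),
#'   `weighted_means` (subjects x K), `posthoc`.
#' @export
friedman_posthoc <- function(weighted_means, posthoc = c("signed_rank", "rank_sum")) {
  posthoc <- match.arg(posthoc)
  if (is.data.frame(weighted_means)) {
    wide <- tidyr::pivot_wider(weighted_means, names_from = "state",
                               values_from = "weighted_mean")
    M <- as.matrix(wide[, -1, drop = FALSE])
    rownames(M) <- wide$subject
  } else {
    M <- as.matrix(weighted_means)
  }
  if (ncol(M) < 2) abort("need at least 2 states")
  drop <- apply(M, 1, function(r) any(!is.finite(r)))
  if (any(drop)) {
    inform(sprintf("excluding %d subject(s) with missing state values", sum(drop)))
    M <- M[!drop, , drop = FALSE]
  }
  if (nrow(M) < 3) abort("need at least 3 complete subjects")
  fr <- stats::friedman.test(M)
  # fully tied rows give a 0/0 statistic; no evidence against the null
  if (is.nan(fr$p.value)) {
    fr$p.value <- 1
    fr$statistic[] <- 0
  }
  K <- ncol(M)
  n_pairs <- K * (K - 1) / 2
  pw <- matrix(NA_real_, K, K)
  for (i in seq_len(K - 1)) {
    for (j in seq.int(i + 1, K)) {
      p <- if (posthoc == "signed_rank") {
        stats::wilcox.test(M[, i], M[, j], paired = TRUE, exact = FALSE)$p.value
      } else {
        stats::wilcox.test(M[, i], M[, j], exact = FALSE)$p.value
      }
      pw[i, j] <- pw[j, i] <- min(1, p * n_pairs)
    }
  }
  structure(list(friedman_p = fr$p.value, friedman_chisq = unname(fr$statistic),
                 pairwise_p = pw, weighted_means = M, posthoc = posthoc),
            class = "within_subject_result")
}

#' @export
print.within_subject_result <- function(x, ...) {
  cat(sprintf("<within_subject_result> Friedman chi^2 = %.2f, p = %.4g (%d subjects, %d states); post-hoc: %s\n",
              x$friedman_chisq, x$friedman_p, nrow(x$weighted_means),
              ncol(x$weighted_means), x$posthoc))
  invisible(x)
}

#' @export
glance.within_subject_result <- function(x, ...) {
  tibble(friedman_chisq = x$friedman_chisq, friedman_p = x$friedman_p,
         n_subjects = nrow(x$weighted_means), K = ncol(x$weighted_means))
}

#' @export
tidy.within_subject_result <- function(x, ...) {
  K <- ncol(x$pairwise_p)
  idx <- which(upper.tri(x$pairwise_p), arr.ind = TRUE)
  tibble(state_1 = idx[, 1], state_2 = idx[, 2],
         p_corrected = x$pairwise_p[idx])
}

#' Quantile pseudo-state assignment
#'
#' Bins trials by a pre-stimulus scalar (typically band power) into
#' `n_bins` quantile groups: a trial lands in bin 4 of 4 if its value falls
#' in the top quarter of the observed values. Ties are resolved
#' deterministically by minimum rank, so tied trials share the bin of the
#' lowest tied rank; fully degenerate input puts every trial in bin 1 with a
#' warning.
#'
#' @param power per-trial scalar values.
#' @param n_bins number of bins.
#' @return integer bin labels in `1..n_bins`.
#' @export
pseudo_state_assign <- function(power, n_bins = 4) {
  n <- length(power)
  if (n < n_bins) abort("need at least n_bins trials")
  bins <- ceiling(rank(power, ties.method = "min") * n_bins / n)
  if (length(unique(bins)) < n_bins) {
    warn("ties leave some pseudo-states empty")
  }
  as.integer(bins)
}

#' Pre-stimulus band power per trial
#'
#' Mean Hilbert-envelope amplitude of band-limited activity in the selected
#' parcels over the immediate pre-stimulus window, the univariate control
#' quantity behind pseudo-states.
#'
#' @param ts a [parcel_ts()] task recording.
#' @param events trial event table.
#' @param band `c(lo, hi)` Hz.
#' @param parcels parcel indices averaged.
#' @param window_s window length before stimulus onset, seconds.
#' @return tibble `trial_id`, `power`.
#' @export
prestim_band_power <- function(ts, events, band, parcels, window_s = 0.106) {
  filt <- bandpass(ts, band[1], band[2])
  env <- hilbert_envelope(filt$data[, parcels, drop = FALSE])
  n_w <- floor(window_s * ts$fs)
  stim <- round(events$stim_onset_s * ts$fs) + 1L
  p <- vapply(stim, function(s) mean(env[s - n_w + seq_len(n_w) - 1L, ]), numeric(1))
  tibble(trial_id = events$trial_id, power = p)
}

#' Between- vs within-subject effect comparison
#'
#' Reduces the trial x state FO matrix to its first principal component
#' (sign fixed so the dominant loading is positive), splits both the PC
#' score and the gamma amplitude into subject means and within-subject
#' residuals, and computes the between-subject Spearman correlation (over
#' subject means) and the within-subject correlation (over residuals). The
#' variability of each effect is assessed by resampling subjects with
#' replacement `n_boot` times; effects are compared by the fraction of
#' bootstrap samples in which one absolute correlation exceeds the other.
#' Additional subject-level predictors (e.g. rest-session FO) can be carried
#' through the same bootstrap as extra between-subject effects.
#'
#' @param trial_fo trials x K matrix of per-trial fractional occupancies.
#' @param amplitude per-trial gamma amplitudes.
#' @param subject subject id per trial.
#' @param n_boot bootstrap samples.
#' @param seed integer seed (optional).
#' @param extra_between named list of subject-level vectors (ordered by
#'   `sort(unique(subject))`) to correlate with subject mean amplitude.
#' @return object of class `effect_comparison`: `observed` (tibble `effect`,
#'   `r`, `r_abs`), `boot` (n_boot x effects matrix of absolute
#'   correlations), `pairwise` (fraction matrix `P(|r_row| > |r_col|)`),
#'   `pc_loading`, `n_redraws`.
#' @export
effect_size_comparison <- function(trial_fo, amplitude, subject, n_boot = 1000,
                                   seed = NULL, extra_between = NULL) {
  trial_fo <- as.matrix(trial_fo)
  subject <- as.vector(subject)
  stopifnot(nrow(trial_fo) == length(amplitude), length(subject) == length(amplitude))
  subj_levels <- sort(unique(subject))
  if (length(subj_levels) < 2) abort("need at least 2 subjects")
  if (any(table(subject) < 2)) abort("every subject needs at least 2 trials")

  pc <- stats::prcomp(trial_fo, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  score <- as.vector(scale(trial_fo, center = TRUE, scale = FALSE) %*% v)

  ms <- tapply(score, subject, mean)[as.character(subj_levels)]
  ma <- tapply(amplitude, subject, mean)[as.character(subj_levels)]
  res_s <- score - ms[match(subject, subj_levels)]
  res_a <- amplitude - ma[match(subject, subj_levels)]

  spearman <- function(a, b) cor(a, b, method = "spearman")
  effects <- c(
    list(between = spearman(ms, ma), within = spearman(res_s, res_a)),
    lapply(extra_between %||% list(), function(x) spearman(x, ma))
  )
  n_eff <- length(effects)
  by_subj <- split(seq_along(subject), subject)[as.character(subj_levels)]

  boot <- matrix(NA_real_, n_boot, n_eff,
                 dimnames = list(NULL, names(effects)))
  n_redraws <- 0L
  with_seed(seed, {
    S <- length(subj_levels)
    for (b in seq_len(n_boot)) {
      repeat {
        draw <- sample.int(S, S, replace = TRUE)
        if (length(unique(draw)) >= 2) break
        n_redraws <- n_redraws + 1L
      }
      rows <- unlist(by_subj[draw])
      vals <- c(
        between = spearman(ms[draw], ma[draw]),
        within = spearman(res_s[rows], res_a[rows])
      )
      for (nm in names(extra_between %||% list())) {
        vals[nm] <- spearman(extra_between[[nm]][draw], ma[draw])
      }
      boot[b, ] <- abs(vals)
    }
  })

  pairwise <- matrix(NA_real_, n_eff, n_eff,
                     dimnames = list(names(effects), names(effects)))
  for (i in seq_len(n_eff)) {
    for (j in seq_len(n_eff)) {
      if (i != j) pairwise[i, j] <- mean(boot[, i] > boot[, j])
    }
  }

  structure(list(
    observed = tibble(effect = names(effects),
                      r = unname(unlist(effects)),
                      r_abs = abs(unname(unlist(effects)))),
    boot = boot, pairwise = pairwise, pc_loading = v, n_redraws = n_redraws
  ), class = "effect_comparison")
}

#' @export
print.effect_comparison <- function(x, ...) {
  cat("<effect_comparison> observed correlations:\n")
  print(x$observed)
  cat(sprintf("bootstrap: %d samples; P(|between| > |within|) = %.3f\n",
              nrow(x$boot), x$pairwise["between", "within"]))
  invisible(x)
}

#' @export
tidy.effect_comparison <- function(x, ...) {
  qs <- apply(x$boot, 2, stats::quantile, probs = c(0.25, 0.5, 0.75))
  dplyr::mutate(x$observed,
                boot_q25 = qs[1, .data$effect], boot_median = qs[2, .data$effect],
                boot_q75 = qs[3, .data$effect])
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.effect_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object$boot), dplyr::everything(),
                            names_to = "effect", values_to = "r_abs")
  df$effect <- factor(df$effect, levels = colnames(object$boot))
  ggplot2::ggplot(df, ggplot2::aes(.data$effect, .data$r_abs)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::labs(x = NULL, y = "|Spearman correlation| (bootstrap)") +
    ggplot2::theme_minimal()
}
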