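#' End-to-end cohort analysis
#'
#' Runs the full pipeline on a (synthetic or synthetic-format) cohort:
#'
#' 1. band-pass each task recording to the state-inference band (1-35 Hz),
#'    extract trial baselines with the first second stripped, z-score per
#'    subject and concatenate;
#' 2. fit the TDE-HMM on the concatenated baselines;
#' 3. quantify per-trial induced gamma amplitude on the raw (unfiltered)
#'    recordings;
#' 4. between-subject analysis: permutation Spearman correlation between
#'    each state's mean posterior probability and the subject's
#'    trial-averaged gamma amplitude;
#' 5. within-subject analysis: pre-stimulus state weights, soft-assigned
#'    weighted trial averages, Friedman omnibus and post-hoc pairwise tests;
#' 6. effect-size comparison: PC1 of the trial FO matrix, subject-level
#'    bootstrap of between- and within-subject correlations.
#'
#' When the cohort carries ground truth, decoded states are aligned to the
#' planted labels by the exhaustive best-agreement permutation so results
#' can be read out for the planted enhancing state.
#'
#' @param cohort a `sim_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param hmm an [hmm_config()].
#' @param band state-inference band, Hz.
#' @param strip_seconds seconds removed from the start of each baseline.
#' @param n_perm permutations for the between-subject tests.
#' @param n_boot bootstrap samples for the effect comparison.
#' @param prestim_window_s pre-stimulus window for trial weights, seconds.
#' @param seed master seed for the stochastic test machinery (permutations,
#'   bootstrap); defaults to the cohort's own seed.
#' @return an object of class `cohort_analysis`; see Details of the
#'   individual components.
#' @export
analyze_cohort <- function(cohort, hmm = hmm_config(), band = c(1, 35),
                           strip_seconds = 1, n_perm = 1000, n_boot = 1000,
                           prestim_window_s = 0.106, seed = NULL) {
  cfg <- cohort$config
  seed <- seed %||% cfg$seed

  baselines <- lapply(cohort$subjects, function(s) {
    filt <- bandpass(s$task$ts, band[1], band[2])
    extract_baselines(filt, s$task$events, strip_seconds)
  })
  concat <- zscore_concatenate(baselines)
  fit <- fit_hmm(concat, hmm)
  K <- hmm$K

  amplitudes <- dplyr::bind_rows(lapply(cohort$subjects, function(s) {
    dplyr::mutate(
      quantify_gamma(s$task$ts, s$task$events, cfg$roi_parcels),
      subject = s$id, .before = 1
    )
  }))

  subject_fo <- fractional_occupancy(fit$gamma, groups = concat$index$subject)
  subject_fo$subject <- as.integer(subject_fo$group)
  subject_fo$group <- NULL
  subj_amp <- amplitudes |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(mean_amplitude = mean(.data$amplitude), .groups = "drop")

  subj_amp <- dplyr::arrange(subj_amp, .data$subject)
  between <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
    sf_k <- dplyr::arrange(subject_fo[subject_fo$state == k, ], .data$subject)
    fo_k <- sf_k$fo
    dplyr::mutate(
      spearman_permutation(fo_k, subj_amp$mean_amplitude, n_perm,
                           seed = derive_seed(seed, 41L, k)),
      state = k, .before = 1
    )
  }))

  weights <- prestim_weights(fit, prestim_window_s)
  weighted_means <- weighted_trial_average(
    amplitudes[, c("subject", "trial_id", "amplitude")], weights
  )
  within <- friedman_posthoc(weighted_means)

  tp <- trial_posteriors(fit)
  trial_fo <- t(vapply(tp$mats, colMeans, numeric(K)))
  trial_tab <- dplyr::inner_join(tp$meta, amplitudes,
                                 by = c("subject", "trial_id"))
  effects <- effect_size_comparison(
    trial_fo[match(paste(trial_tab$subject, trial_tab$trial_id),
                   paste(tp$meta$subject, tp$meta$trial_id)), , drop = FALSE],
    trial_tab$amplitude, trial_tab$subject,
    n_boot = n_boot, seed = derive_seed(seed, 42L)
  )

  state_map <- NULL
  if (!is.null(cohort$subjects[[1]]$task$truth$states)) {
    true_lab <- integer(nrow(concat$index))
    for (s in cohort$subjects) {
      rows <- which(concat$index$subject == s$id)
      true_lab[rows] <- s$task$truth$states[concat$index$orig[rows]]
    }
    bp <- best_label_permutation(true_lab[fit$valid], fit$path[fit$valid],
                                 max(K, cfg$K_true))
    state_map <- list(perm = bp$perm, agreement = bp$agreement)
  }

  structure(list(
    concat = concat, hmm = fit, amplitudes = amplitudes,
    subject_fo = subject_fo, subject_amplitude = subj_amp,
    between = between, weights = weights, weighted_means = weighted_means,
    within = within, trial_fo = trial_fo, effects = effects,
    state_map = state_map, config = cfg
  ), class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>\n")
  print(glance(x$hmm))
  cat("\nBetween-subject permutation Spearman (state FO vs mean gamma amplitude):\n")
  print(x$between)
  cat("\n")
  print(x$within)
  cat("\n")
  print(x$effects)
  if (!is.null(x$state_map)) {
    cat(sprintf("\ndecoded-vs-planted label agreement: %.2f (HMM state of planted state k: %s)\n",
                x$state_map$agreement,
                paste(hmm_state_for_true(x), collapse = ",")))
  }
  invisible(x)
}

# HMM label corresponding to each planted label (inverse of state_map$perm):
# state_map$perm[j] is the true label matched to HMM label j.
hmm_state_for_true <- function(analysis) {
  order(analysis$state_map$perm)
}

#' Results for the planted enhancing state
#'
#' Convenience accessor for ground-truth cohorts: maps the planted
#' gamma-enhancing state to its decoded HMM label and returns the
#' between-subject correlation for that state, the Friedman p, whether the
#' enhancing state has the largest weighted-mean amplitude, and the
#' bootstrap between-vs-within ordering.
#'
#' @param analysis a [analyze_cohort()] result on a cohort with ground
#'   truth.
#' @return one-row tibble.
#' @export
enhancing_state_summary <- function(analysis) {
  if (is.null(analysis$state_map)) abort("cohort carries no ground truth")
  enh_true <- analysis$config$gamma_spec$enhancing_state
  enh_hmm <- hmm_state_for_true(analysis)[enh_true]
  btw <- analysis$between[analysis$between$state == enh_hmm, ]
  wm <- analysis$weighted_means |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(m = mean(.data$weighted_mean, na.rm = TRUE), .groups = "drop")
  tibble(
    enhancing_hmm_state = enh_hmm,
    label_agreement = analysis$state_map$agreement,
    between_r = btw$r, between_p = btw$p,
    friedman_p = analysis$within$friedman_p,
    enhancing_is_largest = wm$state[which.max(wm$m)] == enh_hmm,
    frac_between_gt_within = analysis$effects$pairwise["between", "within"]
  )
}
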