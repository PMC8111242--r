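#' Region layout for synthetic parcellations
#'
#' Synthetic cohorts use a fixed, index-based stand-in for a cortical
#' parcellation: the first 30% of parcels are "frontal", the next 30%
#' "central", the next 20% "parietal" and the final 20% "occipital". The last
#' two parcels play the role of the bilateral cuneus, the region where visual
#' gamma responses are strongest.
#'
#' @param n_parcels total number of parcels.
#' @return named list of integer index vectors, including `cuneus`.
#' @export
parcel_regions <- function(n_parcels) {
  stopifnot(n_parcels >= 5)
  cuts <- round(n_parcels * c(0.3, 0.6, 0.8))
  list(
    frontal   = seq_len(cuts[1]),
    central   = seq.int(cuts[1] + 1, cuts[2]),
    parietal  = seq.int(cuts[2] + 1, cuts[3]),
    occipital = seq.int(cuts[3] + 1, n_parcels),
    cuneus    = c(n_parcels - 1L, n_parcels)
  )
}

#' Specification of one synthetic brain state
#'
#' A state is a set of narrow-band oscillators, each active on a subset of
#' parcels while the state is visited, on top of white observation noise.
#' Oscillators are realised as band-pass filtered white noise scaled to the
#' requested amplitude (in units of the noise SD), which gives controllable
#' band power without phase bookkeeping.
#'
#' @param state_id integer state label.
#' @param oscillators list of oscillators, each a list with `parcels`
#'   (integer indices), `freq` (centre frequency, Hz, within the 1-35 Hz
#'   analysis band), `amplitude` (SD of the oscillation relative to the noise
#'   SD) and `bandwidth` (full width of the pass band, Hz).
#' @param noise_sd SD of the white observation noise while this state is
#'   active.
#' @return an object of class `state_spec`.
#' @export
state_spec <- function(state_id, oscillators, noise_sd = 1) {
  for (o in oscillators) {
    stopifnot(length(o$parcels) >= 1, is.finite(o$amplitude), o$amplitude >= 0,
              o$freq >= 1, o$freq <= 35, o$bandwidth > 0)
  }
  structure(list(state_id = as.integer(state_id), oscillators = oscillators,
                 noise_sd = noise_sd), class = "state_spec")
}

#' Canonical 4-state topography set
#'
#' Builds the default planted states used by [cohort_config()]. The design
#' mirrors the qualitative structure of empirical sub-35 Hz network states:
#' state 1 (the "gamma-enhancing" analogue) carries strong centro-parietal
#' delta and an occipital alpha deficit; state 2 strong occipital alpha;
#' state 3 frontal theta; state 4 central beta. For `K != 4` a generic set of
#' spectrally separated states on round-robin parcel blocks is returned.
#'
#' @param n_parcels number of parcels.
#' @param K number of states.
#' @return list of `K` [state_spec()] objects.
#' @export
default_state_specs <- function(n_parcels, K = 4) {
  reg <- parcel_regions(n_parcels)
  osc <- function(parcels, freq, amplitude, bandwidth = 2) {
    list(parcels = parcels, freq = freq, amplitude = amplitude, bandwidth = bandwidth)
  }
  if (K == 4) {
    list(
      state_spec(1, list(osc(c(reg$central, reg$parietal), 2.5, 1.6, 1.5),
                         osc(reg$occipital, 10, 0.4))),
      state_spec(2, list(osc(reg$occipital, 10, 1.8),
                         osc(reg$central, 20, 0.8, 4))),
      state_spec(3, list(osc(reg$frontal, 5.5, 1.5),
                         osc(reg$occipital, 10, 1.0))),
      state_spec(4, list(osc(c(reg$central, reg$frontal), 25, 1.6, 5),
                         osc(reg$occipital, 10, 1.0)))
    )
  } else {
    freqs <- seq(2.5, 28, length.out = K)
    blocks <- split(seq_len(n_parcels), rep_len(seq_len(K), n_parcels))
    lapply(seq_len(K), function(k) {
      state_spec(k, list(osc(blocks[[k]], freqs[k], 1.6)))
    })
  }
}

#' Configuration of a synthetic cohort
#'
#' Collects every knob of the generative model: cohort size, Markov state
#' dynamics and their between-subject variability, trial structure, and the
#' state-coupled gamma-burst model. Defaults reproduce the study conditions
#' the pipeline targets: 15 subjects, 50 parcels at 250 Hz, K = 4 states with
#' approximately 100 ms lifetimes, 2-4 s pre-stimulus baselines, subject
#' gamma peaks uniform in 42-74 Hz, and bursts confined to 0.6-2.0 s after
#' stimulus onset in the cuneus stand-in parcels.
#'
#' @param n_subjects,n_parcels,fs,K_true cohort dimensions.
#' @param transition_base K x K row-stochastic base transition matrix
#'   (default: 0.96 self-transition, i.e. 100 ms mean lifetime at 250 Hz).
#' @param subject_fo_jitter Dirichlet concentration for per-subject
#'   perturbation of `transition_base` rows; larger = less between-subject
#'   occupancy variation; `Inf` disables jitter.
#' @param n_trials trials per subject.
#' @param baseline_range,post_range uniform ranges (s) for the pre-stimulus
#'   baseline and the post-stimulus trial duration.
#' @param rest_duration_s duration of each rest session (s); `0` disables
#'   rest sessions.
#' @param n_rest_sessions rest sessions per subject (pre/post task).
#' @param state_specs list of [state_spec()]; default
#'   [default_state_specs()].
#' @param gamma_spec list: `peak_freq_range`, `burst_onset`, `burst_window`
#'   (s after stimulus onset), `base_amplitude`, `coupling_between` (slope of
#'   subject burst amplitude on subject enhancing-state FO),
#'   `coupling_within` (amplitude increment when the enhancing state is
#'   active at stimulus onset), `subject_sd`, `trial_sd` (noise SDs), and
#'   `enhancing_state`.
#' @param roi_parcels indices of the cuneus stand-ins carrying the bursts.
#' @param seed master seed; all sub-streams derive from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 15, n_parcels = 50, fs = 250, K_true = 4,
                          transition_base = NULL, subject_fo_jitter = 150,
                          n_trials = 60, baseline_range = c(2, 4),
                          post_range = c(3, 5), rest_duration_s = 300,
                          n_rest_sessions = 2, state_specs = NULL,
                          gamma_spec = list(), roi_parcels = NULL, seed = 1) {
  if (is.null(transition_base)) {
    transition_base <- matrix(0.04 / (K_true - 1), K_true, K_true)
    diag(transition_base) <- 0.96
  }
  if (nrow(transition_base) != K_true || ncol(transition_base) != K_true ||
      any(abs(rowSums(transition_base) - 1) > 1e-8) || any(transition_base < 0)) {
    abort("transition_base must be a row-stochastic K_true x K_true matrix")
  }
  if (baseline_range[1] < 1) {
    abort("baseline_range[1] must be >= 1 s (the stripped first second must leave data)")
  }
  gs <- utils::modifyList(list(
    peak_freq_range = c(42, 74), burst_onset = 0.6, burst_window = 1.4,
    base_amplitude = 1, coupling_between = 3, coupling_within = 0.4,
    subject_sd = 0.05, trial_sd = 0.15, enhancing_state = 1L
  ), gamma_spec)
  stopifnot(is.finite(gs$coupling_between), is.finite(gs$coupling_within))
  if (gs$burst_onset + gs$burst_window > post_range[1]) {
    abort("gamma burst window must fit inside the shortest trial")
  }
  if (is.null(state_specs)) state_specs <- default_state_specs(n_parcels, K_true)
  if (length(state_specs) != K_true) abort("need one state_spec per state")
  if (is.null(roi_parcels)) roi_parcels <- parcel_regions(n_parcels)$cuneus
  structure(list(
    n_subjects = n_subjects, n_parcels = n_parcels, fs = fs, K_true = K_true,
    transition_base = transition_base, subject_fo_jitter = subject_fo_jitter,
    n_trials = n_trials, baseline_range = baseline_range, post_range = post_range,
    rest_duration_s = rest_duration_s, n_rest_sessions = n_rest_sessions,
    state_specs = state_specs, gamma_spec = gs, roi_parcels = roi_parcels,
    seed = seed
  ), class = "cohort_config")
}

#' Sample a Markov state sequence
#'
#' @param transition K x K row-stochastic transition matrix.
#' @param n_samples length of the sequence.
#' @param initial either a single starting state or a length-K initial
#'   distribution; default uniform.
#' @param seed integer seed (optional).
#' @return integer vector of state labels in `1..K`.
#' @export
generate_state_sequence <- function(transition, n_samples, initial = NULL, seed = NULL) {
  transition <- as.matrix(transition)
  K <- nrow(transition)
  if (K < 1 || ncol(transition) != K) abort("transition must be square with K >= 1")
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8)) {
    abort("transition rows must be non-negative and sum to 1")
  }
  if (n_samples < 1) abort("n_samples must be >= 1")
  with_seed(seed, {
    init <- if (is.null(initial)) {
      sample.int(K, 1)
    } else if (length(initial) == 1) {
      as.integer(initial)
    } else {
      sample.int(K, 1, prob = initial)
    }
    if (n_samples == 1) return(init)
    cumA <- t(apply(transition, 1, cumsum))
    if (K == 1) cumA <- matrix(1, 1, 1)
    markov_path_cpp(cumA, init, runif(n_samples - 1))
  })
}

# band-pass filtered white noise with unit SD, length n
narrowband_noise <- function(n, fs, freq, bandwidth) {
  lo <- max(freq - bandwidth / 2, 0.1)
  hi <- min(freq + bandwidth / 2, fs / 2 - 1)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x / sd(x)
}

#' Render a recording from a state sequence
#'
#' Realises the generative signal model: state-gated narrow-band oscillators
#' plus white noise. While state `k` is visited, each of its oscillators adds
#' band-limited noise of the requested amplitude to its parcel set.
#'
#' @param states integer state labels, one per sample.
#' @param specs list of [state_spec()], one per state label.
#' @param fs sampling rate (Hz); must exceed twice the highest oscillator
#'   frequency.
#' @param n_parcels number of parcels; default: the largest parcel index
#'   named by any oscillator.
#' @param seed integer seed (optional).
#' @return numeric `samples x parcels` matrix.
#' @export
render_recording <- function(states, specs, fs, n_parcels = NULL, seed = NULL) {
  states <- as.integer(states)
  if (max(states) > length(specs)) abort("state label without a matching state_spec")
  maxf <- max(c(0, unlist(lapply(specs, function(s) {
    vapply(s$oscillators, `[[`, numeric(1), "freq")
  }))))
  if (fs <= 2 * maxf) abort("fs must exceed twice the highest oscillator frequency")
  if (is.null(n_parcels)) {
    n_parcels <- max(unlist(lapply(specs, function(s) {
      lapply(s$oscillators, `[[`, "parcels")
    })))
  }
  n <- length(states)
  with_seed(seed, {
    noise_sd <- vapply(specs, `[[`, numeric(1), "noise_sd")[states]
    out <- matrix(rnorm(n * n_parcels), n, n_parcels) * noise_sd
    for (k in seq_along(specs)) {
      gate <- as.numeric(states == k)
      if (!any(gate > 0)) next
      for (o in specs[[k]]$oscillators) {
        if (o$amplitude == 0) next
        x <- narrowband_noise(n, fs, o$freq, o$bandwidth %||% 2) * o$amplitude * gate
        out[, o$parcels] <- out[, o$parcels] + x
      }
    }
    out
  })
}

# Hann-envelope gamma burst added in place on the ROI columns
add_gamma_burst <- function(data, fs, stim_start, peak_freq, amplitude,
                            onset, duration, parcels) {
  n <- round(duration * fs)
  idx <- stim_start + round(onset * fs) + seq_len(n) - 1L
  idx <- idx[idx <= nrow(data)]
  m <- length(idx)
  if (m == 0 || amplitude <= 0) return(data)
  env <- 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
  tt <- (seq_len(m) - 1) / fs
  for (p in parcels) {
    phase <- runif(1, 0, 2 * pi)
    data[idx, p] <- data[idx, p] + amplitude * env * sin(2 * pi * peak_freq * tt + phase)
  }
  data
}

#' Generate one subject's task session
#'
#' Produces a continuous recording of `n_trials` trials, each a 2-4 s
#' state-switching baseline (fixation cross) followed by a post-stimulus
#' period into which a gamma burst at the subject's individual peak frequency
#' is planted in the ROI parcels. The planted burst amplitude is
#' `base + coupling_between * (FO_enh - 1/K) + coupling_within * 1[pre-stimulus
#' state = enhancing] + subject noise + trial noise`, where `FO_enh` is the
#' subject's realised baseline fractional occupancy of the enhancing state.
#'
#' @param cfg a [cohort_config()].
#' @param subject_id integer subject index (used in the sub-seeding scheme).
#' @param transition optional subject-specific transition matrix; default
#'   `cfg$transition_base`.
#' @param seed seed for this session; default derived from `cfg$seed` and
#'   `subject_id`.
#' @return list with `ts` (a [parcel_ts()] whose segments mark each trial's
#'   baseline and post-stimulus period), `events` (tibble: `trial_id`,
#'   `baseline_onset_s`, `stim_onset_s`, `trial_end_s`) and `truth` (list:
#'   sample-wise `states`, per-trial `prestim_state` and `amplitude`,
#'   `peak_freq`, realised baseline `fo`).
#' @export
generate_task_session <- function(cfg, subject_id, transition = NULL, seed = NULL) {
  gs <- cfg$gamma_spec
  fs <- cfg$fs
  transition <- transition %||% cfg$transition_base
  seed <- seed %||% derive_seed(cfg$seed, 101L, subject_id)
  with_seed(seed, {
    nb <- round(runif(cfg$n_trials, cfg$baseline_range[1], cfg$baseline_range[2]) * fs)
    np <- round(runif(cfg$n_trials, cfg$post_range[1], cfg$post_range[2]) * fs)
    total <- sum(nb) + sum(np)
    states <- generate_state_sequence(transition, total,
                                      seed = derive_seed(seed, 1L))
    data <- render_recording(states, cfg$state_specs, fs, cfg$n_parcels,
                             seed = derive_seed(seed, 2L))

    b_start <- cumsum(c(1L, (nb + np)[-cfg$n_trials]))
    stim_start <- b_start + nb
    trial_end <- stim_start + np
    prestim_state <- states[stim_start - 1L]

    base_rows <- unlist(mapply(seq.int, b_start, stim_start - 1L, SIMPLIFY = FALSE))
    fo <- tabulate(states[base_rows], cfg$K_true) / length(base_rows)

    peak_freq <- with_seed(derive_seed(cfg$seed, 7L, subject_id),
                           runif(1, gs$peak_freq_range[1], gs$peak_freq_range[2]))
    subj_off <- gs$coupling_between * (fo[gs$enhancing_state] - 1 / cfg$K_true) +
      rnorm(1, 0, gs$subject_sd)
    amp <- gs$base_amplitude + subj_off +
      gs$coupling_within * (prestim_state == gs$enhancing_state) +
      rnorm(cfg$n_trials, 0, gs$trial_sd)
    amp <- pmax(amp, 0)

    for (i in seq_len(cfg$n_trials)) {
      data <- add_gamma_burst(data, fs, stim_start[i], peak_freq, amp[i],
                              gs$burst_onset, gs$burst_window, cfg$roi_parcels)
    }

    segments <- tibble(
      start = c(b_start, stim_start),
      end = c(stim_start, trial_end),
      label = rep(c("baseline", "trial"), each = cfg$n_trials),
      trial_id = rep(seq_len(cfg$n_trials), 2)
    )
    segments <- dplyr::arrange(segments, .data$start)

    events <- tibble(
      trial_id = seq_len(cfg$n_trials),
      baseline_onset_s = (b_start - 1) / fs,
      stim_onset_s = (stim_start - 1) / fs,
      trial_end_s = (trial_end - 1) / fs
    )

    list(
      ts = parcel_ts(data, fs, subject_id = subject_id, segments = segments),
      events = events,
      truth = list(states = states, prestim_state = prestim_state,
                   amplitude = amp, peak_freq = peak_freq, fo = fo)
    )
  })
}

# one rest session: state switching, no gamma bursts
generate_rest_session <- function(cfg, subject_id, transition, seed) {
  n <- round(cfg$rest_duration_s * cfg$fs)
  states <- generate_state_sequence(transition, n, seed = derive_seed(seed, 1L))
  data <- render_recording(states, cfg$state_specs, cfg$fs, cfg$n_parcels,
                           seed = derive_seed(seed, 2L))
  ts <- parcel_ts(data, cfg$fs, subject_id = subject_id)
  list(ts = ts, states = states,
       fo = tabulate(states, cfg$K_true) / n)
}

# one Dirichlet draw per row, concentration c * base row
jitter_transition <- function(base, concentration) {
  if (!is.finite(concentration)) return(base)
  K <- nrow(base)
  out <- base
  for (i in seq_len(K)) {
    g <- stats::rgamma(K, shape = concentration * base[i, ])
    out[i, ] <- g / sum(g)
  }
  out
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject transition matrices by Dirichlet perturbation of
#' `transition_base` (inducing between-subject fractional-occupancy
#' variation), then generates rest sessions and a task session per subject.
#' Subject mean gamma amplitude increases with the subject's enhancing-state
#' FO with slope `coupling_between`; trial amplitudes additionally depend on
#' the pre-stimulus state through `coupling_within`.
#'
#' @param cfg a [cohort_config()].
#' @return an object of class `sim_cohort`: per-subject recordings plus
#'   ground-truth tibbles `subject_truth` (realised FO per state, peak
#'   frequency, mean planted amplitude) and `trial_truth` (pre-stimulus state
#'   and planted amplitude per trial).
#' @export
generate_cohort <- function(cfg) {
  if (cfg$n_subjects < 2) abort("n_subjects must be >= 2")
  subjects <- vector("list", cfg$n_subjects)
  sub_truth <- vector("list", cfg$n_subjects)
  tri_truth <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    A_i <- with_seed(derive_seed(cfg$seed, 11L, i),
                     jitter_transition(cfg$transition_base, cfg$subject_fo_jitter))
    rest <- list()
    if (cfg$rest_duration_s > 0 && cfg$n_rest_sessions > 0) {
      rest <- lapply(seq_len(cfg$n_rest_sessions), function(r) {
        generate_rest_session(cfg, i, A_i, derive_seed(cfg$seed, 20L + r, i))
      })
      names(rest) <- paste0("rest", seq_along(rest))
    }
    task <- generate_task_session(cfg, i, transition = A_i)
    subjects[[i]] <- list(id = i, transition = A_i, rest = rest, task = task)
    sub_truth[[i]] <- tibble(
      subject = i, state = seq_len(cfg$K_true), fo_baseline = task$truth$fo,
      peak_freq = task$truth$peak_freq,
      mean_amplitude = mean(task$truth$amplitude)
    )
    tri_truth[[i]] <- tibble(
      subject = i, trial_id = seq_len(cfg$n_trials),
      prestim_state = task$truth$prestim_state,
      amplitude = task$truth$amplitude
    )
  }
  structure(list(
    config = cfg, subjects = subjects,
    subject_truth = dplyr::bind_rows(sub_truth),
    trial_truth = dplyr::bind_rows(tri_truth)
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sim_cohort> %d subjects, %d parcels @ %g Hz, K = %d, %d trials/subject, %d rest session(s)\n",
              cfg$n_subjects, cfg$n_parcels, cfg$fs, cfg$K_true, cfg$n_trials,
              length(x$subjects[[1]]$rest)))
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' Persists a simulated cohort in a directory layout: `config.json`, and per
#' subject `task_data.tsv`, `task_states.tsv`, `task_events.csv`,
#' `rest<i>_data.tsv`, `rest<i>_states.tsv` plus `truth.json`. All files are
#' plain text so cohorts survive any transport that preserves text.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  cfg_out <- cfg[setdiff(names(cfg), "state_specs")]
  cfg_out$transition_base <- as.data.frame(cfg$transition_base)
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in cohort$subjects) {
    sd <- file.path(dir, sprintf("subject_%02d", s$id))
    dir.create(sd, showWarnings = FALSE)
    readr::write_tsv(as.data.frame(s$task$ts$data), file.path(sd, "task_data.tsv"),
                     col_names = FALSE, progress = FALSE)
    readr::write_tsv(tibble(state = s$task$truth$states),
                     file.path(sd, "task_states.tsv"), progress = FALSE)
    readr::write_csv(s$task$events, file.path(sd, "task_events.csv"), progress = FALSE)
    readr::write_tsv(s$task$ts$segments, file.path(sd, "task_segments.tsv"), progress = FALSE)
    for (r in seq_along(s$rest)) {
      readr::write_tsv(as.data.frame(s$rest[[r]]$ts$data),
                       file.path(sd, sprintf("rest%d_data.tsv", r)),
                       col_names = FALSE, progress = FALSE)
      readr::write_tsv(tibble(state = s$rest[[r]]$states),
                       file.path(sd, sprintf("rest%d_states.tsv", r)), progress = FALSE)
    }
    jsonlite::write_json(
      list(prestim_state = s$task$truth$prestim_state,
           amplitude = s$task$truth$amplitude,
           peak_freq = s$task$truth$peak_freq, fo = s$task$truth$fo),
      file.path(sd, "truth.json"), digits = NA
    )
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- cohort_config(
    n_subjects = cfg_raw$n_subjects, n_parcels = cfg_raw$n_parcels,
    fs = cfg_raw$fs, K_true = cfg_raw$K_true,
    transition_base = as.matrix(cfg_raw$transition_base),
    subject_fo_jitter = cfg_raw$subject_fo_jitter, n_trials = cfg_raw$n_trials,
    baseline_range = cfg_raw$baseline_range, post_range = cfg_raw$post_range,
    rest_duration_s = cfg_raw$rest_duration_s,
    n_rest_sessions = cfg_raw$n_rest_sessions,
    gamma_spec = as.list(cfg_raw$gamma_spec), roi_parcels = cfg_raw$roi_parcels,
    seed = cfg_raw$seed
  )
  dirs <- sort(list.dirs(dir, recursive = FALSE))
  subjects <- lapply(seq_along(dirs), function(i) {
    sd <- dirs[i]
    dat <- as.matrix(readr::read_tsv(file.path(sd, "task_data.tsv"),
                                     col_names = FALSE, progress = FALSE,
                                     show_col_types = FALSE))
    dimnames(dat) <- NULL
    seg <- readr::read_tsv(file.path(sd, "task_segments.tsv"), progress = FALSE,
                           show_col_types = FALSE)
    events <- readr::read_csv(file.path(sd, "task_events.csv"), progress = FALSE,
                              show_col_types = FALSE)
    truth <- jsonlite::read_json(file.path(sd, "truth.json"), simplifyVector = TRUE)
    truth$states <- readr::read_tsv(file.path(sd, "task_states.tsv"),
                                    progress = FALSE, show_col_types = FALSE)$state
    rest_files <- sort(list.files(sd, "^rest[0-9]+_data", full.names = TRUE))
    rest <- lapply(seq_along(rest_files), function(r) {
      rd <- as.matrix(readr::read_tsv(rest_files[r], col_names = FALSE,
                                      progress = FALSE, show_col_types = FALSE))
      dimnames(rd) <- NULL
      st <- readr::read_tsv(file.path(sd, sprintf("rest%d_states.tsv", r)),
                            progress = FALSE, show_col_types = FALSE)$state
      list(ts = parcel_ts(rd, cfg$fs, subject_id = i), states = st,
           fo = tabulate(st, cfg$K_true) / length(st))
    })
    names(rest) <- if (length(rest)) paste0("rest", seq_along(rest))
    list(id = i, transition = NULL, rest = rest,
         task = list(ts = parcel_ts(dat, cfg$fs, subject_id = i, segments = seg),
                     events = events, truth = truth))
  })
  sub_truth <- dplyr::bind_rows(lapply(subjects, function(s) {
    tibble(subject = s$id, state = seq_len(cfg$K_true),
           fo_baseline = s$task$truth$fo, peak_freq = s$task$truth$peak_freq,
           mean_amplitude = mean(s$task$truth$amplitude))
  }))
  tri_truth <- dplyr::bind_rows(lapply(subjects, function(s) {
    tibble(subject = s$id, trial_id = seq_along(s$task$truth$amplitude),
           prestim_state = s$task$truth$prestim_state,
           amplitude = s$task$truth$amplitude)
  }))
  structure(list(config = cfg, subjects = subjects,
                 subject_truth = sub_truth, trial_truth = tri_truth),
            class = "sim_cohort")
}
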