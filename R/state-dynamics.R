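#' Fractional occupancy
#'
#' Fraction of samples assigned to each state (hard assignment from a label
#' path) or mean posterior probability (soft, from a posterior matrix),
#' optionally per group (e.g. subject or trial).
#'
#' @param x integer state path, T x K posterior matrix, or `tde_hmm`.
#' @param K number of states (required for a path without attributes).
#' @param groups optional grouping vector, one entry per sample.
#' @return tibble with columns `group` (if given), `state`, `fo`; FO sums to
#'   1 within each group.
#' @export
fractional_occupancy <- function(x, K = NULL, groups = NULL) {
  if (inherits(x, "tde_hmm")) x <- x$gamma
  soft <- is.matrix(x)
  if (soft) K <- ncol(x)
  if (is.null(K)) K <- max(x)
  one <- function(xx) {
    if (soft) colMeans(xx, na.rm = TRUE) else tabulate(xx, K) / length(xx)
  }
  if (is.null(groups)) {
    n <- if (soft) nrow(x) else length(x)
    if (n == 0) abort("empty unit")
    return(tibble(state = seq_len(K), fo = one(x)))
  }
  idx <- split(seq_along(groups), groups)
  dplyr::bind_rows(lapply(names(idx), function(g) {
    xx <- if (soft) x[idx[[g]], , drop = FALSE] else x[idx[[g]]]
    tibble(group = g, state = seq_len(K), fo = one(xx))
  }))
}

# run-length view of a path restricted to one segment
segment_runs <- function(path) {
  r <- rle(path)
  ends <- cumsum(r$lengths)
  tibble(state = r$values, length = r$lengths,
         start = ends - r$lengths + 1L, end = ends,
         truncated = seq_along(r$values) %in% c(1L, length(r$values)))
}

path_runs <- function(path, segments = NULL) {
  if (is.null(segments)) segments <- rep(1L, length(path))
  parts <- split(seq_along(path), segments)
  dplyr::bind_rows(lapply(parts, function(rows) segment_runs(path[rows])))
}

#' State lifetimes
#'
#' Durations of uninterrupted state visits, in seconds. Runs truncated by a
#' segment boundary (the first and last run of every segment) are excluded:
#' their true duration is censored.
#'
#' @param path integer state labels.
#' @param fs sampling rate in Hz.
#' @param segments optional segment id per sample; runs never span segments.
#' @return tibble with columns `state`, `duration_s`.
#' @export
state_lifetimes <- function(path, fs, segments = NULL) {
  if (fs <= 0) abort("fs must be positive")
  runs <- path_runs(path, segments)
  runs <- runs[!runs$truncated, , drop = FALSE]
  tibble(state = runs$state, duration_s = runs$length / fs)
}

#' Interval times between state visits
#'
#' Time between the end of one visit to a state and the start of the next
#' visit to the same state, per segment.
#'
#' @inheritParams state_lifetimes
#' @return tibble with columns `state`, `interval_s`.
#' @export
state_intervals <- function(path, fs, segments = NULL) {
  if (fs <= 0) abort("fs must be positive")
  if (is.null(segments)) segments <- rep(1L, length(path))
  parts <- split(seq_along(path), segments)
  out <- list()
  for (rows in parts) {
    runs <- segment_runs(path[rows])
    for (k in unique(runs$state)) {
      rk <- runs[runs$state == k, , drop = FALSE]
      if (nrow(rk) < 2) next
      gaps <- rk$start[-1] - rk$end[-nrow(rk)] - 1L
      out[[length(out) + 1]] <- tibble(state = k, interval_s = gaps / fs)
    }
  }
  if (!length(out)) return(tibble(state = integer(), interval_s = numeric()))
  dplyr::bind_rows(out)
}

#' Event-locked fractional occupancy
#'
#' Averages state probability (or decoded indicators) across trials at each
#' time point relative to a locking event, then across subjects, retaining
#' the between-subject SD. Trials shorter than the window contribute only to
#' the time points they cover.
#'
#' @param trials list of per-trial matrices (time x K), each starting at the
#'   locking event.
#' @param fs sampling rate in Hz.
#' @param subjects subject id per trial (default: all one subject).
#' @return tibble with columns `time_s`, `state`, `fo`, `sd`, `n_subjects`,
#'   `n_trials`.
#' @export
timelocked_fo <- function(trials, fs, subjects = NULL) {
  if (!length(trials)) abort("no trials")
  subjects <- subjects %||% rep(1L, length(trials))
  K <- ncol(trials[[1]])
  max_len <- max(vapply(trials, nrow, integer(1)))
  by_subj <- split(trials, subjects)
  subj_means <- lapply(by_subj, function(trs) {
    acc <- matrix(0, max_len, K)
    cnt <- matrix(0, max_len, K)
    for (m in trs) {
      r <- seq_len(nrow(m))
      acc[r, ] <- acc[r, ] + m
      cnt[r, ] <- cnt[r, ] + 1
    }
    acc / ifelse(cnt > 0, cnt, NA)
  })
  arr <- simplify2array(subj_means) # max_len x K x S
  mean_fo <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  sd_fo <- apply(arr, c(1, 2), sd, na.rm = TRUE)
  n_sub <- apply(!is.na(arr), c(1, 2), sum)
  cover <- vapply(seq_len(max_len), function(t) {
    sum(vapply(trials, nrow, integer(1)) >= t)
  }, integer(1))
  tibble(
    time_s = rep((seq_len(max_len) - 1) / fs, K),
    state = rep(seq_len(K), each = max_len),
    fo = as.vector(mean_fo), sd = as.vector(sd_fo),
    n_subjects = as.vector(n_sub), n_trials = rep(cover, K)
  )
}

#' Test for a time trend in event-locked occupancy
#'
#' Fits, per subject and state, an ordinary least-squares slope of
#' event-locked FO on time (in seconds), and tests the subject slopes
#' against zero with a one-sample t-test.
#'
#' @param fo_t tibble with columns `subject`, `time_s`, `state`, `fo` (one
#'   row per subject, state and time point).
#' @param window optional `c(lo, hi)` restriction of the time axis, seconds.
#' @return tibble with one row per state: `mean_slope`, `t`, `p`,
#'   `n_subjects`; per-subject slopes in the `slopes` attribute.
#' @export
fo_slope_test <- function(fo_t, window = NULL) {
  if (!is.null(window)) {
    fo_t <- dplyr::filter(fo_t, .data$time_s >= window[1], .data$time_s <= window[2])
  }
  if (dplyr::n_distinct(fo_t$subject) < 2) abort("need at least 2 subjects")
  slopes <- fo_t |>
    dplyr::group_by(.data$subject, .data$state) |>
    dplyr::summarise(slope = {
      ok <- is.finite(.data$fo)
      stats::coef(stats::lm(.data$fo[ok] ~ .data$time_s[ok]))[2]
    }, .groups = "drop")
  res <- slopes |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      mean_slope = mean(.data$slope),
      t = tryCatch(stats::t.test(.data$slope)$statistic, error = function(e) NA_real_),
      p = tryCatch(stats::t.test(.data$slope)$p.value, error = function(e) NA_real_),
      n_subjects = dplyr::n(), .groups = "drop"
    )
  attr(res, "slopes") <- slopes
  res
}

#' Plot event-locked fractional occupancy
#'
#' @param fo_t tibble from [timelocked_fo()].
#' @return a ggplot object.
#' @export
plot_timelocked_fo <- function(fo_t) {
  ggplot2::ggplot(fo_t, ggplot2::aes(x = .data$time_s, y = .data$fo,
                                     colour = factor(.data$state),
                                     fill = factor(.data$state))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fo - .data$sd,
                                      ymax = .data$fo + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from event (s)", y = "fractional occupancy",
                  colour = "state", fill = "state") +
    ggplot2::theme_minimal()
}
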