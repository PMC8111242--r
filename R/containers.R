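#' Parcel-level multichannel time series
#'
#' A light container for one recording: a numeric `samples x parcels` matrix,
#' its sampling rate, the subject it belongs to, and a segment table marking
#' sub-intervals of interest (rest, trial baselines, trials). Segments use
#' half-open sample intervals `[start, end)` with 1-based starts, so
#' `end - start` is the segment length and consecutive segments share no
#' sample.
#'
#' @param data numeric matrix, samples in rows, parcels in columns.
#' @param fs sampling rate in Hz.
#' @param subject_id subject identifier.
#' @param segments tibble with columns `start`, `end`, `label` and optionally
#'   `trial_id`. Defaults to one segment spanning the whole recording.
#' @return an object of class `parcel_ts`.
#' @export
parcel_ts <- function(data, fs, subject_id = "S1", segments = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) abort("parcel_ts data must be finite")
  if (fs <= 0) abort("fs must be positive")
  if (is.null(segments)) {
    segments <- tibble(start = 1L, end = nrow(data) + 1L, label = "rest")
  }
  segments <- as_tibble(segments)
  if (nrow(segments)) {
    stopifnot(all(segments$start >= 1), all(segments$end <= nrow(data) + 1),
              all(segments$end > segments$start))
  }
  structure(
    list(data = data, fs = fs, subject_id = subject_id, segments = segments),
    class = "parcel_ts"
  )
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> subject %s: %d samples x %d parcels @ %g Hz (%.1f s), %d segment(s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              nrow(x$data) / x$fs, nrow(x$segments)))
  invisible(x)
}

#' @export
dim.parcel_ts <- function(x) dim(x$data)

n_parcels <- function(ts) ncol(ts$data)

# pull the rows of a single segment
segment_rows <- function(seg) seq.int(seg$start, seg$end - 1L)

#' Concatenated, standardised multi-subject data
#'
#' The result of [zscore_concatenate()]: all subjects' segment data stacked in
#' time, with a per-sample index recording the subject, segment, trial and the
#' sample's position within (and distance from the end of) its segment.
#'
#' @param data numeric matrix, total samples x parcels.
#' @param index tibble with one row per sample: `subject`, `segment`,
#'   `trial_id`, `pos` (1-based position in segment), `rev_pos` (1 = last
#'   sample of the segment).
#' @param fs sampling rate in Hz.
#' @return an object of class `concat_data`.
#' @export
concat_data <- function(data, index, fs) {
  data <- as.matrix(data)
  index <- as_tibble(index)
  if (nrow(index) != nrow(data)) abort("index must have one row per sample")
  structure(list(data = data, index = index, fs = fs), class = "concat_data")
}

#' @export
print.concat_data <- function(x, ...) {
  cat(sprintf("<concat_data> %d samples x %d parcels @ %g Hz, %d subject(s), %d segment(s)\n",
              nrow(x$data), ncol(x$data), x$fs,
              dplyr::n_distinct(x$index$subject),
              dplyr::n_distinct(paste(x$index$subject, x$index$segment))))
  invisible(x)
}

#' @export
dim.concat_data <- function(x) dim(x$data)

# segment start rows (in concatenated coordinates), in order of appearance
concat_segment_starts <- function(x) {
  key <- paste(x$index$subject, x$index$segment)
  which(key != dplyr::lag(key, default = ""))
}
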