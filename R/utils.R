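#' @importFrom Rcpp sourceCpp
#' @useDynLib gammastates, .registration = TRUE
#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor sd var fft rnorm runif setNames
NULL

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed. Sub-streams
#' (per subject, per trial, per restart) are derived by hashing the master
#' seed together with small integer tags, so that any part of a simulation
#' can be regenerated in isolation. The result is always a valid positive
#' 32-bit integer seed.
#'
#' @param seed master seed (single integer).
#' @param ... integer tags identifying the sub-stream.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  # multiplier kept small so h * mult + x stays exactly representable in a double
  for (x in as.numeric(tags)) {
    h <- (h * 69069 + (x %% m) + 12345) %% m
    h <- (h * 69069 + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the symmetric tridiagonal eigenproblem. Tapers are
#' normalised to unit energy; the sign convention makes each taper's mean
#' (or, for odd tapers, its leading lobe) positive.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product; `k` tapers are well concentrated for
#'   `k <= 2 nw - 1`.
#' @param k number of tapers.
#' @return an `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, k >= 1, nw > 0)
  if (k > n) abort("more tapers requested than samples")
  w <- nw / n
  t_idx <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  M <- matrix(0, n, n)
  M[cbind(1:n, 1:n)] <- diag_v
  M[cbind(1:(n - 1), 2:n)] <- off_v
  M[cbind(2:n, 1:(n - 1))] <- off_v
  ev <- eigen(M, symmetric = TRUE)
  h <- ev$vectors[, seq_len(k), drop = FALSE]
  h <- sweep(h, 2, sqrt(colSums(h^2)), "/")
  for (j in seq_len(k)) {
    s <- sum(h[, j])
    if (abs(s) > 1e-10) {
      if (s < 0) h[, j] <- -h[, j]
    } else if (h[which.max(abs(h[, j])), j] < 0) {
      h[, j] <- -h[, j]
    }
  }
  h
}

#' Amplitude envelope via the analytic signal
#'
#' Returns `Mod(x + i H(x))` where `H` is the Hilbert transform, computed by
#' the standard one-sided FFT construction.
#'
#' @param x numeric vector (or matrix; columns are transformed independently).
#' @return envelope with the same shape as `x`.
#' @export
hilbert_envelope <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, hilbert_envelope))
  n <- length(x)
  m <- stats::nextn(n, c(2, 3, 5)) # keep the FFT on a composite length
  X <- fft(c(x, numeric(m - n)))
  h <- numeric(m)
  h[c(1, m / 2 + 1)] <- 1
  h[2:(m / 2)] <- 2
  Mod(fft(X * h, inverse = TRUE) / m)[seq_len(n)]
}

# frequencies of an n-point real FFT at sampling rate fs (one-sided)
rfft_freqs <- function(n, fs) (0:(n %/% 2)) * fs / n

check_prob_rows <- function(m, tol = 1e-8, what = "matrix") {
  if (any(m < -tol)) abort(paste0(what, " has negative entries"))
  if (any(abs(rowSums(m) - 1) > tol)) {
    abort(paste0("rows of ", what, " must sum to 1"))
  }
  invisible(m)
}
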