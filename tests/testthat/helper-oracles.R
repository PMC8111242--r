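# Independent oracles used across test files. These deliberately avoid the
# package's own computational paths.

# Exact HMM posteriors by enumerating all K^T paths.
enumerate_posteriors <- function(logB, A, pi0) {
  T_len <- nrow(logB); K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  lp <- apply(paths, 1, function(p) {
    v <- log(pi0[p[1]]) + logB[1, p[1]]
    for (t in seq_len(T_len)[-1]) v <- v + log(A[p[t - 1], p[t]]) + logB[t, p[t]]
    v
  })
  m <- max(lp)
  w <- exp(lp - m); Z <- sum(w); w <- w / Z
  gamma <- sapply(seq_len(K), function(k) {
    sapply(seq_len(T_len), function(t) sum(w[paths[, t] == k]))
  })
  list(gamma = gamma, loglik = log(Z) + m)
}

# Welch-style band power of one channel via averaged periodograms.
welch_band_power <- function(x, fs, band, n_seg = 512) {
  n <- length(x)
  starts <- seq(1, n - n_seg + 1, by = n_seg)
  f <- (0:(n_seg - 1)) * fs / n_seg
  sel <- f >= band[1] & f <= band[2]
  mean(vapply(starts, function(s) {
    pg <- Mod(fft(x[s + seq_len(n_seg) - 1]))^2 / n_seg
    mean(pg[sel])
  }, numeric(1)))
}

# random row-stochastic matrix
random_transition <- function(K) {
  A <- matrix(stats::runif(K * K), K, K)
  A / rowSums(A)
}

# small ready-made task cohort for pipeline-level tests
tiny_cohort <- function(seed = 42, n_subjects = 4, n_trials = 6) {
  cohort_config(
    n_subjects = n_subjects, n_parcels = 8, n_trials = n_trials,
    rest_duration_s = 0, seed = seed
  ) |> generate_cohort()
}
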