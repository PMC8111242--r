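test_that("state sequences follow the transition structure", {
  # absorbing chain stays put
  s <- generate_state_sequence(diag(3), 100, initial = 2, seed = 1)
  expect_true(all(s == 2))

  # geometric sojourns: mean lifetime 1/(1 - p)
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  s <- generate_state_sequence(A, 2e5, seed = 2)
  lt <- state_lifetimes(s, fs = 1)
  expect_equal(mean(lt$duration_s), 10, tolerance = 0.02)

  # uniform chain: long-run FO near the 1/K stationary distribution
  A4 <- matrix(0.25, 4, 4)
  s4 <- generate_state_sequence(A4, 1e6, seed = 3)
  fo <- fractional_occupancy(s4, K = 4)$fo
  expect_true(all(fo >= 0.245 & fo <= 0.255))

  # reproducibility and validation
  expect_identical(generate_state_sequence(A, 500, seed = 9),
                   generate_state_sequence(A, 500, seed = 9))
  expect_error(generate_state_sequence(matrix(c(1, 1, 0, 1), 2, 2), 10),
               "sum to 1")
})

test_that("rendered recordings carry the planted band power", {
  fs <- 250
  # lone 10 Hz oscillator: spectral mass concentrated in its band
  sp <- state_spec(1, list(list(parcels = 3, freq = 10, amplitude = 5, bandwidth = 2)),
                   noise_sd = 1e-3)
  x <- render_recording(rep(1, 4000), list(sp), fs, n_parcels = 4, seed = 1)
  pg <- Mod(fft(x[, 3]))^2
  f <- (0:3999) * fs / 4000
  expect_gt(sum(pg[f >= 8 & f <= 12]) / sum(pg[f > 0 & f <= fs / 2]), 0.99)

  # zero amplitudes: band power indistinguishable across states
  sp0 <- lapply(1:2, function(k) {
    state_spec(k, list(list(parcels = 1, freq = 10 * k, amplitude = 0, bandwidth = 2)))
  })
  states <- rep(1:2, each = 2000)
  x0 <- render_recording(states, sp0, fs, n_parcels = 2, seed = 2)
  p1 <- welch_band_power(x0[states == 1, 1], fs, c(8, 12), 256)
  p2 <- welch_band_power(x0[states == 2, 1], fs, c(8, 12), 256)
  expect_equal(p1 / p2, 1, tolerance = 0.25)

  # two contrasting states: epoch-conditioned power contrast has the planted sign
  spA <- state_spec(1, list(list(parcels = 1, freq = 10, amplitude = 2, bandwidth = 2)))
  spB <- state_spec(2, list(list(parcels = 2, freq = 2, amplitude = 2, bandwidth = 1)))
  states <- rep(rep(1:2, each = 500), 10)
  x2 <- render_recording(states, list(spA, spB), fs, n_parcels = 2, seed = 3)
  a_alpha <- welch_band_power(x2[states == 1, 1], fs, c(8, 12), 250)
  b_alpha <- welch_band_power(x2[states == 2, 1], fs, c(8, 12), 250)
  a_delta <- welch_band_power(x2[states == 1, 2], fs, c(1, 3), 250)
  b_delta <- welch_band_power(x2[states == 2, 2], fs, c(1, 3), 250)
  expect_gt(a_alpha, b_alpha)
  expect_gt(b_delta, a_delta)

  expect_error(render_recording(c(1, 2), list(sp), fs), "state label")
})

test_that("task sessions plant trial structure and state-coupled amplitudes", {
  cfg <- cohort_config(n_subjects = 2, n_parcels = 8, n_trials = 40,
                       rest_duration_s = 0, seed = 5)
  ses <- generate_task_session(cfg, 1)

  # baseline lengths within the configured 2-4 s range at 250 Hz
  blen <- round((ses$events$stim_onset_s - ses$events$baseline_onset_s) * cfg$fs)
  expect_true(all(blen >= 500 & blen <= 1000))

  # planted within-subject effect has the configured size
  ind <- ses$truth$prestim_state == cfg$gamma_spec$enhancing_state
  expect_gt(sum(ind), 3)
  diffs <- mean(ses$truth$amplitude[ind]) - mean(ses$truth$amplitude[!ind])
  expect_equal(diffs, cfg$gamma_spec$coupling_within, tolerance = 0.35)

  # no coupling: planted amplitudes independent of the pre-stimulus state
  cfg0 <- cohort_config(n_subjects = 2, n_parcels = 8, n_trials = 60,
                        rest_duration_s = 0, seed = 6,
                        gamma_spec = list(coupling_within = 0, coupling_between = 0))
  ses0 <- generate_task_session(cfg0, 1)
  ind0 <- as.numeric(ses0$truth$prestim_state == 1)
  expect_lt(abs(cor(ind0, ses0$truth$amplitude)), 0.3)

  # truth bookkeeping: FO vector sums to 1, labels in range
  expect_equal(sum(ses$truth$fo), 1, tolerance = 1e-12)
  expect_true(all(ses$truth$states %in% seq_len(cfg$K_true)))
})

test_that("cohorts are deterministic and plant the between-subject coupling", {
  c1 <- tiny_cohort(seed = 10)
  c2 <- tiny_cohort(seed = 10)
  expect_identical(c1$subjects[[2]]$task$ts$data, c2$subjects[[2]]$task$ts$data)
  expect_identical(c1$trial_truth, c2$trial_truth)

  # strong coupling: planted FO and planted mean amplitude correlate strongly
  cfg <- cohort_config(n_subjects = 15, n_parcels = 8, n_trials = 10,
                       rest_duration_s = 0, seed = 11)
  coh <- generate_cohort(cfg)
  st <- coh$subject_truth
  enh <- st[st$state == cfg$gamma_spec$enhancing_state, ]
  expect_gt(cor(enh$fo_baseline, enh$mean_amplitude, method = "spearman"), 0.6)

  # no jitter, no coupling: nothing to correlate
  cfg0 <- cohort_config(n_subjects = 16, n_parcels = 8, n_trials = 10,
                        rest_duration_s = 0, subject_fo_jitter = Inf, seed = 12,
                        gamma_spec = list(coupling_between = 0))
  coh0 <- generate_cohort(cfg0)
  st0 <- coh0$subject_truth[coh0$subject_truth$state == 1, ]
  expect_lt(abs(cor(st0$fo_baseline, st0$mean_amplitude, method = "spearman")), 0.65)

  # subject peak frequencies within the configured range
  expect_true(all(st$peak_freq >= 42 & st$peak_freq <= 74))
})

test_that("gamma bursts are confined to the post-stimulus window", {
  cfg <- cohort_config(n_subjects = 2, n_parcels = 8, n_trials = 12,
                       rest_duration_s = 0, seed = 13,
                       gamma_spec = list(base_amplitude = 3, trial_sd = 0,
                                         subject_sd = 0, coupling_between = 0))
  ses <- generate_task_session(cfg, 1)
  fs <- cfg$fs
  pk <- ses$truth$peak_freq
  roi <- cfg$roi_parcels[1]
  band <- c(pk - 10, pk + 10)
  base_rows <- unlist(lapply(seq_len(nrow(ses$events)), function(i) {
    seq.int(round(ses$events$baseline_onset_s[i] * fs) + 1,
            round(ses$events$stim_onset_s[i] * fs))
  }))
  resp_rows <- unlist(lapply(seq_len(nrow(ses$events)), function(i) {
    s0 <- round(ses$events$stim_onset_s[i] * fs) + 1
    seq.int(s0 + round(0.7 * fs), s0 + round(1.9 * fs))
  }))
  p_base <- welch_band_power(ses$ts$data[base_rows, roi], fs, band, 250)
  p_resp <- welch_band_power(ses$ts$data[resp_rows, roi], fs, band, 250)
  # baseline at the white-noise floor, response well above it
  expect_gt(p_resp / p_base, 2)
  # pure-noise reference channel (frontal parcel) for the same band
  p_ref <- welch_band_power(ses$ts$data[base_rows, 1], fs, band, 250)
  expect_equal(p_base / p_ref, 1, tolerance = 0.3)
})

test_that("cohorts round-trip through the plain-text format", {
  coh <- tiny_cohort(seed = 20, n_subjects = 2, n_trials = 3)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects[[1]]$task$ts$data, coh$subjects[[1]]$task$ts$data,
               tolerance = 1e-12)
  expect_equal(back$trial_truth$amplitude, coh$trial_truth$amplitude,
               tolerance = 1e-12)
  expect_equal(back$subjects[[2]]$task$events, coh$subjects[[2]]$task$events,
               tolerance = 1e-12)
})
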