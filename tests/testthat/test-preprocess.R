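test_that("bandpass preserves the pass band and rejects out-of-band energy", {
  fs <- 250
  t <- seq(0, 8, by = 1 / fs)
  tone10 <- parcel_ts(cbind(sin(2 * pi * 10 * t)), fs)
  out10 <- bandpass(tone10, 1, 35)
  mid <- 200:1800 # ignore filter edge transients
  expect_equal(sd(out10$data[mid, 1]), sd(tone10$data[mid, 1]), tolerance = 0.01)

  tone60 <- parcel_ts(cbind(sin(2 * pi * 60 * t)), fs)
  out60 <- bandpass(tone60, 1, 35)
  expect_lt(sd(out60$data[mid, 1]) / sd(tone60$data[mid, 1]), 0.05)

  dc <- parcel_ts(cbind(rep(2, 2001)), fs)
  expect_lt(max(abs(bandpass(dc, 1, 35)$data[, 1])), 1e-10)

  expect_error(bandpass(tone10, 1, 130), "Nyquist")
})

test_that("bandpass is idempotent up to filter tolerance", {
  fs <- 250
  set.seed(11)
  x <- parcel_ts(cbind(rnorm(5000), rnorm(5000)), fs)
  once <- bandpass(x, 1, 35)
  twice <- bandpass(once, 1, 35)
  r1 <- apply(once$data, 2, sd)
  r2 <- apply(twice$data, 2, sd)
  expect_true(all(abs(r2 / r1 - 1) < 0.01))
})

test_that("baseline extraction strips the first second and drops short baselines", {
  fs <- 250
  ts <- parcel_ts(matrix(rnorm(3000 * 2), 3000, 2), fs)
  events <- tibble::tibble(trial_id = 1:2,
                           baseline_onset_s = c(0, 6),
                           stim_onset_s = c(3, 9),
                           trial_end_s = c(6, 12))
  out <- extract_baselines(ts, events, strip_seconds = 1)
  expect_equal(out$segments$end - out$segments$start, c(500, 500))
  expect_equal(out$segments$end, round(events$stim_onset_s * fs) + 1)

  # strip 0: the full baseline survives
  out0 <- extract_baselines(ts, events, strip_seconds = 0)
  expect_equal(out0$segments$end - out0$segments$start, c(750, 750))

  # a 0.8 s baseline is dropped with a warning
  ev_short <- tibble::tibble(trial_id = 1, baseline_onset_s = 0,
                             stim_onset_s = 0.8, trial_end_s = 2)
  expect_warning(short <- extract_baselines(ts, ev_short, 1), "dropping")
  expect_equal(nrow(short$segments), 0)
})

test_that("z-scoring standardises per subject and is scale invariant", {
  fs <- 100
  set.seed(1)
  a <- parcel_ts(matrix(rnorm(400, mean = 3, sd = 2), 200, 2), fs, subject_id = 1)
  b <- parcel_ts(matrix(rnorm(400), 200, 2), fs, subject_id = 2)
  cc <- zscore_concatenate(list(a, b))

  expect_equal(nrow(cc$data), 400)
  for (s in 1:2) {
    rows <- cc$index$subject == s
    expect_equal(colMeans(cc$data[rows, ]), c(0, 0), tolerance = 1e-10)
    expect_equal(apply(cc$data[rows, ], 2, sd), c(1, 1), tolerance = 1e-10)
  }
  # index maps halves to the two subjects
  expect_equal(unique(cc$index$subject[1:200]), 1)
  expect_equal(unique(cc$index$subject[201:400]), 2)

  # scaling one subject's raw data changes nothing
  a7 <- parcel_ts(a$data * 7, fs, subject_id = 1)
  cc7 <- zscore_concatenate(list(a7, b))
  expect_equal(cc7$data, cc$data, tolerance = 1e-12)

  # zero-variance parcel is reported with subject and parcel
  flat <- parcel_ts(cbind(rnorm(100), rep(1, 100)), fs, subject_id = 9)
  expect_error(zscore_concatenate(list(flat)), "parcel\\(s\\) 2 for subject 9")
})

test_that("splitting concatenated data recovers per-subject standardised data", {
  fs <- 100
  set.seed(2)
  ts_list <- lapply(1:3, function(s) {
    parcel_ts(matrix(rnorm(300, s, s), 100, 3), fs, subject_id = s)
  })
  cc <- zscore_concatenate(ts_list)
  for (s in 1:3) {
    rows <- cc$index$subject == s
    x <- ts_list[[s]]$data
    manual <- sweep(sweep(x, 2, colMeans(x)), 2, apply(x, 2, sd), "/")
    expect_equal(cc$data[rows, ], manual, tolerance = 1e-12)
    expect_equal(cc$index$pos[rows], seq_len(nrow(x)))
  }
})

test_that("sign alignment recovers planted sign corruption", {
  fs <- 100
  set.seed(3)
  base <- matrix(rnorm(500 * 2), 500, 2)
  base[, 2] <- 0.7 * base[, 1] + 0.3 * base[, 2] # correlated parcels

  # an exact mirror is already consistent in covariance structure: the
  # alignment objective is maximal without any flip, and the post-flip
  # lagged cross-covariance patterns of the two subjects coincide
  a <- parcel_ts(base, fs, subject_id = 1)
  b <- parcel_ts(-base, fs, subject_id = 2)
  res <- align_signs(list(a, b), lags = -2:2)
  s1 <- gammastates:::lagged_cov_stack(res$flipped[[1]]$data, -2:2)
  s2 <- gammastates:::lagged_cov_stack(res$flipped[[2]]$data, -2:2)
  expect_equal(s1, s2, tolerance = 1e-12)

  # a single-parcel corruption is undone: the within-subject sign pattern
  # of the corrupted subject must end up opposite to the clean subject's
  bad <- parcel_ts(sweep(base, 2, c(1, -1), "*"), fs, subject_id = 2)
  res_bad <- align_signs(list(a, bad), lags = -2:2)
  expect_equal(prod(res_bad$flips[1, ]) * prod(res_bad$flips[2, ]), -1)
  sb1 <- gammastates:::lagged_cov_stack(res_bad$flipped[[1]]$data, -2:2)
  sb2 <- gammastates:::lagged_cov_stack(res_bad$flipped[[2]]$data, -2:2)
  expect_equal(sb1, sb2, tolerance = 1e-12)

  # an already consistent cohort is a fixed point
  set.seed(4)
  c2 <- parcel_ts(base + matrix(rnorm(1000, sd = 0.1), 500, 2), fs, subject_id = 3)
  res2 <- align_signs(list(a, c2), lags = -2:2)
  expect_equal(prod(res2$flips[1, ]) * prod(res2$flips[2, ]), 1)
})

test_that("greedy sign alignment attains the exhaustive optimum on a small instance", {
  fs <- 100
  set.seed(5)
  base <- matrix(rnorm(400 * 2), 400, 2)
  base[, 2] <- 0.8 * base[, 1] + 0.2 * base[, 2]
  corrupt <- list(c(1, -1), c(-1, 1), c(1, 1))
  ts_list <- lapply(1:3, function(s) {
    noisy <- base + matrix(rnorm(800, sd = 0.05), 400, 2)
    parcel_ts(sweep(noisy, 2, corrupt[[s]], "*"), fs, subject_id = s)
  })
  lags <- -2:2
  res <- align_signs(ts_list, lags)

  # brute force over all 2^(3*2) flip assignments
  stacks0 <- lapply(ts_list, function(t) gammastates:::lagged_cov_stack(t$data, lags))
  best <- -Inf
  grid <- expand.grid(rep(list(c(-1, 1)), 6))
  for (i in seq_len(nrow(grid))) {
    fl <- matrix(as.numeric(grid[i, ]), 3, 2)
    st <- lapply(1:3, function(s) gammastates:::flip_stack(stacks0[[s]], fl[s, ]))
    best <- max(best, gammastates:::sign_objective(st))
  }
  expect_equal(res$objective, best, tolerance = 1e-10)

  # invariance to a global sign inversion of the whole cohort
  inv <- lapply(ts_list, function(t) parcel_ts(-t$data, fs, t$subject_id, t$segments))
  res_inv <- align_signs(inv, lags)
  expect_equal(res_inv$objective, res$objective, tolerance = 1e-10)
})
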