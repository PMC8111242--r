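test_that("permutation Spearman matches exact enumeration at n = 4", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  res <- spearman_permutation(x, y, n_perm = 20000, seed = 1)

  # exact enumeration over all 24 permutations
  allp <- gammastates:::all_permutations(4)
  r_obs <- cor(x, y, method = "spearman")
  r_all <- vapply(allp, function(p) cor(x, y[p], method = "spearman"), numeric(1))
  p_exact <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
  expect_equal(res$p, p_exact, tolerance = 0.02)

  # perfect monotone association: r = 1 and the smallest attainable p
  res1 <- spearman_permutation(1:10, (1:10)^2, n_perm = 999, seed = 2)
  expect_equal(res1$r, 1)
  expect_lt(res1$p, 0.005)

  expect_error(spearman_permutation(rep(1, 5), 1:5, 10), "constant")
})

test_that("permutation p-values are valid under the null", {
  set.seed(3)
  n_sim <- 300
  p_vals <- replicate(n_sim, {
    x <- rnorm(15); y <- rnorm(15)
    spearman_permutation(x, y, n_perm = 199)$p
  })
  rate <- mean(p_vals <= 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("pre-stimulus weights average the posterior tail", {
  # build a small fitted-object stand-in through the real pipeline
  coh <- tiny_cohort(seed = 30, n_subjects = 3, n_trials = 5)
  baselines <- lapply(coh$subjects, function(s) {
    extract_baselines(bandpass(s$task$ts, 1, 35), s$task$events, 1)
  })
  cc <- zscore_concatenate(baselines)
  fit <- suppressWarnings( # deliberately short EM; posteriors are all we need
    fit_hmm(cc, hmm_config(K = 2, n_restarts = 1, max_iter = 5, seed = 1))
  )

  w <- prestim_weights(fit, 0.106)
  # 26 samples at 250 Hz, averaged per state; rows sum to 1
  n_w <- floor(0.106 * 250)
  expect_equal(n_w, 26)
  sums <- w |>
    dplyr::group_by(subject, trial_id) |>
    dplyr::summarise(s = sum(weight), .groups = "drop")
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-8)

  # index-arithmetic oracle for one trial
  tp <- trial_posteriors(fit)
  m1 <- tp$mats[[1]]
  manual <- colMeans(m1[nrow(m1) - n_w + seq_len(n_w), ])
  expect_equal(w$weight[w$subject == tp$meta$subject[1] &
                          w$trial_id == tp$meta$trial_id[1]],
               unname(manual), tolerance = 1e-12)

  # one-hot and uniform posteriors map to one-hot / uniform weights
  fit2 <- fit
  fit2$gamma <- cbind(1, 0)[rep(1, nrow(fit2$gamma)), ]
  w2 <- prestim_weights(fit2, 0.106)
  expect_true(all(w2$weight[w2$state == 1] == 1))
  fit3 <- fit
  fit3$gamma[] <- 0.5
  w3 <- prestim_weights(fit3, 0.106)
  expect_true(all(w3$weight == 0.5))
})

test_that("weighted trial averages reduce correctly and match direct summation", {
  set.seed(4)
  n_tr <- 20
  amp <- tibble::tibble(subject = 1, trial_id = 1:n_tr, amplitude = rnorm(n_tr))
  wmat <- matrix(runif(n_tr * 3), n_tr, 3)
  wmat <- wmat / rowSums(wmat)
  weights <- tibble::tibble(
    subject = 1, trial_id = rep(1:n_tr, each = 3),
    state = rep(1:3, n_tr), weight = as.vector(t(wmat))
  )
  res <- weighted_trial_average(amp, weights)
  for (k in 1:3) {
    expect_equal(res$weighted_mean[res$state == k],
                 sum(wmat[, k] * amp$amplitude) / sum(wmat[, k]),
                 tolerance = 1e-12)
  }

  # uniform weights: every state equals the plain mean
  wu <- weights; wu$weight <- 1 / 3
  resu <- weighted_trial_average(amp, wu)
  expect_equal(resu$weighted_mean, rep(mean(amp$amplitude), 3), tolerance = 1e-12)

  # one-hot weights: hard group means
  lab <- sample.int(3, n_tr, replace = TRUE)
  wh <- weights; wh$weight <- as.numeric(wh$state == lab[wh$trial_id])
  resh <- suppressWarnings(weighted_trial_average(amp, wh))
  for (k in unique(lab)) {
    expect_equal(resh$weighted_mean[resh$state == k],
                 mean(amp$amplitude[lab == k]), tolerance = 1e-12)
  }

  # invariance to positive rescaling of a trial's weight row
  ws <- weights
  ws$weight[ws$trial_id == 5] <- ws$weight[ws$trial_id == 5] * 9
  # per-state normalisation means results change -- but multiplying ALL
  # trials' rows by the same constant must not
  wall <- weights; wall$weight <- wall$weight * 7
  expect_equal(weighted_trial_average(amp, wall)$weighted_mean,
               res$weighted_mean, tolerance = 1e-12)
})

test_that("Friedman omnibus and post-hoc detect planted state differences", {
  # identical columns: ranks tie everywhere, nothing to reject
  M <- matrix(rep(rnorm(10), 4), 10, 4)
  res0 <- friedman_posthoc(M)
  expect_gt(res0$friedman_p, 0.99)

  # one state shifted +10 SD for all subjects
  set.seed(5)
  M1 <- matrix(rnorm(14 * 4), 14, 4)
  M1[, 2] <- M1[, 2] + 10
  res1 <- friedman_posthoc(M1)
  expect_lt(res1$friedman_p, 0.05)
  expect_true(all(res1$pairwise_p[2, -2] < 0.05))

  # K = 2: the post-hoc reduces to the direct paired test (Bonferroni = 1)
  M2 <- M1[, 1:2]
  res2 <- friedman_posthoc(M2)
  direct <- stats::wilcox.test(M2[, 1], M2[, 2], paired = TRUE, exact = FALSE)$p.value
  expect_equal(res2$pairwise_p[1, 2], direct, tolerance = 1e-12)

  # rank-sum variant is available
  res3 <- friedman_posthoc(M1, posthoc = "rank_sum")
  expect_lt(res3$pairwise_p[2, 1], 0.05)

  # tidy/glance accessors
  expect_equal(nrow(tidy(res1)), 6)
  expect_equal(glance(res1)$n_subjects, 14)
})

test_that("pseudo-state binning follows quantile ranks", {
  expect_equal(pseudo_state_assign(1:8, 4), rep(1:4, each = 2))
  expect_warning(out <- pseudo_state_assign(rep(2, 6), 4), "empty")
  expect_true(all(out == 1))

  set.seed(6)
  p <- runif(1000)
  bins <- pseudo_state_assign(p, 4)
  expect_true(all(abs(tabulate(bins, 4) - 250) <= 1))
  # bin order respects the underlying values
  expect_true(max(p[bins == 1]) < min(p[bins == 4]))
})

test_that("effect comparison separates between- and within-subject coupling", {
  set.seed(7)
  S <- 10; n_tr <- 20
  subject <- rep(1:S, each = n_tr)

  # pure between-subject construction: amplitude a monotone function of the
  # subject mean FO score, zero trial noise
  subj_fo <- runif(S, 0.1, 0.6)
  fo1 <- pmin(pmax(subj_fo[subject] + rnorm(S * n_tr, sd = 0.03), 0), 1)
  trial_fo <- cbind(fo1, (1 - fo1) / 3, (1 - fo1) / 3, (1 - fo1) / 3)
  subj_means <- tapply(trial_fo[, 1], subject, mean)
  amp_b <- (2 * subj_means^2)[subject] + rnorm(S * n_tr, sd = 1e-6)
  res_b <- effect_size_comparison(trial_fo, amp_b, subject, n_boot = 200, seed = 1)
  expect_equal(res_b$observed$r_abs[res_b$observed$effect == "between"], 1)
  expect_lt(res_b$observed$r_abs[res_b$observed$effect == "within"], 0.2)
  expect_gt(res_b$pairwise["between", "within"], 0.9)

  # within-only construction: amplitudes driven by residual FO
  amp_w <- (fo1 - subj_means[subject]) * 5 + rnorm(S * n_tr, sd = 0.05)
  res_w <- effect_size_comparison(trial_fo, amp_w, subject, n_boot = 200, seed = 2)
  expect_gt(res_w$pairwise["within", "between"], 0.9)

  # residual subject means vanish by construction
  # (between/within decomposition is exact)
  resids <- amp_w - tapply(amp_w, subject, mean)[subject]
  expect_lt(max(abs(tapply(resids, subject, mean))), 1e-10)

  # PC1 scores match an independent eigendecomposition on a small toy
  toy <- matrix(runif(40), 10, 4)
  toy <- toy / rowSums(toy)
  ev <- eigen(cov(toy), symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  score_oracle <- scale(toy, scale = FALSE) %*% v
  res_t <- effect_size_comparison(toy, rnorm(10), rep(1:5, each = 2),
                                  n_boot = 10, seed = 3)
  score_pkg <- scale(toy, scale = FALSE) %*% res_t$pc_loading
  expect_equal(as.vector(score_pkg), as.vector(score_oracle), tolerance = 1e-10)

  # extra between-subject effects travel through the bootstrap
  extra <- list(rest = subj_fo)
  res_e <- effect_size_comparison(trial_fo, amp_b, subject, n_boot = 50,
                                  seed = 4, extra_between = extra)
  expect_true("rest" %in% res_e$observed$effect)
  expect_equal(ncol(res_e$boot), 3)
})

test_that("pre-stimulus band power feeds pseudo-states", {
  fs <- 250
  set.seed(8)
  n <- 20 * fs
  dat <- cbind(rnorm(n), rnorm(n))
  # alpha bursts in the pre-stimulus window of half the trials
  events <- tibble::tibble(trial_id = 1:4,
                           baseline_onset_s = c(0, 5, 10, 15),
                           stim_onset_s = c(3, 8, 13, 18),
                           trial_end_s = c(5, 10, 15, 20))
  for (i in c(2, 4)) {
    rows <- round(events$stim_onset_s[i] * fs) + (-199:0)
    dat[rows, 1] <- dat[rows, 1] + 4 * sin(2 * pi * 10 * seq_along(rows) / fs)
  }
  ts <- parcel_ts(dat, fs)
  bp <- prestim_band_power(ts, events, band = c(8, 12), parcels = 1)
  expect_true(all(bp$power[c(2, 4)] > bp$power[c(1, 3)]))
  bins <- pseudo_state_assign(bp$power, 2)
  expect_equal(bins, c(1, 2, 1, 2))
})
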