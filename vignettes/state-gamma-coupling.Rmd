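---
title: "Linking spontaneous brain-network states to induced gamma responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking spontaneous brain-network states to induced gamma responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific question

Narrow-band gamma responses induced by visual stimulation vary widely both
between individuals and from trial to trial, for reasons that are largely
unexplained. One candidate explanation is that slower (< 35 Hz) spontaneous
network activity — measurable at rest or in the pre-stimulus baseline —
biases how visual cortex responds. `gammastates` implements a complete
analysis pipeline for testing that idea on parcel-level electrophysiological
recordings:

1. describe spontaneous sub-gamma activity as a small set of recurring
   **brain states**, inferred by a time-delay embedded hidden Markov model
   (TDE-HMM);
2. quantify the **induced gamma response** per trial as percent power change
   in an individually determined gamma band over visual cortex;
3. relate the two, **between subjects** (does a subject's preference for a
   state predict their average response?) and **within subjects** (does the
   state visited just before stimulus onset predict the single-trial
   response?).

Because suitable recordings are rarely shareable, the package ships a
synthetic-cohort generator that plants all of the structure the pipeline is
supposed to find, giving every stage a recovery test.

## The state model

The observation vector is a parcel time series $y_t \in \mathbb{R}^P$
(50 parcels at 250 Hz in the reference configuration), band-passed to
1–35 Hz, z-scored per subject and concatenated across subjects. Each sample
is augmented with lagged copies over a symmetric window (±7 samples, 15
lags), so a zero-mean Gaussian with full covariance on the embedded space
encodes the autocovariance — hence the spectrum and cross-spectrum — of a
state. The embedded data are reduced by PCA to twice the parcel count
before the HMM is fit.

Inference is maximum-likelihood EM (Baum–Welch). The forward–backward
recursions run in compiled code with per-step rescaling after max-shifting
each emission log-density row, which is numerically equivalent to log-space
message passing; chains restart at every segment boundary so state
assignments never bridge discontinuous data. Restarted short EM runs from
k-means-seeded responsibilities (5 by default) guard against local optima;
the best short run is continued to convergence (relative log-likelihood
change below `tol`, default `1e-5`). State covariances are ridge-regularised
by `cov_reg * trace/dim` (default `1e-3`).

Two deliberate simplifications relative to common practice:

* **EM rather than variational Bayes.** The downstream analyses consume
  only the state posteriors and state spectra, which EM provides; priors
  would add parameters the analyses never use. The log-likelihood trace is
  monotone (checked in the tests), which VB free energies only guarantee in
  their own metric.
* **Masked samples get uniform posteriors.** Embedding invalidates a few
  samples at each segment edge. Their posterior rows are set to $1/K$ so
  the posterior stays aligned with the raw time axis. This slightly dilutes
  quantities computed near segment ends (notably the pre-stimulus weights,
  whose window includes the final embedding margin of every baseline).

Posterior decoding assigns each sample to its most probable state, ties
broken towards the lower state index. HMM state labels are arbitrary;
where ground truth exists, decoded labels are aligned to it by exhaustively
maximising agreement over label permutations.

## State spectra and band maps

State-specific power and coherence use a state-weighted multitaper
estimator: posteriors are normalised to weights
$\rho_t^{(k)} = \gamma_t^{(k)} / (\sum_t \gamma_t^{(k)} / T)$ (time mean of
each column is exactly 1), and each sliding window's multitaper
cross-spectrum contributes to state $k$ with the window-mean of
$\rho^{(k)}$. The printed estimator is a whole-series transform; computing
it on finite windows (2 s, 50% overlap, 3 DPSS tapers by default) is what
makes spectra at 1 Hz estimable, and the window-mean weighting preserves two
exact identities that the tests verify to machine precision:

* $\rho \equiv 1$ recovers the ordinary multitaper spectrum;
* the occupancy-weighted mean of the state spectra equals the unweighted
  spectrum (the per-window weights of the states sum to one by
  construction).

Band maps average power in named bands (delta 1–3, theta 4–7, alpha 8–12,
beta 13–30, gamma 60–90 Hz; a `"feature"` preset widens delta to 1–4 Hz, a
band convention used for regional feature analyses) and express each state
relative to the mean over states, so relative maps average to zero across
states. Since state inference runs on ≤ 35 Hz data, a gamma-band map is only
meaningful when the spectra are computed on an unfiltered copy of the data.

DPSS tapers are computed from the standard symmetric tridiagonal
eigenproblem; no numerical integration is involved and the first taper of a
2 s window at bandwidth parameter 2 matches textbook concentration values.

## Matching states across recordings

Models fitted independently (e.g. on rest and on task baselines) are
matched by correlating band-wise spatial power maps across parcels
(Pearson), averaging the correlation matrices over bands, and clustering
all $2K$ states hierarchically (Euclidean distance, Ward linkage). The
clustering features are rows of the *joint* $2K \times 2K$ correlation
matrix, i.e. every state is described by its correlation with all states of
both models in one coordinate frame; identical states then merge at height
zero regardless of labelling. Cross-model pairs are read off greedily in
order of cophenetic merge height, removing both members after each match,
with ties broken by state index.

## Gamma quantification

Induced gamma is measured with the standard high-frequency recipe: 300 ms
windows stepped by 50 ms, 2 Slepian tapers, 40–100 Hz, power averaged over
the ROI parcels (the cuneus stand-ins by default). Each trial is normalised
to percent change against its own pre-stimulus baseline (window centres in
−0.5 to −0.2 s). The individual gamma band is the peak of the
trial-averaged normalised response within 42–74 Hz (±10 Hz), the response
window 0.6–2.0 s after stimulus onset; all are configurable. Windows are
centred on their time stamps, and a window is assigned to the baseline when
its centre falls inside the baseline interval. Peak detection operates on
the trial average, not single trials, because single-trial spectra at this
window length are too noisy to anchor a band. All averaging steps are
linear, so the mean of per-trial amplitudes equals the amplitude of the
trial-averaged representation — a property the tests check directly.

## Inferential layer

* **Between subjects:** each state's mean posterior probability over the
  recording is correlated (Spearman) with the subject's trial-averaged
  gamma amplitude; the two-sided p-value comes from randomly permuting one
  vector, with the `(1 + #{...}) / (1 + n)` small-sample correction.
  10,000 permutations by default.
* **Within subjects:** per-trial state weights are the mean posterior over
  the final 106 ms before stimulus onset (the scale of one mean state
  lifetime; a configuration value, not a constant of nature). Weighted
  trial averages per state feed a Friedman omnibus test and
  Bonferroni-corrected pairwise post-hoc tests. The post-hoc default is the
  *paired* signed-rank test because the compared values are within-subject;
  the unpaired rank-sum variant is available since conventions differ.
  Fully tied inputs are reported as p = 1 rather than NaN.
* **Pseudo-states:** as a univariate control, trials can be binned into
  quantile groups of pre-stimulus band power (Hilbert envelope over a
  region); ties share the bin of the lowest tied rank, so degenerate input
  collapses into bin 1 with a warning.
* **Effect-size comparison:** the trial × state occupancy matrix is reduced
  to its first principal component (sign fixed so the dominant loading is
  positive — otherwise bootstrap correlations could flip sign between
  runs), and both PC score and amplitude are split into subject means and
  within-subject residuals. Subject-mean correlation = between effect;
  residual correlation = within effect. Subjects are resampled with
  replacement (1000 draws; trials travel with their subject; draws with
  fewer than two distinct subjects are redrawn and counted) and effects are
  compared by the fraction of draws in which one absolute correlation
  exceeds the other. Additional subject-level predictors (e.g. rest-session
  occupancies) ride along in the same bootstrap.

## The synthetic cohort

The generator's defaults are the reference study conditions: 15 subjects,
50 parcels at 250 Hz, K = 4 states, 2–4 s baselines (with the first second
later stripped, since in a real task it would carry the previous trial's
button-press activity), post-stimulus periods of 3–5 s, subject gamma peaks
uniform in 42–74 Hz, and bursts confined to 0.6–2.0 s after stimulus onset.
States are sets of narrow-band oscillators — band-passed white noise gated
by state occupancy — on region-based parcel sets; the default four states
mimic the qualitative physiology (a centro-parietal delta state with an
occipital alpha deficit, an occipital alpha state, a frontal theta state, a
central beta state). Mean state lifetime under the default self-transition
of 0.96 is 25 samples = 100 ms, the scale reported for empirical baseline
states.

Between-subject structure comes from Dirichlet jitter of the base
transition matrix (concentration 150 by default, giving an occupancy SD of
roughly 0.04–0.06 for the enhancing state — the literature does not report
this quantity, so it is a calibration choice made once). Gamma-burst
amplitude is `base + coupling_between * (FO_enh − 1/K) + coupling_within *
1[pre-stimulus state = enhancing] + subject noise + trial noise` with
defaults 1, 3, 0.4, 0.05 and 0.15: the between-subject term dominates the
within-subject term, mirroring the empirical ordering of the two effects.
All randomness derives from one master seed through a documented hashing
scheme (`derive_seed`), so any subject or trial can be regenerated in
isolation.

What the generator does **not** emulate: sensor-level physics (field
spread, beamforming leakage and its orthogonalization), physiological
artifacts (eye blinks, cardiac components), non-Markovian state dynamics,
1/f background spectra, and any behavioural/attentional covariate. Passing
recovery tests on this cohort therefore demonstrates the pipeline's
correctness, not that real recordings satisfy the generative assumptions.

## Numerical choices worth knowing

* **Band-pass filter:** a zero-phase FFT-mask filter rather than a
  recursive (Butterworth-style) design. At a 1 Hz corner, recursive filters
  leave multi-second edge transients (a constant input leaks through at the
  percent level) and their transition bands make repeated filtering change
  the signal by several percent RMS; the spectral mask rejects DC exactly
  and is exactly idempotent. The trade-off — ringing around sharp
  transients — is immaterial for band-limiting before state inference.
* **Sign alignment** across subjects maximises the summed pairwise
  correlation of vectorised lagged cross-covariance stacks by greedy
  per-(subject, parcel) flipping with random restarts (the all-`+1` start
  is always included). The objective is invariant to flipping *all* of a
  subject's parcels — covariance cannot see a global sign — so results are
  defined up to that equivalence class, and a cohort-wide sign inversion
  leaves the solution unchanged.
* **Segment bookkeeping** uses half-open `[start, end)` intervals with
  1-based starts throughout.
* **Lifetimes and intervals** exclude runs truncated by segment boundaries
  (their duration is censored); intervals are gaps between consecutive
  visits within a segment.
* **Quantile binning** uses minimum ranks so ties are deterministic.
* **The pre-stimulus weight window** is `floor(window_s * fs)` final
  samples of each baseline segment (26 samples at the 106 ms default and
  250 Hz).

## Problem sizes

The test-suite and acceptance-script cohorts use 15 subjects, 10 parcels
and 24–30 trials per subject with rest sessions disabled — enough planted
structure for every recovery check while keeping a full pipeline run at
well under a minute. The matching check runs six seed pairs on a planted
4-state recording of 80 s; the dynamics check uses a $10^6$-sample chain.
These sizes are the package's own validation choices; the generator's
defaults (above) describe the full-scale reference conditions.

## Limitations

* The pipeline evaluates association, not out-of-sample prediction: no
  model trained on rest data is applied to unseen task data.
* Gamma quantification targets amplitude only; response frequency and
  latency are untouched.
* EM point estimates carry no posterior uncertainty over HMM parameters;
  restarts mitigate but cannot exclude local optima.
* The within-subject analysis inherits the uniform-posterior dilution at
  baseline ends described above; with short pre-stimulus windows this
  biases soft weights towards uniformity and thus the within-subject effect
  towards zero (conservative).

## A minimal session

```{r example}
library(gammastates)

cfg <- cohort_config(n_subjects = 15, n_parcels = 10, n_trials = 30,
                     rest_duration_s = 0, seed = 1)
cohort <- generate_cohort(cfg)

analysis <- analyze_cohort(cohort, hmm_config(K = 4, seed = 1),
                           n_perm = 2000, n_boot = 1000)
enhancing_state_summary(analysis)

# state power topographies of the fitted model
spectra <- weighted_multitaper(analysis$concat, analysis$hmm$gamma)
plot_band_maps(band_maps(spectra, spectral_bands()[c("delta", "theta",
                                                     "alpha", "beta")]))

# bootstrap comparison of between- vs within-subject effects
autoplot(analysis$effects)
```
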