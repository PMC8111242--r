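# gammastates

Links spontaneous sub-35 Hz brain-network dynamics to stimulus-induced
gamma responses in parcel-level electrophysiological (M/EEG-style)
recordings.

Visual stimuli evoke narrow-band gamma oscillations (individual peaks
between roughly 42 and 74 Hz) in occipital cortex, but their amplitude
varies widely across people and across trials. This package implements a
pipeline for asking whether that variability is foreshadowed by slower,
spontaneous network activity:

1. **State inference.** Band-pass (1–35 Hz), z-score and concatenate the
   pre-stimulus baselines (or rest recordings) of all subjects; fit a
   time-delay embedded Gaussian hidden Markov model (TDE-HMM: ±7 lags, PCA
   to 2 × parcels, K = 4 states, maximum-likelihood EM with exact
   forward–backward recursions in compiled code). Each state *k* gets a
   per-sample posterior probability γₜ⁽ᵏ⁾.
2. **State description.** State-weighted multitaper spectra via the
   normalised weights ρₜ⁽ᵏ⁾ = γₜ⁽ᵏ⁾ / (Σₜ γₜ⁽ᵏ⁾ / T), summarised as
   band-limited power maps relative to the state mean; fractional
   occupancy, lifetimes and interval times; matching of independently
   fitted models by power-map correlation plus Ward/Euclidean hierarchical
   clustering.
3. **Gamma quantification.** Sliding-window multitaper time–frequency power
   (300 ms / 50 ms / 2 Slepian tapers, 40–100 Hz) over the ROI, percent
   change against the −0.5 to −0.2 s baseline, individual peak ±10 Hz,
   response window 0.6–2 s → one amplitude per trial.
4. **Coupling statistics.** Between subjects: permutation-Spearman
   correlation of state occupancy with trial-averaged amplitude. Within
   subjects: soft trial grouping by mean pre-stimulus (−106 to 0 ms) state
   probability, Friedman omnibus + Bonferroni post-hoc tests, pseudo-state
   (quantile power) controls. Effect sizes: PC1 of the trial-occupancy
   matrix, split into subject means vs within-subject residuals, compared
   through a 1000-draw subject-level bootstrap.

Since such datasets are rarely shareable, the package includes a fully
seeded synthetic-cohort generator that plants Markov state dynamics,
state-specific spectral topographies, and state-coupled gamma bursts — so
every stage of the pipeline has a ground-truth recovery test.

## Worked example

```r
library(gammastates)

cfg <- cohort_config(n_subjects = 15, n_parcels = 10, n_trials = 30,
                     rest_duration_s = 0, seed = 1)
cohort <- generate_cohort(cfg)

analysis <- analyze_cohort(cohort, hmm_config(K = 4, n_restarts = 2,
                                              max_iter = 30, seed = 1),
                           n_perm = 2000, n_boot = 1000)
enhancing_state_summary(analysis)
```

```
# A tibble: 1 × 7
  enhancing_hmm_state label_agreement between_r between_p friedman_p enhancing_is_largest frac_between_gt_within
                <int>           <dbl>     <dbl>     <dbl>      <dbl> <lgl>                                 <dbl>
1                   1           0.627     0.946  0.000500     0.0282 TRUE                                      1
```

Reading the row: the generator's "gamma-enhancing" state was recovered as
HMM state `enhancing_hmm_state` (decoded labels agree with the planted path
on `label_agreement` of samples). Subjects who occupy that state more show
larger trial-averaged gamma responses (`between_r`, permutation p
`between_p`); trials beginning in that state have the largest weighted-mean
amplitude (`enhancing_is_largest`), with the Friedman omnibus rejecting at
`friedman_p`; and the subject-level bootstrap ranks the between-subject
effect above the within-subject one in `frac_between_gt_within` of draws —
the ordering planted by the generator (`coupling_between` dominates
`coupling_within`).

Other entry points: `weighted_multitaper()` + `band_maps()` +
`plot_band_maps()` for state topographies, `state_lifetimes()` /
`fractional_occupancy()` / `timelocked_fo()` for dynamics,
`power_map_correlation()` + `hierarchical_match()` for cross-model state
matching, `quantify_gamma()` for the TF stage, and
`effect_size_comparison()` with `autoplot()` for the bootstrap effect
comparison. Fitted models support `tidy()` and `glance()`.

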