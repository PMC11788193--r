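---
title: "Inferring seizure risk states and state-dependent stimulation effects from hourly RNS telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring seizure risk states and state-dependent stimulation effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnstates)
```

## The problem

Brain-responsive neurostimulation devices for drug-resistant focal epilepsy
store continuous hourly counts of interictal epileptiform activity (IEA)
and of *long episodes* (LE) — detections of epileptiform activity that
outlast a preset duration and serve as a proxy for electrographic seizures.
IEA waxes and wanes on circadian and multidien (multi-day) cycles, and
seizure likelihood tracks the phase of those cycles. `rnstates` implements
a two-stage analysis of such telemetry:

1. **Risk-state inference.** Hourly IEA counts are z-scored and band-pass
   filtered into five period bands (24 h and 7, 15, 20, 30 days, each
   spanning 0.8–1.2 × the nominal period). The instantaneous phase of each
   band, obtained from the Hilbert analytic signal, is shifted by π so the
   rising half of each cycle occupies (0, π). The five shifted phases plus
   log(1 + LE count) are reduced by PCA, and two- and three-state
   multivariate Gaussian hidden Markov models (HMMs) are fit per patient to
   the leading principal components. The state count is chosen by the
   cohort-summed AIC, state labels are made identifiable (the high-risk
   state is the one with the largest mean LE count), and per-hour states
   are decoded from the smoothed posterior. Decoded states are validated by
   Wilcoxon rank-sum tests on hourly LE and IEA counts.

2. **State-dependent transition modelling.** For each hour, the therapy-1
   stimulation parameters (charge density, frequency, pulse width, burst
   duration, averaged across the two bursts) are categorized against the
   manufacturer-recommended baseline settings. A mixed-effects logistic
   regression then models the probability that the *next* hour is low-risk,
   conditional on the current state, within strata defined by lead location
   (mesiotemporal vs neocortical) and stimulation montage
   (monopolar/lead-to-lead vs bipolar), with a per-patient random intercept
   and a per-patient random slope on scaled days since implant. Inference
   uses Wald 95% CIs with Holm control across the fixed terms of each fit,
   plus Nakagawa marginal/conditional R² on the logit scale.

Because the original clinical-trial telemetry is proprietary, the package
ships a seeded synthetic-cohort generator with full ground truth, so every
stage is testable end to end.

## The synthetic cohort generator

`simulation_config()` fixes the study conditions; `simulate_cohort()`
draws one hourly table per patient plus a ground-truth sidecar.

* **Counts.** IEA is Poisson with log intensity
  `log(base rate) + Σ_b A_b sin(2π t / P_b + φ_b) + bump · 1{high}`;
  LE is Poisson at 0.3/h (low state) or 0.8/h (high state), the by-state
  hourly means reported for this device population. The base rate is
  40.9/h. The state bump on IEA is small (0.15 on the log scale): most of
  the IEA contrast between states comes from phase-locking, and a large
  intrinsic bump would inject a state square wave into the multidien bands
  and corrupt their filtered phases.
* **Latent chain.** The next-hour state follows
  `logit P(low) = baseline(current) − coupling · rising + patient effect +
  stimulation effects`, with baselines derived from the configured mean
  dwell times (`logit` of the stay/leave probability) and `rising` the
  rising-phase indicator of a designated coupling band. Positive coupling
  makes rising-phase hours high-risk-prone, the direction reported for
  seizure timing relative to multidien IEA cycles.
* **Defaults.** The default conditions couple the state strongly
  (coupling 5) to the dominant 30-day cycle, with asymmetric baseline
  hazards (mean dwell 2000 h low / 25 h high *in the absence of phase
  forcing*). Under forcing this produces phase-locked states with realized
  dwells of a few hundred hours — multi-day risk episodes. This regime was
  chosen deliberately: a 2-state Gaussian HMM on five near-uniform phase
  features plus a sparse LE feature structurally prefers a half-split of
  the slowest phase dimension (a uniform phase split gains ≈ 0.7 nats per
  hour against ≈ 0.05 nats per hour for the 0.3-vs-0.8 LE rate contrast,
  and slower splits pay less chain entropy). Ground truth that is not
  phase-locked to the dominant slow cycle is therefore unidentifiable to
  the method, whereas the phase-locked regime both matches the scientific
  premise (risk states defined in relation to cycle phase) and keeps the
  generator's truth recoverable.
* **Stimulation schedules.** Therapy-1 parameters are stepwise-constant
  within sub-periods of each programming epoch (each epoch ≥ 720 h, the
  30-day inclusion threshold), drawn over the evaluated ranges. Sub-period
  changes are sometimes programmed mid-hour and emitted as timestamped
  change events to exercise the start-of-hour imputation rule. Hours are
  independently stimulation-disabled with probability 0.12 (the cohort
  figure of 88.1% stimulated hours), and detection counts occasionally hit
  zero, exercising the zeroing rule.
* **What it does not emulate.** No raw ECoG, no detector model, no
  detection-setting changes, no parameter co-dependencies (in practice low
  frequencies pair with long bursts), no montage-specific effect profiles
  unless configured. Passing recovery tests on this generator shows the
  pipeline is correct and well calibrated under its assumptions; it cannot
  show that real seizure risk follows a two-state Markov chain.

## Numerical and design choices

* **Filtering.** First-order Butterworth band-pass, applied forward then
  backward so the net filter has zero phase lag — phase is interpreted
  downstream, so phase distortion must be avoided. Series are
  reflect-padded by `min(3 × high edge, length − 1)` samples to suppress
  transients on epoch-length series. Filtering and phase extraction run per
  contiguous recording segment (the Hilbert transform is invalid across
  gaps); programming-epoch boundaries do not interrupt a segment.
* **Standardization.** IEA z-scoring is per segment. log-LE uses
  `log(1 + count)` since zero counts are ubiquitous.
* **PCA.** Fit per patient on the concatenated feature rows (centred,
  unit-scaled columns), matching the per-patient HMMs; phases are treated
  as linear variables, exactly as in the source analysis. The number of
  components retained defaults to five, and the smallest number reaching
  80% cumulative explained variance is reported as a diagnostic.
* **HMM.** Log-space forward–backward (no underflow up to 10⁵ hours) with
  the chain restarting at segment boundaries; covariances regularized by
  `1e-6 × mean feature variance` on the diagonal; k-means initialization
  with jittered restarts under a fixed seed stream; posterior (smoothed)
  decoding for downstream use, Viterbi retained for exhaustive-enumeration
  cross-checks. For K = 3 the relabeling tie among the two non-LE states is
  resolved by the unweighted mean shifted phase over all five bands; exact
  ties fall back to mean IEA.
* **Transition models.** Hours without stimulation map to every reference
  category, so the intercept reads as the baseline transition rate in the
  absence of stimulation. The random-effects reading of "patient and days
  since implant" is a per-patient random intercept plus an independent
  per-patient random slope on scaled days; days also enters as a fixed
  effect. Estimation is by Laplace approximation (`lme4::glmer`); strata
  with too few patients or rows fall back to fixed-effects logistic
  regression, and the bipolar–neocortical stratum additionally uses
  continuous (centred/scaled) parameter values, mirroring the low-sample
  treatment in the source analysis. The Holm family is all non-intercept
  fixed terms of one fit; the intercept is never adjusted. CIs are Wald on
  the log-odds scale. R² uses the Nakagawa logit-link decomposition with
  `σ²_fixed` the sample variance of the fixed linear predictor and
  `σ²_random` the summed random-effect variances.
* **Open calls made here.** PCA per patient (not per epoch); z-scoring per
  segment; untrialled categories reported as "Not trialed" rather than
  silently dropped; quasi-complete separation is flagged with a warning and
  the affected term left in place rather than removed.

## Problem sizes in the shipped tests

The test-suite and acceptance-script simulations are sized so the whole
pipeline runs in minutes on one CPU: recovery fits use sequences of
800–5000 hours, pipeline runs use 2-patient cohorts of 4320 hours, the
state-count selection study uses 20 seeds × 3 patients × 800 hours, and
the odds-ratio coverage study uses 50 replicates of 10 patients × 1000
hours with a fast symmetric chain (mean dwell 30 h) so that transition
events are plentiful. Effect sizes, rates and thresholds are never scaled
— only the number of patients and hours.

## Known limitations

* The ≥ 95% state-recovery level quoted for the HMM applies to
  well-separated emissions (means ≥ 4 within-state SDs apart). On the full
  pipeline's phase + log-LE features under the default LE rates
  (0.3 vs 0.8/h), the information ceiling is lower: even an HMM whose
  emission parameters are fit on the true states decodes ≈ 89–95% of
  hours, and the unsupervised pipeline typically reaches 55–90%
  (antipodal orientations of a slow-phase split are nearly
  likelihood-equivalent, so the EM solution's alignment with the true
  boundary varies across realizations). The
  acceptance script reports the pipeline's realized agreement alongside
  the well-separated benchmark.
* Phases are treated as linear, not circular, in both PCA and the Gaussian
  emissions; the wrap at 0/2π blurs state boundaries slightly.
* The transition models assume effects are constant over time within an
  epoch and include no interactions or look-ahead horizons beyond one
  hour.
* LE-to-seizure correspondence is consumed as an annotation; the package
  never computes it.
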