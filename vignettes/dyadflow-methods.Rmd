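---
title: "Methods: behavioural and spectral connectivity statistics in dyadflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural and spectral connectivity statistics in dyadflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadflow)
```

dyadflow implements the statistical pipeline of a dyadic ("social")
Pavlovian conditioning experiment with paired-site electrophysiology. Two
macaques face each other; a conditioned stimulus signals, concurrently, the
subject's own reward probability and the partner's. In the *self-variable*
block the subject's probability takes one of {0.25, 0.5, 0.75} across three
stimuli while the partner's is fixed at 0.2; in the *partner-variable*
block the roles are swapped. A resource-limitation constraint means the two
animals are never rewarded on the same trial. Anticipatory licking during
the stimulus period indexes the subject's subjective valuation of the
upcoming outcome; dual-site field potentials from the medial prefrontal
cortex (MPFC) and lateral hypothalamus (LH) index inter-areal coordination.
The scientific question the statistics serve is whether an intervention
(the drug condition, labelled DCZ, versus vehicle) selectively removes the
influence of the *partner's* reward prospects on the subject's valuation
and weakens the MPFC-to-LH direction of coupling.

The package has four analysis stages — licking, gaze, field-field
coherence, Granger causality — plus a synthetic-data generator that
produces inputs with known ground truth for all of them. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and what the bundled tests do and do not establish.

## Synthetic-data generator

The generator is first-class, tested code: every analysis stage in the test
suite and the acceptance script runs on its output.

**Trials.** `simulate_trials()` realises the block structure exactly: each
stimulus appears `trials_per_block/3` times per block in pseudorandom
order, and a single uniform draw per trial maps to outcomes
(`self`/`partner`/`neither`) with the configured probabilities, so
self-reward and partner-reward are mutually exclusive by construction.
Configurations implying `p_self + p_partner > 1` are rejected.

**Licking.** `simulate_licks()` places lick events as an inhomogeneous
Bernoulli process per 1-ms bin — the simplest process matching a
threshold-crossing detector — at rate `baseline_rate` before stimulus onset
and `baseline_rate + self_slope * p_self + partner_slope * p_partner`
after; under DCZ, `partner_slope` is multiplied by
`dcz_partner_attenuation`. Events are convolved with a 20-ms boxcar
(vibration-sensor envelope) and Gaussian noise of SD `noise_sd` is added.
The published analyses report licking only on a normalised scale, so the
physical effect sizes are free parameters. The defaults — 3 licks/s
baseline, +4 licks/s per unit self-probability, -3 licks/s per unit
partner-probability, attenuation 0.1, noise SD 0.1 — were chosen once, for
two reasons: they give a probability dependence that is clearly detectable
at the standard block size without being trivial (the implied
paired-difference standardized effect in the vehicle partner-variable block
is about 0.5), and the noise floor is small enough that the detector sees
essentially clean pulse edges. What the generator does **not** model: lick
kinematics, consummatory licking after the outcome, reaction times, or any
behaviour of the partner animal.

**Gaze.** `simulate_gaze()` draws a per-trial ROI occupancy from a beta
distribution with condition-specific mean and concentration 20, then emits
500 Hz positions as a two-state (inside/outside ROI) Markov chain with a
150-ms mean dwell, mimicking fixation runs rather than per-sample darting —
real gaze is strongly autocorrelated, and the subsampling-invariance
property of the ROI statistic depends on exactly this feature. A 2%
blink/track-loss rate invalidates samples. Saccade dynamics and pupillometry
are out of scope.

**Field potentials.** `simulate_lfp()` draws each trial's segment (-2 s to
+2 s around onset, 1 kHz) from a vector autoregressive model: every channel
an AR(1) with coefficient 0.9 (most spectral mass below ~20 Hz, crudely
matching the 1/f character of field potentials), plus a directed lag-1
coupling from every MPFC channel onto every LH channel. At stimulus onset
the coupling blocks switch instantaneously to `coupling *
stimulus_coupling_gain` (vehicle) or `coupling * dcz_coupling_gain` (DCZ);
a 200-sample burn-in precedes each segment, and the analyses only use
windows well inside each regime. Because the coupling is feed-forward the
companion matrix is block-triangular, so stability is governed by the AR
coefficient alone and the ground-truth causal direction is MPFC to LH only.
Biophysical LFP generation (volume conduction, laminar structure) is not
modelled.

**Reproducibility.** Every generator derives a labelled RNG stream from the
master seed (`derive_seed(seed, "licks")` etc.), so regenerating one signal
type never perturbs another, and identical seeds give bit-identical output.

## Licking statistics

Licks are detected as upward threshold crossings with a 50-ms refractory
period (the source does not state one; 50 ms prevents double-counting
sensor ripple at 1 kHz while staying well below inter-lick intervals).
Frequencies are counted in the animal-specific 500-ms stimulus epoch
(501-1000 ms or 251-750 ms after onset; a configuration field, not a
hard-coded constant) and z-scored against the 500-ms pre-onset epoch.
Because a per-trial SD of a count over 500 ms is ill-defined, the baseline
mean and SD are pooled across the trials of each (session, block,
condition) cell — the normalisation's grouping is the one genuinely open
choice here, and pooling is the conservative reading. Outlier screening
uses the unscaled 3-MAD rule (`mad_keep()`): no 1.4826 normality factor,
because the rule is stated as a plain MAD threshold; when the MAD is zero
only values equal to the median are kept. Screening is applied to the z
values (after normalisation), the second open choice.

The **licking modulation** is the mean of chronologically paired
differences between preferred trials (highest self-probability, or lowest
partner-probability, depending on block) and non-preferred trials, each
group sorted by trial index and paired positionally. The chronological
pairing absorbs slow within-session trends (satiety, motivation) that
would otherwise inflate the variance of the difference. When group sizes
differ the pairing truncates to the shorter group, preserving the
chronological matching.

The **Monte Carlo permutation test** (`lick_permutation_test()`) pools
preferred trials across the two conditions and non-preferred trials across
the two conditions, then re-splits each pool at random into groups of the
original sizes 1000 times (default), recomputing the modulation per
simulated condition exactly as for the observed data and recording the
simulated intervention effect (simulated vehicle minus simulated DCZ). The
two-sided p-value is `2 * min(tail proportions)` with add-one smoothing;
the coarser published criterion — observed effect above the 97.5th
percentile — is returned as a flag alongside. A Welch t-test on the two
sets of paired differences accompanies the permutation test. Spearman
associations between z-scored frequency and the varying probability use
midranks for ties and exact enumeration for n of 10 or fewer without ties.

A power note for planning: the observed intervention effect is a
difference of two n-pair means, so its standard error is
`sigma_d * sqrt(2/n)` with `sigma_d` the paired-difference SD. At the
standard 40 pairs per group and two-sided alpha 0.05, a standardized
effect of 0.5 on the paired-difference scale therefore carries roughly
50-60% power (0.63 or larger is needed for the conventional 80%); block
counts, not permutation counts, are the binding resource.

## Gaze

`roi_proportions()` is the fraction of valid samples inside the ROI
rectangle (boundary inclusive); blink and out-of-range samples leave both
numerator and denominator, so the statistic is a proportion of *valid*
time. Conditions are compared with a two-sided Welch t-test on per-trial
proportions; the outcome-period comparison is restricted to
partner-rewarded trials. The outcome period is taken as the 1-s window from
partner feedback (its length is not numerically specified in the source;
1 s matches the stimulus period).

## Field-field coherence

Per channel pair, the 4-s trial segments are concatenated into one long
series, notch-filtered at 60 and 120 Hz (zero-phase second-order
Butterworth band-stop, 2 Hz half-width — the filter itself is unspecified
in the source; the series mean is subtracted and restored around the
filter to avoid edge transients), convolved with L2-normalised complex
Morlet wavelets at 24 log-spaced frequencies `2^(k*7/23)`, k = 0..23 (1 to
128 Hz), and re-segmented. The cycle count is fixed at 7, the standard
compromise between time and frequency resolution over this range. Edge
effects at segment joins are accepted: the 4-s segments dwarf the wavelet
support at every analysed frequency above 1 Hz.

Single-trial "coherence" is identically 1, so trial averaging happens at
the spectral level:

$$C(t, f) = \frac{\left|\overline{W_x W_y^*}\right|^2}
{\overline{|W_x|^2}\; \overline{|W_y|^2}}$$

with bars denoting trial means. Maps are kept on the analysis window
(-500 ms to +1000 ms: 1500 x 24 bins), baseline-normalised by subtracting
the mean over the 500 ms before onset per frequency, and the modulation map
is the across-pair average of per-pair DCZ-minus-vehicle differences.

**Cluster significance.** The null is built by subsampling: 200 maps are
drawn (without replacement) from the two conditions pooled along the pair
axis, split 100/100 into simulated conditions, subtracted positionally, and
the 0.5th and 99.5th percentiles over all 3,600,000 resulting values are
recorded; 1000 repetitions give two distributions of percentile values.
Observed bins below the 0.5th percentile of the low-cut distribution (or
above the 99.5th of the high-cut) are candidates; candidates are joined by
8-connected flood fill (edges or corners touching) and components smaller
than 10 bins are pruned. Note an asymmetry inherited from the published
procedure: the null percentiles are taken over raw per-pair difference
values, while the thresholds are applied to the across-pair *mean* map.
This makes the test conservative in proportion to the pair count — the
mean map's noise shrinks with the number of pairs while the thresholds do
not — which is why the specificity property below is comfortably met, and
why detectable effects must exceed roughly `2.58 * sqrt(2) * sigma`, with
`sigma` the per-pair per-bin noise.

`simulate_coherence_stack()` generates synthetic normalised-coherence maps
for exercising this test: temporally smoothed Gaussian noise (20-ms SD
kernel) with per-bin SD 0.025, the delta-method sampling error
`sqrt(2C(1-C)^2/n)` of magnitude-squared coherence for weak coherence
(C about 0.1) estimated from roughly 250 trials. With that noise level a
0.1 coherence drop sits close to the detection threshold
(`2.58 * sqrt(2) * 0.025 = 0.091`), so the bundled sensitivity check
operates near the boundary of what the published procedure can detect —
recovery rates reflect the procedure's conservatism, not an implementation
artefact; with more trials per pair (smaller `sigma`) the same drop is
recovered essentially always.

## Granger causality

The causality analysis uses the 1-250 ms post-stimulus window. Trials are
treated as realisations of one stationary process: lagged regressions are
stacked per trial and never span trial boundaries. The model order is
chosen by AIC (`N log det(Sigma_ML) + 2 p n^2`) over candidates fitted on
identical effective samples, up to 50 samples (50 ms at 1 kHz) in the
full-scale configuration; coefficients come from OLS.

Diagnostics exclude problematic data rather than flagging results:
collinearity via the regressor condition number (threshold 1e10),
nonstationarity via the companion spectral radius (margin 0.02) backed by a
per-channel augmented Dickey-Fuller regression, and heteroscedasticity via
an ARCH LM test on the residuals (lag 10, level 0.01). These thresholds are
conventional defaults; the source names the three problems without
quantifying them.

Autocovariances follow from the companion-form Lyapunov equation (solved by
a doubling iteration) and the Yule-Walker recursion; reduced (sub-process)
models are recovered from the autocovariance sequence by a direct
block-Toeplitz solve, with the lag depth chosen so the autocovariance has
decayed below 1e-9 (capped at 200). Spectral causality uses the Geweke
decomposition: bivariate directly from the pair model, conditional by
premultiplying the full transfer function with the reduced model's inverse
transfer and partialling the source innovations — the conditional mode
collapses to the bivariate formula when the conditioning set is
uninformative, and removes mediated influence in chain topologies (both
are tested). The session pipeline runs in bivariate mode per MPFC-LH pair,
the fallback appropriate for small channel counts; conditional mode is
exposed for denser montages. The frequency grid is 0 to 128 Hz in 1.67-Hz
steps (77 points; the last is 126.92 Hz since the step does not land on
128).

Pair-level inference is the nested-model F-test on the time-domain GC with
Benjamini-Hochberg FDR at Q = 0.05 per (session, condition) family. The
published procedure reports per-frequency proportions of significant pairs
but defines significance through the F-test, leaving the frequency
resolution unspecified; the package's explicit interpretation is that a
pair counts as significant *at a frequency* when it passes FDR and its
spectral GC at that frequency exceeds the median of its own spectrum. This
confines a significant pair's contribution to the frequency range where
its causal power actually concentrates (for the low-frequency-coupled
generator, the delta/theta end), which is the behaviour the session-level
test needs. Session summaries then compare conditions per frequency with a
one-sided paired t-test (DCZ lower), both on proportions and on mean GC
differences.

## Problem sizes used by the tests and acceptance script

The published study's scale (16 MPFC channels, 1632 pairs, 11 sessions,
1000 subsampling repetitions) is not sensible for a test suite, so the
bundled checks run scaled-down study conditions, stated here as the
package's own choices:

* permutation calibration: 300 null experiments, 200 permutations each,
  40 trials per group; power: 200 seeds at the generator defaults with the
  DCZ partner effect fully attenuated (paired-difference effect d of about
  0.5);
* cluster test: stacks of 200 maps, 100 subsampling repetitions; 100 null
  datasets for specificity, 50 seeds for sensitivity of an injected 0.1
  drop over 100 ms x 3 bins;
* causality: AIC recovery on VAR(5) at n = 10,000 over 50 seeds; the
  end-to-end study uses 11 sessions, 12 trials per condition, 2 MPFC and
  2 LH channels, baseline coupling 0.12 with gains 1 (vehicle) versus 0.2
  (DCZ), order search to 10 — calibrated by pilot simulation so that the
  vehicle condition sits clearly above the FDR threshold while the DCZ
  condition straddles it, which is the regime where the per-frequency
  proportion test is informative.

Passing these checks establishes that the statistics do what they claim on
data satisfying the generator's assumptions (Poisson-like licking,
beta-distributed gaze occupancy, linear Gaussian VAR field potentials with
an instantaneous regime switch). They do not establish robustness to
features real recordings have and the generator lacks: nonstationary
oscillatory bursts, 1/f-mismatched spectra, shared-reference artefacts,
movement contamination, or nonlinear coupling.

## Worked example

```{r example, eval = FALSE}
cfg <- study_config(
  seed = 5, n_perm = 200, n_rep = 100,
  task = task_config(trials_per_block = 30, n_sessions = 2)
)
report <- run_study(cfg, out_dir = "study-out")
str(report$behavior$`partner-variable`$permutation)
```

Each stage is also callable on its own; `tidy()`, `glance()` and
`autoplot()` methods summarise and draw the permutation, cluster and
session-causality results.

## Known limitations

* The subsampling cluster test inherits the mean-versus-per-pair threshold
  asymmetry discussed above; a max-statistic permutation test would have
  calibrated sensitivity but is out of scope.
* Spectral causality is parametric (MVAR); nonparametric and state-space
  variants are out of scope.
* The conditional GC reduced model is recovered from a truncated
  autocovariance sequence; for spectral radii very close to 1 the
  truncation error grows and the bivariate mode is preferable.
* Per-frequency causality significance is an explicit interpretation (FDR
  pass plus above-own-median spectrum), stated here because the published
  description does not fully specify it.
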