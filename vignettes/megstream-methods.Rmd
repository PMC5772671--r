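---
title: "Decoding bistable auditory percepts from MEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding bistable auditory percepts from MEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A continuous stream of A-B-A tone triplets (A = 1414 Hz, B = 1000 Hz;
100 ms tones, 50 ms gaps, 200 ms silence; 600 ms per trial) is perceptually
bistable: listeners alternately hear a single "gallop" rhythm or two
segregated streams, and report the current percept by holding one of two
buttons. The physical stimulus never changes, so any systematic difference
in the evoked magnetic field between report states is a neural correlate of
the subjective percept. `megstream` implements the complete analysis chain
needed to test for such differences at the single-subject and group level —
and, because no public dataset accompanies this paradigm, a synthetic-data
generator with a known planted ground truth against which every stage of
the chain can be validated.

## Generative model of a synthetic recording

A recording is produced in five steps:

1. **Percept dynamics.** A two-state renewal process: dominance durations
   are i.i.d. lognormal(`mu_log`, `sigma_log`) and states strictly
   alternate. Defaults `mu_log = log(4)`, `sigma_log = 0.7` (log-seconds)
   give a median dominance of 4 s and a right-skewed duration distribution
   that becomes normal under log transform, the canonical signature of
   bistable switching. A Markov chain adds nothing for two states under
   forced alternation, so the renewal form is used.
2. **Stimulus timeline.** Trials tile each block exactly
   (`block_s * 1000 / trial_ms` per block); blocks are laid out as
   independent contiguous segments and no epoch ever crosses a block
   boundary.
3. **Source activity.** Each trial stamps a fixed evoked waveform (one
   biphasic deflection per tone, Gaussian bumps at ~50/~100 ms after tone
   onset) on three temporal-cortex sources. Trials falling in a
   "segregated" segment additionally receive a constant
   `effect_amplitude` on the two right-temporal sources inside the
   250–267 ms window. The effect is **additive** on source amplitude —
   the simplest mechanism producing an additive difference of evoked
   time courses, which is exactly what the downstream statistics test.
4. **Forward projection.** `data = L %*% S + noise`, with `L` a
   unit-column-norm Gaussian lead field by default (any matrix can be
   supplied). Head modelling is deliberately out of scope: the statistics
   under test are agnostic to how `L` was obtained.
5. **Button reports.** The true percept sequence is re-emitted as a button
   stream with each switch delayed by a truncated-Gaussian motor latency
   (mean 400 ms, SD 100 ms, floor 0) — reports lag perception, which is why
   the analysis later discards switch-adjacent trials. Ambiguous "none" /
   "both buttons" segments can be injected for testing the exclusion logic.

Everything is driven by one master seed; identical `(config, seed)` pairs
give bit-identical recordings, and the planted effect is exactly
recoverable from noiseless data (this is asserted in the test suite).

### What the generator does not emulate

Sensor physics (gradiometer geometry, noise spectra, environmental
artifacts), head movement, physiological artifacts, inter-subject
anatomical variability, and any nonstationarity of the percept process.
Consequently, passing tests demonstrate that the *statistics and
bookkeeping* of the pipeline are correct and calibrated — not that the
pipeline is robust to every pathology of real MEG data.

### Effect size and noise

The default `effect_amplitude = 0.3` against unit sensor noise was chosen
once so that a synthetic cohort lands in the weak-decoding regime
characteristic of perceptual-state MEG experiments: single-trial accuracies
in the low-to-mid 50% range with multivariate tests significant in most
subjects. A tenfold larger amplitude makes every stage trivially
significant and would validate nothing about behaviour near threshold.

## Preprocessing

The fixed order is filter → downsample → label → exclude → epoch →
baseline-correct → robust-average.

* **Filtering.** Separate 5th-order Butterworth low-pass (30 Hz) and
  high-pass (0.1 Hz) filters, applied forward–backward (zero phase, so the
  effective magnitude order doubles). Each block is filtered independently.
  A 0.1 Hz high-pass has a multi-second impulse response, so the
  forward–backward pass uses odd-reflection padding of ~3 time constants;
  without it the edge transient of a 5-minute block reaches tens of percent
  of signal amplitude. After filtering, decimation to 300 Hz (integer
  factor; a polyphase resampler with a warning otherwise), rescaling event
  indices.
* **Labelling.** A trial is labelled with the one percept held over its
  entire 600 ms window; mixtures, "none" and "both" are `ambiguous`.
* **Switch-adjacent exclusion.** "Immediately before and after a switch" is
  read literally as one trial on each side (`n_exclude = 1`, configurable):
  for each label change between consecutive unambiguous trials, the last
  trial of the old state and first of the new are dropped.
* **Baseline.** The stimulus is continuous — there is no silent
  pre-stimulus interval — so the default baseline is the whole-epoch mean
  per trial and channel (any sub-window can be configured).
* **Robust averaging.** Iteratively reweighted mean per channel and
  timepoint with Tukey bisquare weights,
  `w = (1 - (r/(k*MAD))^2)^2` for `|r| < k*MAD` else 0, `k = 4.685`
  (95% Gaussian efficiency), residuals scaled by the across-trial MAD,
  iterated to `1e-6` or 20 iterations. If every trial is rejected at a
  timepoint the estimate falls back to the median with a warning. With
  identical trials the weights are identically 1 and the result equals the
  plain mean.

## Spatio-temporal SVD features

The pooled (both-percept) epochs are reduced without ever consulting the
labels: SVD of the channels × (trials·samples) unfolding gives 5 spatial
modes; SVD over samples of the pooled projected data gives 5 temporal
modes; each trial becomes a 5 × 5 coefficient matrix flattened
spatial-major into 25 features. Unfolding on pooled single trials (rather
than on averages) is one of two defensible readings of "combined" data;
it is exposed rather than hidden, and the alternative can be obtained by
averaging upstream. SVD sign ambiguity is fixed deterministically (the
largest-|·| element of every basis vector is made positive) so results are
exactly reproducible. Features are not z-scored by default (an option
exists); classes are balanced first — the majority percept is subsampled to
the minority count, either at evenly spaced positions over the acquisition
(`spread`, default) or from the start (`sequential`, the robustness check).

## Canonical variate analysis

For features `X` (n × p) and a binary class indicator, the treatment
(between-class) and residual (within-class) SSP matrices give generalized
eigenvalues of `W^{-1}B`; Wilks' Λ = Π(1+λᵢ)⁻¹, with at most
min(p, q) = 1 nonzero eigenvalue for two classes. Significance:

* **Bartlett** (default, reported as `chi2`):
  χ² = −(n − 1 − (p+q+1)/2)·ln Λ on p·q degrees of freedom.
* **Rao's F** (always also reported): F = ((1−Λ)/Λ)·(n−p−1)/p on
  (p, n−p−1) degrees of freedom — *exact* for q = 1, and identical to the
  pooled-variance two-sample t-test when p = 1.

The test suite verifies Λ against the determinant identity
det(W)/det(W+B), the t-test equivalence at p = 1, affine invariance of
(Λ, χ², p) under invertible feature transforms, and null calibration at
n = 200, p = 25. Bartlett's approximation is mildly anticonservative at
those dimensions (its rejection rate sits just above the nominal 5%),
which is why the exact-F variant exists and is used where exactness is
asserted. A singular residual matrix is ridge-regularized by
`1e-8 · trace(W)/p` with a warning; n ≤ p + 2 is refused with advice to
reduce the number of modes. Per-subject screens use α = 0.05 uncorrected,
matching the convention of reporting one collapsed test per subject.

## SVM classification

Stratified 10-fold cross-validation, re-randomized over 100 repetitions
(both configurable); the reported rate is the mean held-out accuracy over
repetitions. Stratification preserves the (already balanced) class ratio in
every fold. The RBF kernel is
`K(x,x') = exp(−‖x−x'‖² / (2·s²))` with `s` the *kernel scale* — stated
explicitly because libraries disagree on the γ ↔ scale convention
(`gamma = 1/(2 s²)` underneath). Hyperparameters come from a two-stage
9 × 9 log-spaced grid search: stage 1 spans s ∈ [1e−3, 1e15] and
C ∈ [1e−3, 1e9], one single 10-fold CV per point under a shared fold
assignment; stage 2 re-searches ±1 stage-1 grid step around the winner
(clipped at the stage-1 bounds when the winner lies on an edge) with a
fresh fold assignment. Ties prefer the smallest box constraint, then the
smallest kernel scale — the least flexible model.

Above-chance inference uses the one-sided binomial tail with
k = round(accuracy · n) at chance 0.5 (classes are balanced). This test
inherits the optimism of treating cross-validated trials as independent;
it is reproduced as the primary inference deliberately, and
`permutation_pvalue()` provides a calibrated alternative built from
label-permutation nulls.

## Minimum-norm source analysis

Sensor epochs are first reduced to their top 16 temporal SVD modes (pooled
over retained trials), then mapped through the ridge-form minimum-norm
operator `J = L'(LL' + λI)^{-1} Y`, algebraically identical to
`(L'L + λI)^{-1} L' Y`. The default regularization
λ = trace(LL')/(n_sensors · SNR²) with SNR = 3 is the standard
noise-power heuristic; any λ > 0 can be supplied. "Posterior variance" of a
source is the variance of its reconstructed time course pooled over
retained trials (the per-condition alternative would differ only under
strong imbalance). Unconstrained analyses greedily select the five
highest-variance sources subject to a 15 mm minimum separation;
ROI-restricted analyses take the best source inside a 10 mm sphere (radius
configurable; the three a-priori spheres sit at rAC (54, −14, 11),
lAC (−49, −20, 5) and rPIPS (34, −72, 38) — the rPIPS z-coordinate is
typeset ambiguously in the source table and (34, −72, 38) is adopted,
configurable). A single-source ROI yields 5 temporal-mode features;
multi-source analyses reuse exactly the sensor-level 5 × 5 path, so
sensor and source pipelines share all downstream code.

## Group-level time-course statistics

Per subject, PCA over right-temporal channels of the two robust-averaged
evoked responses concatenated in time yields one shared spatial component
(a per-state PCA is available; the joint default keeps both time courses
in a common basis so their difference is interpretable). The
gallop-minus-segregated component time courses (180 samples, 0–600 ms at
300 Hz) are stacked across subjects and tested pointwise with one-sample
t-tests; runs exceeding the two-sided p < 0.005 threshold form clusters
scored by mass (summed |t|). Family-wise error is controlled at
p < 0.05 against the max-cluster-mass distribution from random sign flips
of whole subjects — flipping entire time courses preserves each subject's
temporal autocorrelation, making the null assumption-free and directly
verifiable by simulation (the suite measures the realized FWE rate). This
is a deliberate methodological substitution for parametric random-field
cluster inference, whose assumptions the synthetic data need not honour.
Cluster bounds are reported half-open in ms, `[start, end)`, mapped by
`t = i/300` s. Published analyses of this paradigm print the significant
window variously as 250–267 ms and 250–273 ms; the package reports
whatever its own cluster test finds.

For a synthetic *cohort*, one template lead field is shared across
subjects by default: with independent random lead fields the planted
effect's sensor-level polarity is random per subject and group averaging
would cancel it — the shared template stands in for the common anatomy
that aligns effect polarity across real listeners.

## Numerical choices and degenerate inputs

* Filter padding: odd reflection, `3/f_c` seconds, capped by data length.
* SVD sign fixing as above; rank deficiency reduces `k` with a warning.
* Robust averaging with zero MAD (identical trials): weight 1 where the
  residual is zero, 0 elsewhere.
* CVA: ridge fallback for singular `W`; refusal for n ≤ p + 2.
* Grid search: ties broken toward the simplest model; stage-2 bounds
  clipped at stage-1 limits.
* Cluster permutation: degenerate zero-variance timepoints contribute
  t = 0 rather than NaN; fewer than 100 permutations are refused.
* All randomness flows through named integer seeds via a private RNG
  stream that never perturbs the caller's `.Random.seed`.

## Problem sizes used in the shipped simulations

The package defaults describe the full paradigm (274 sensors, six
5-minute blocks, 600 Hz). The test suite and the acceptance script run the
same code on scaled instances chosen to exercise every stage with
comfortable statistical power on a single CPU: cohorts of 14 subjects with
30 sensors and three 2-minute blocks (~600 trials/subject, ~400 after
exclusion and balancing), 20 cross-validation repetitions, 1000 sign-flip
permutations, and 200–1000 replicate simulations for calibration checks.
These sizes are the package's own choices and are stated here so that any
number produced by the tests can be tied to its design.

## Known limitations

* The binomial above-chance test is anticonservative under CV dependence
  (by design, as the primary inference); use the permutation alternative
  for calibrated single-subject claims.
* The synthetic lead field carries no geometry: source-level *localization*
  performance on real anatomy is untested (and untestable here).
* Robust averaging weights are computed per channel/timepoint
  independently; no spatial or temporal smoothness is imposed.
* Sequential spatial-then-temporal SVD is not globally optimal for a joint
  rank-(5,5) approximation (it is exact when the data truly have that
  rank, which the tests exploit).
* Block-boundary-truncated dominance durations enter uncorrected
  (censoring is ignored), as is conventional for this paradigm.
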