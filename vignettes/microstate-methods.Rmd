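---
title: "Methods: task-based EEG microstate analysis"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task-based EEG microstate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstates)
```

This vignette documents the statistical model behind `mstates`, the exact
procedure each stage implements, every tunable with its units and default,
and the numerical conventions that make runs bit-reproducible. It is the
reference for *why* the code does what it does; the README shows *how* to
run it.

# 1. Model and assumptions

An epoch is a matrix $V \in \mathbb{R}^{C\times T}$ of voltages (µV) over
$C$ channels and $T$ timepoints. The global field power at timepoint $t$ is
the population spatial standard deviation

$$\mathrm{GFP}(t) = \sqrt{\tfrac{1}{C}\sum_c \big(V_{ct} - \bar V_{\cdot t}\big)^2},$$

which separates a scalp map into *shape* ($V_{\cdot t}/\mathrm{GFP}(t)$) and
*strength* ($\mathrm{GFP}(t)$). The microstate hypothesis is that the shape
trajectory is piecewise constant: a small set of template maps, each
dominating a contiguous run of timepoints. The pipeline's assumptions, made
explicit:

- **Polarity matters.** In task ERPs a polarity reversal reflects a
  different generator configuration, so clustering and the cosine statistic
  are polarity-*sensitive*: $v$ and $-v$ are different states and
  $\cos\theta$ can be negative. (Resting-state microstate work often
  ignores polarity; that convention is deliberately not used here.)
- **Shape and strength are analyzed separately.** All topographic inference
  runs on GFP-normalized data; amplitude differences are left to the
  channel-wise post-hoc stage on raw per-epoch averages.
- **Epochs are exchangeable under the null.** The TANOVA permutation scheme
  assumes that, absent a condition effect, condition labels can be
  reassigned to pooled epochs without changing the distribution of the
  statistic.
- **Common time grid.** All epochs share one sampling rate and one analysis
  window, discretized as a half-open interval (section 5).

# 2. The pipeline, stage by stage

## 2.1 ERPs and the grand–grandmean

Per subject and condition, epochs are averaged timepoint-wise
(`averageEpochs`), optionally baseline-corrected over a closed ms interval
(`baselineCorrect`), then GFP-normalized (`normalizeByGFP`): each column is
divided by its GFP so every timepoint has unit GFP. A timepoint whose GFP
falls below the tolerance `1e-12` is an error, not a silent `NaN` — flat
columns mean broken input. The *grand–grandmean* (`grandGrandmean`) is the
plain mean of the normalized subject-by-condition ERPs; by default it is
**not** re-normalized, so its GFP profile shows residual inter-subject
topographic variability. Re-normalization is available
(`renormalize = TRUE`) for users who want the clustering input itself at
unit GFP; the default keeps the averaging step a pure mean. This was a
genuine judgment call; the flag records it.

## 2.2 Topographic clustering and segmentation

`kmeansTopographies` clusters the $T$ timepoint columns with Lloyd's
algorithm under squared Euclidean distance:

- `nRestarts = 50` seeded restarts; each initializes the $k$ centroids from
  $k$ *distinct timepoints* sampled without replacement (real maps, not
  random noise).
- `maxIter = 100` Lloyd iterations per restart; assignment ties go to the
  **lowest cluster id**.
- An empty cluster aborts the restart, which is re-drawn with a fresh
  derived seed and counted (`nReseeds` in the model and in pipeline
  provenance); more than 100 consecutive reseed failures is an error.
- The best restart minimizes the summed within-cluster squared distance
  (`innerDistanceSum`).

The implementation is hand-written because these conventions (data-point
initialization, deterministic tie-break, counted reseeds) are part of the
method's contract; `stats::kmeans` is used in the test suite as an
independent cross-check that the attained objective matches.

`segmentMicrostates` converts the label sequence into microstates: maximal
runs of identical labels, each reported as a half-open `[start_ms, end_ms)`
interval (the end is the last sample plus one sampling step). A
`minDurationMs` (default 0 = off) absorbs shorter runs into the neighboring
run, shortest-first. `sweepK` fits a range of $k$ (default 2–20) and
suggests the knee of the objective curve (largest second difference) —
a suggestion, never an automatic choice, because $k$ selection in
microstate analysis is ultimately a substantive decision.

## 2.3 TANOVA

For one microstate and two conditions A and B:

1. Observed statistic: average each condition's pooled epochs, GFP-normalize
   the averaged ERP, average the normalized columns over the microstate's
   timepoints, and take $\cos\theta$ between the two resulting topography
   vectors (clamped to $[-1,1]$ against rounding).
2. Null: pool all epochs of both conditions, permute, relabel the first
   $n_A$ as A and the rest as B, and recompute the same statistic;
   `nPerm = 3000` times by default. With `stratified = TRUE` the shuffle is
   done within subject.
3. $p = \dfrac{1 + \#\{\text{null} \le \text{observed}\}}{n_\text{perm}+1}$
   (add-one convention, lower tail: topographic *difference* means a *small*
   cosine). The floor is $1/(n_\text{perm}+1)$, i.e. $1/3001$ at the
   default; the convention `"rank"` (no add-one) is available but not
   default because the add-one form is valid (never anti-conservative) at
   any $n_\text{perm}$.
4. Bonferroni over the $M$ microstates: `alphaAdj = alpha / M`
   (e.g. $0.05/18 \approx 0.0028$, $0.05/30 \approx 0.0017$,
   $0.05/41 \approx 0.0012$).

## 2.4 Channel-wise post-hoc tests

For each microstate that survived TANOVA: epoch counts are equalized first
(`equalizeEpochs`, a seeded sorted subsample of the larger condition only),
each epoch is collapsed to its per-channel mean over the microstate's
timepoints, and each channel gets a two-sided paired-by-index t-test
(`stats::t.test`), Bonferroni-corrected over the $C$ channels
($0.05/30 \approx 0.0017$). A channel with zero-variance differences is
reported as *degenerate*: $t = 0$ and $p = 1$ when the mean difference is
zero, rather than `NaN`. `paired = FALSE` switches to Welch tests for
designs without a meaningful epoch pairing.

## 2.5 Reverse power analysis and median split

`achievedPower(n, alpha, d)` is the exact power of a two-sided paired
t-test: with $df = n-1$, critical value $t_c = qt(1-\alpha/2, df)$ and
noncentrality $d\sqrt{n}$, power is
$P(T > t_c) + P(T < -t_c)$ under the noncentral $t$.
`minimalDetectableEffect` inverts this by monotone root-finding
(`uniroot`, tolerance $10^{-12}$): at $n = 107$, $\alpha = 0.05$, power
$0.80$ the minimal detectable $d$ is $0.2733 \approx 0.27$. `medianSplit`
assigns ties to the low group and flags the degenerate all-tied case.

# 3. The synthetic generator

## 3.1 What it emulates

The generator mirrors a visual-task ERP study design: a 30-channel 10-20
montage (`defaultMontage()`), 250 Hz sampling over a $[0, 600)$ ms
post-stimulus window, two within-subject conditions, and per-subject epoch
averaging as the step that pulls the ERP out of single-trial noise. The
default study size — 107 subjects, 16 retained epochs per subject and
condition — matches a realistic retention budget (≈13,600 epochs over 107
subjects and 8 design cells). Ground truth is explicit:

- **Templates** (`makeTemplates`): unit-GFP maps with pairwise angular
  separation ≥ `minAngleDeg` (default 60°), drawn by seeded rejection
  sampling; at exactly 90° a QR construction is used, since exact
  orthogonality has probability zero under rejection. Templates are *not*
  average-referenced — unit GFP alone fixes the scale, and non-centered
  maps keep low-channel-count examples (e.g. two orthogonal maps in two
  channels) well-defined.
- **Timeline** (`tileTimeline` / `makeTimeline`): contiguous half-open
  segments tiling the window, adjacent segments carrying different
  templates; the default 100 ms tiling sits in the conventional 60–120 ms
  microstate-duration range.
- **Envelope** (`defaultEnvelope`): a strictly positive GFP waveform in µV —
  a 2 µV floor plus components near 180 and 400 ms, loosely an ERP's GFP.
- **Effect** (`effectSpec`): in condition B, the templates of the affected
  segments are rotated by *exactly* `angleDeg`. The rotation is closed-form:
  for target cosine $c$ and a zero-mean unit-GFP direction $u \perp v$,
  the rotated map is $\alpha v + \beta u$ with
  $\alpha = c/\sqrt{1 + m^2(1 - c^2)}$, $\beta$ fixed by unit GFP, where $m$
  is the template mean; this preserves unit GFP *and* hits the requested
  angle to ~$10^{-15}$ degrees, so recovered effect sizes can be checked
  against truth without calibration slack. `amplitudeRatio` scales
  condition B's envelope in affected segments.
- **Subject jitter**: additive Gaussian (sd `subjectSd`, default 0.1 on the
  unit-GFP scale) on each subject's templates, renormalized — subjects share
  the microstate architecture but not identical maps.
- **Epoch noise**: i.i.d. Gaussian per channel and timepoint, sd `noiseSd`
  (default 10 µV — larger than the signal floor, so single epochs look like
  EEG: the ERP only emerges by averaging). A channel covariance can be
  supplied (`noiseCov`) for spatially correlated noise.

All randomness derives from one master seed in the `TruthManifest` through a
deterministic seed-derivation function, so a manifest fully determines the
dataset; `writeTruthManifest` serializes doubles at 17 significant digits so
a round-tripped manifest regenerates it bit-exactly.

## 3.2 What it does not emulate

No volume conduction or leadfield physics, no 1/f spectral shape or alpha
rhythm, no artifacts (blinks, muscle), no latency jitter between trials, no
gradual microstate transitions, no learning or fatigue drift across the
session. The generator is a *statistical* ground truth for validating the
analysis chain, not a forward model of EEG.

# 4. Tunables at a glance

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `nSubjects` | 107 | subjects | realistic large-study size; also the power-analysis N |
| `nEpochsPerCondition` | 16 | epochs | ≈ retained-epoch budget per design cell |
| `samplingRate` | 250 | Hz | 4 ms step; 150 samples in [0, 600) |
| `window` | [0, 600) | ms | post-stimulus ERP range |
| `minAngleDeg` | 60 | degrees | well-separated templates; feasible by rejection in 30 channels |
| segment duration | 100 | ms | conventional 60–120 ms microstate duration |
| `noiseSd` | 10 | µV | single-trial SNR < 1; averaging is essential |
| `subjectSd` | 0.1 | unit-GFP scale | visible but architecture-preserving subject variation |
| `k` | user-set | — | substantive choice; `sweepK` only suggests |
| `nRestarts` / `maxIter` | 50 / 100 | — | restarts dominate solution quality for T ≤ a few hundred |
| `nPerm` | 3000 | — | p floor 1/3001, resolves p against α/M down to M ≈ 41 |
| `alpha` | 0.05 | — | Bonferroni-adjusted per family |
| `minDurationMs` | 0 (off) | ms | smoothing changes the estimand; off by default |

# 5. Numerical conventions

- **Half-open time windows everywhere**: a window $[a, b)$ at step
  $\Delta = 1000/\text{rate}$ contains samples $a, a+\Delta, \dots < b$;
  segment and microstate boundaries never double-count a sample.
  `baselineCorrect` is the one closed interval (both endpoints are samples
  users point at).
- **GFP tolerance** `1e-12` for normalization; unit-GFP validity in S4
  objects at `1e-9` (slack for accumulated rounding).
- **Ties**: k-means assignment → lowest cluster id; `medianSplit` ties →
  low group.
- **Cosines clamped** to $[-1, 1]$; zero vectors are errors.
- **p-values**: add-one convention by default (section 2.3).
- **Seeds**: every stochastic step takes an explicit seed; nested seeds are
  derived from a master seed by a fixed integer recurrence, never from R's
  global RNG state, so results are independent of call order.

# 6. Validation problem sizes

The test suite exercises the mathematics at sizes chosen for exactness and
speed: brute-force k-means enumeration at 8 timepoints (every partition
checked), noiseless recovery with 3 templates where the clustering objective
must vanish and boundaries must be exact, closed-form paired-t oracles,
Monte-Carlo power checks at $10^5$ draws, and a TANOVA type-I calibration of
220 null replicates at 199 permutations (the attained level 10/200 = 0.05 is
exactly representable under the add-one convention), asserted against the
exact binomial 95% band. These sizes are validation choices; analysis
defaults remain at the study scale above.

# 7. Limitations

- k-means is a hard-assignment model; gradually morphing topographies get
  sliced into states regardless.
- Bonferroni is conservative when microstates (or channels) are correlated,
  which they are; the cost is power, not validity.
- The paired post-hoc pairs epochs *by index* after equalization — a
  convention, not a physiological pairing; use `paired = FALSE` when index
  pairing is meaningless.
- BrainVision import supports ASCII exports only (`readBrainVisionAscii`);
  binary `.eeg` files are rejected with an informative error.
- The generator's noise is white in time; permutation inference does not
  depend on this, but effect-size intuition from simulations may be
  optimistic relative to temporally correlated noise.
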