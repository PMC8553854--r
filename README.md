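# mstates

Task-based EEG microstate analysis in R: topographic k-means segmentation of
event-related potentials (ERPs), permutation-based topographic analysis of
variance (TANOVA), channel-wise post-hoc tests, and a fully seeded synthetic
epoch generator with known ground truth for validating the whole chain.

## The scientific problem

A multichannel ERP is a matrix `V ∈ ℝ^{C×T}` (C channels, T timepoints). At
each timepoint `t` the scalp map `V[, t]` has a *global field power*

```
GFP(t) = sqrt( mean_c ( V[c, t] − mean(V[, t]) )² )
```

i.e. the population spatial standard deviation across electrodes. The
*microstate* model holds that the normalized topography `V[, t] / GFP(t)`
does not vary continuously but dwells in a small number of quasi-stable maps
that succeed one another abruptly. The analysis questions are:

1. **Segmentation.** Which maps, and when? Cluster the T normalized
   topographies with polarity-sensitive k-means (topographies of opposite
   polarity are *different* states here), then read maximal runs of identical
   cluster labels as microstates.
2. **Topographic comparison.** Within each microstate, do two experimental
   conditions A and B produce the same map? The test statistic is the cosine
   `cos θ` between the conditions' microstate topographies (GFP-normalized,
   averaged over the microstate's timepoints); the null distribution comes
   from re-averaging after randomly permuting the condition labels of the
   pooled single epochs (TANOVA). p-values use the add-one convention
   `p = (1 + #{null ≤ observed}) / (nPerm + 1)` and are Bonferroni-adjusted
   over the number of microstates.
3. **Localization.** For microstates with a significant topographic
   difference, paired t-tests per channel on the per-epoch microstate
   averages (epoch counts equalized by seeded subsampling first), Bonferroni
   over the 30 channels (α/30 ≈ 0.0017).
4. **Design sensitivity.** A reverse power analysis: the smallest paired
   standardized effect `d` detectable at given N, α, and power, via the
   noncentral t distribution (`d = 0.27` for N = 107, α = 0.05, power 0.80).

Because every step is a judgment call (normalization, tie-breaking,
permutation scheme), the package also ships a generator that simulates epochs
from an explicit truth — unit-GFP template maps on a timeline, a GFP
envelope, an exact-angle between-condition rotation, per-subject jitter, and
per-epoch Gaussian noise, all derived from one master seed — so the pipeline
can be validated against known answers.

## Worked example

Simulate a small study with a 25° topographic rotation injected into the
second 100-ms segment of condition B, then run the full pipeline:

```r
library(mstates)

tpl <- makeTemplates(3, 30, minAngleDeg = 60, seed = 7)
tl  <- tileTimeline(tpl, window = c(0, 600), durationMs = 100)
man <- truthManifest(
  templateSet = tpl, timeline = tl,
  effect = effectSpec(affectedSegments = 2L, angleDeg = 25),
  nSubjects = 6, nEpochsPerCondition = 12,
  noiseSd = 8, subjectSd = 0.05, seed = 42L
)
man
#> TruthManifest: 6 subjects x 2 conditions, 12 epochs/condition
#>   3 templates, 6 segments, noise sd 8 uV, subject sd 0.05, seed 42
#>   effect: 25 deg rotation (amplitude ratio 1) in segment(s) 2

cfg <- pipelineConfig(manifest = man, k = 3, nRestarts = 20, nPerm = 499)
res <- runPipeline(cfg)
sm  <- summarizeResults(res)

sm$durations
#>   microstate start_ms end_ms duration_ms cluster_id
#> 1          1        0    100         100          1
#> 2          2      100    200         100          3
#> 3          3      200    300         100          2
#> 4          4      300    400         100          1
#> 5          5      400    500         100          3
#> 6          6      500    600         100          2

print(sm$tanova, digits = 3)
#>   comparison microstate cos_theta_obs p_value significant alpha_adj
#> 1     A_vs_B          1         0.996   0.956       FALSE    0.0083
#> 2     A_vs_B          2         0.909   0.002        TRUE    0.0083
#> 3     A_vs_B          3         0.998   0.148       FALSE    0.0083
#> 4     A_vs_B          4         0.999   0.338       FALSE    0.0083
#> 5     A_vs_B          5         0.999   0.314       FALSE    0.0083
#> 6     A_vs_B          6         0.995   0.168       FALSE    0.0083

head(sm$posthoc)
#>   comparison microstate channel          t      p_value direction significant
#> 1     A_vs_B          2     Fp1 -14.421185 8.687586e-23        -1        TRUE
#> 2     A_vs_B          2     Fp2  -5.946126 9.381049e-08        -1        TRUE
#> 3     A_vs_B          2      Fz  -5.982966 8.072727e-08        -1        TRUE
#> 4     A_vs_B          2      F3  11.413740 1.003022e-17         1        TRUE
#> 5     A_vs_B          2      F4  12.580987 9.532589e-20         1        TRUE
#> 6     A_vs_B          2      F7   2.450421 1.673508e-02         1       FALSE
```

The TANOVA flags exactly the microstate carrying the injected effect
(microstate 2, the [100, 200) ms window), and the post-hoc stage localizes
it to specific channels. Re-running with the same configuration reproduces
these numbers bit for bit; the seeds live in the config
(`cfg$seeds`) and the simulation truth in the manifest.

The reverse power analysis:

```r
round(minimalDetectableEffect(107, alpha = 0.05, power = 0.80), 2)
#> [1] 0.27
```

## Package tour

| Area | Key functions |
|---|---|
| Synthetic truth | `makeTemplates`, `tileTimeline` / `makeTimeline`, `effectSpec`, `truthManifest`, `simulateDataset`, `simulateEpoch` |
| ERP / GFP | `computeGFP`, `gfpCurve`, `averageEpochs`, `baselineCorrect`, `normalizeByGFP`, `grandGrandmean` |
| Clustering | `kmeansTopographies`, `segmentMicrostates`, `applySegmentation`, `sweepK` |
| TANOVA | `cosTheta`, `observedCosines`, `permutationNull`, `runTanova`, `tanovaP`, `adjustAlpha` |
| Post-hoc | `equalizeEpochs`, `channelTTests` |
| Power / split | `achievedPower`, `minimalDetectableEffect`, `medianSplit` |
| I/O | `writeEpochBundle` / `readEpochBundle`, `writeTruthManifest` / `readTruthManifest`, `readBrainVisionAscii`, `epochsFromContinuous`, result writers |
| Orchestration | `pipelineConfig`, `readPipelineConfig`, `runPipeline`, `summarizeResults`, `writeResultsBundle` |

A thin command-line wrapper with `simulate` / `run` / `power` / `split`
subcommands is installed at `system.file("scripts", "run-pipeline.R",
package = "mstates")`.

The methods vignette (`vignettes/microstate-methods.Rmd`, source form)
documents the model, every tunable with units and rationale, the numerical
conventions (tie-breaking, half-open windows, p-value convention,
tolerances), and the generator's scope and limitations.

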