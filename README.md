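# cohseg

Does group membership bias how people process a dynamic event they all
watch together? `cohseg` is an R package for answering that question from
three behavioural channels recorded while two groups of observers (e.g.
rival sports fans) view one shared stimulus:

* **Gaze coherence** — normalized scanpath saliency (NSS): at each time
  step a fixation map is built from a reference group's gaze positions
  (Gaussian bump per observer), normalized to zero mean / unit SD over
  cells, and read out at a test observer's gaze position. Scoring each
  participant against the other *n* − 1 members of their own group and
  against a random *n* − 1 sample of the opposing group gives a
  per-participant difference score `NSS_same − NSS_other`.
* **Event segmentation** — observers press a button whenever one
  meaningful unit of activity ends and another begins. A group's
  segmentation magnitude is the sum of unit-peak Gaussians (SD 1000 ms)
  around its presses, normalized by group size. Each participant's
  presses are scored against their own group (self excluded) minus the
  other group, again yielding difference scores. Significant **event
  boundaries** are local maxima of the pooled magnitude above a
  circular-shift permutation threshold (95% criterion).
* **Memory** — probe items are binned by forward distance to the next
  event boundary (Tukey box-plot outlier removal, then distance
  tertiles); accuracy and confidence cell means feed per-participant
  own-team-minus-other-team contrasts.

All difference-score sets end in the same inference layer: one-sample
*t*-test, Cohen's *d* = *t*/sqrt(*n*), and a **one-tailed JZS Bayes
factor** (Cauchy(0, sqrt(2)/2) prior on the standardized effect,
truncated to the predicted direction, integrated numerically) so that
evidence *for* the absence of group bias can be quantified, plus a
sequential Bayes-factor curve. Because raw recordings of this kind are
rarely shareable, the package ships a synthetic cohort generator with
known ground truth (gaze attractor + optional group offset; boundary-
locked presses + optional group-specific boundaries; memory accuracy tied
to boundary distance with an optional confidence-only own-group bias), so
the whole chain is testable end to end.

## Worked example

Evidence for the null from a published-style gaze result (t(14) = −0.46
from 15 observers, testing the directional prediction of an own-group
advantage):

```r
library(cohseg)
jzs_bf_one_sample(-0.46, 15, side = "positive")
#> JZS Bayes factor (one-sample, r = 0.707, positive-sided): BF01 = 5.167 (BF10 = 0.194)
```

BF01 ≈ 5.2: the data are about five times more likely under "no own-group
gaze advantage" than under the directional alternative — substantial
evidence for unbiased gaze.

A fully synthetic end-to-end run, with a segmentation bias injected (half
of the latent event boundaries visible to only one group) but unbiased
gaze and memory:

```r
cfg <- cohort_config(n_group_a = 8, n_group_b = 8, duration_s = 90,
                     gaze_noise_sd = 40, indiv_offset_sd = 50,
                     boundary_times_s = seq(8, 85, by = 7),
                     group_specific_boundaries = 0.5, seed = 42)
report <- run_pipeline(run_config(simulate = cfg, n_permutations = 500,
                                  seed = 42))
report
#> cohseg pipeline report
#>   gaze: M = -0.1313, SD = 1.0568, t(15) = -0.50, p = 0.626, d = -0.12, BF01 = 5.43
#>   segmentation: M = 0.1191, SD = 0.0810, t(15) = 5.88, p = 0.000, d = 1.47, BF01 = 0.00
#>   confidence: M = 0.0054, SD = 0.1178, t(15) = 0.18, p = 0.858, d = 0.05, BF01 = 3.40
#>   accuracy: M = 0.0025, SD = 0.0466, t(15) = 0.21, p = 0.836, d = 0.05, BF01 = 3.32
#>   Event boundaries: 8 significant peaks (threshold 0.3865 at alpha 0.05, 500 permutations)
#>   at (s): 7.9, 22.1, 36.0, 49.8, 56.9, 64.0, 71.0, 85.1
```

Exactly the injected structure is recovered: the segmentation difference
scores are strongly positive (each group agrees better with itself,
because some boundaries are group-specific), while gaze and both memory
contrasts correctly return evidence for the null (BF01 > 3). With
`out_dir` set, `run_pipeline()` also writes score tables, the boundary
list, a JSON manifest (seeds, parameters, every exclusion count) and a
plain-text summary. A thin CLI over the same function lives in
`inst/scripts/cohseg-pipeline.R`.

See `vignettes/cohseg-methods.Rmd` for the model and design decisions,
the generator's assumptions, calibration results, and a known limitation
of the gaze-channel *t*-test.

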