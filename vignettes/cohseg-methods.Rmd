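---
title: "Measuring group bias in shared-event viewing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring group bias in shared-event viewing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohseg)
```

## The question and the measurement chain

When two groups of observers — say, rival sports fans — watch the same
dynamic event, does group membership bias how they process it online?
`cohseg` operationalises this with per-participant *difference scores*: a
measure of how well a participant's behaviour agrees with their own group
minus how well it agrees with the other group. If group membership shapes
processing, these scores sit above zero; if online processing is
stimulus-driven, they scatter around zero. Three behavioural channels are
covered:

1. **Gaze coherence** via normalized scanpath saliency (NSS).
2. **Event-segmentation agreement** via kernel-smoothed button-press
   magnitude.
3. **Memory**, where boundary-distance effects on accuracy are expected
   but own-group bias should appear (if anywhere) in confidence, not
   accuracy.

Each channel ends in the same inference layer: a one-sample *t*-test with
Cohen's *d*, and a one-tailed JZS Bayes factor that can quantify evidence
*for* the null — essential, because "no group bias" is a substantive
conclusion here, not a failed test.

## Gaze coherence (NSS)

At each analysis step (default 40 ms) on a common 60 Hz grid, the valid
gaze positions of a reference group are turned into a fixation map: a sum
of isotropic unit-peak Gaussians on a grid downsampled from screen
resolution. The map is normalized to zero mean and unit SD *using only
that time point's values* (a spatiotemporal-window variant is deliberately
not offered: it distorts scores around abrupt coherence changes), and the
test participant's NSS is the normalized value at their gaze cell
(nearest-cell lookup; no interpolation, matching the discrete map
semantics).

Per participant, the own-group reference is the other *n* − 1 members of
their group (self-exclusion avoids scoring a participant against their own
gaze), and the other-group reference is a seeded random sample of *n* − 1
members of the opposing group, so both references have equal size. A step
contributes only when the participant's gaze is valid and **both** maps
rest on at least `min_refs = 4` valid reference positions; a constant map
(zero cell SD) invalidates the step. Every dropped participant-step is
counted by reason, and the retention fraction reconciles exactly with the
totals.

Tunable parameters, defaults, and rationale:

| parameter | default | units | why |
|---|---|---|---|
| `step_ms` | 40 | ms | analysis step of the underlying method |
| `min_refs` | 4 | observers | minimum references per fixation map |
| `sigma_px` | 1.2 deg at 65 cm (`visual_angle_px()`, ~34 px on a 1280 px / 52 cm display) | px | spatial kernel; standard in the NSS literature; not fixed by the method itself |
| `downsample` | 8 | px/cell | speed; oracle tests at factor 1 confirm conclusions are grid-invariant |
| analysis rate | 60 | Hz | common grid; tracks at other rates are resampled by nearest-valid-sample within half a period |

The implementation exploits the separability of the Gaussian bump: the
per-step map value at the gaze cell, the cell mean, and the cell SD are
computed from one-dimensional kernel sums without materialising maps,
vectorised over steps. The test suite proves this fast path equal (to
1e-9) to the naive build-map/normalize/look-up route, which is itself
checked against a brute-force triple loop.

The other-group sample is drawn once per participant per run. We also
implemented and evaluated per-time-point redrawing (the method's
literature leaves this open); it changed nothing in the calibration
experiments reported below, so the simpler once-per-run convention was
kept and is recorded in the run manifest.

## Segmentation agreement

Around every button press a unit-peak Gaussian with SD 1000 ms is placed;
a group's magnitude series is the per-time sum divided by the number of
contributing participants. The unit-peak-plus-normalization convention
makes the series interpretable as expected per-participant agreement: if
everyone presses at one instant the series equals 1 there. Difference
scores evaluate, at each of a participant's own press times (analytically,
not from the grid), the own-group magnitude with that participant left out
(normalizer *n* − 1, avoiding autocorrelation with their own presses)
minus the other group's magnitude (normalizer = that group's size, each
reference set normalized by its own size).

**Event boundaries** are local maxima of the pooled magnitude series that
exceed a resampling threshold: each participant's train is circularly
shifted by an independent uniform offset (wrapping at the stimulus
duration; press counts and inter-press structure preserved, alignment
destroyed), the pooled series is recomputed, and the threshold is the
(1 − alpha) quantile of all pooled null values (default alpha 0.05, 1000
permutations). Peaks are greedily thinned to a 2 s minimum separation,
higher peaks first, earlier time winning ties. The 100 ms grid is ample
for a 1000 ms kernel. Null-series evaluation truncates the kernel at 10
SD, which at double precision is exact (exp(−50) ≈ 2e−22). Edges receive
no kernel correction; because the null wraps, observed and null edges are
comparable.

## Memory binning and contrasts

Each probe item's distance is the *forward* distance to the nearest
boundary at or after the probe (items at a boundary get 0; items with no
later boundary are flagged missing). A nearest-either-direction variant
exists behind the same interface but forward distance is the default: the
probed moment is remembered in the context of the episode it opens into.
Items beyond the Tukey fence (Q3 + 1.5 IQR, interpolated type-7
quartiles — the conventional reading of a "box plot criterion") are
removed; kept items are split at the 1/3 and 2/3 empirical quantiles into
tertiles labelled `[0, c1]`, `(c1, c2]`, `(c2, max]`. Tertiles are
computed once on items (distances do not depend on test occasion).
Aggregation yields per-participant cell means (test time × content group ×
tertile) for accuracy and confidence; the fan-alignment contrast is the
participant's mean over own-team cells minus other-team cells, feeding the
same inference layer. Full four-way mixed ANOVAs are intentionally out of
scope: the single theoretically loaded interaction is captured by the
contrast, and the remaining effects are routine omnibus machinery.

## Inference layer

`one_sample_t()` and `two_sample_t()` wrap `stats::t.test()` (pooled
variance for the two-sample case) and add Cohen's *d* (= mean/SD, so
*d* = *t*/sqrt(*n*) holds to 1e−10 for one-sample results).

The JZS Bayes factor treats the standardized effect delta as
Cauchy(0, *r*) under the alternative, with *r* = sqrt(2)/2 — the default
of the mainstream Bayesian-t software this convention comes from — and
integrates the noncentral-*t* likelihood of the observed statistic over
that prior. Numerically, the prior CDF is substituted (so the integral
becomes a mean likelihood over a bounded interval), the quadrature is
split at the likelihood peak delta = *t*/sqrt(*n*), and each piece is
rescaled to O(1); adaptive quadrature then achieves a relative error
bounded by 1e−6 across the useful range (|*t*| up to ~50; beyond that a
dense trapezoid fallback keeps the negligible off-peak piece finite). The
one-sided factor truncates the same prior to one sign and renormalizes —
one integral family for all three directions — and the posterior
probability of the positive direction falls out of the same two
half-integrals. Tests verify the quadrature against two independent
oracles (the g-mixture form for the two-sided factor; a 400k-point
trapezoid in delta space for the one-sided factor) to 1e−4.
`sequential_bf()` recomputes the factor on every prefix of the sample in
acquisition order, the standard robustness display for small samples.

## The synthetic cohort generator

No raw recordings of this kind are publicly deposited, so the generator is
a first-class module: every downstream stage is exercised on cohorts with
known ground truth.

* **Gaze**: one shared attractor trajectory per cohort (an
  Ornstein–Uhlenbeck-style smooth walk per axis, correlation time 1.5 s,
  stationary SD an eighth of the screen, reflected at edges) mimics
  ball-following gaze with a single smoothness knob. Each participant adds
  a stable idiosyncratic offset (SD 50 px ≈ 1.8 deg; real observers
  differ persistently in where they look, and this participant-level
  variance is what group-level *t*-tests rest on), white measurement
  noise (SD 30 px), i.i.d. sample dropout (5%), and — in biased worlds —
  a horizontal group offset. The degenerate world with all three noise
  terms at zero reproduces the attractor exactly, which the tests assert.
* **Presses**: each latent boundary visible to a participant's group is
  marked with probability 0.8 at the boundary plus 0.5 s Gaussian jitter,
  plus Poisson spurious presses; `group_specific_boundaries` makes a
  fraction of boundaries visible to one group only (the segmentation
  analogue of a group bias).
* **Memory**: correct-answer probability declines logistically with
  boundary distance (base 0.9, slope 0.02 logits/s) and *contains no
  own-group term by construction*; confidence is a latent Gaussian
  (base 3, SD 0.7) plus an optional additive own-group bias, rounded and
  clipped to 1–5. This builds in the dissociation the analysis should
  recover: a confidence bias without an accuracy bias.

What the generator does **not** emulate: saccade/fixation microstructure,
visual saliency of the actual footage, burst-like equipment dropout,
PANAS-style affect dynamics. Passing tests therefore show the *analysis
chain* is correct and calibrated under plausible structure, not that any
particular real dataset satisfies its assumptions.

## Calibration experiments, problem sizes, and a known limitation

The simulation-based tests run at desk scale, chosen so the full suite
stays in minutes: gaze worlds with 8 observers per group, 90 s of
stimulus, grid factor 32, evaluated over 50 seeds; press worlds with 15
per group, 300 s, 19 boundaries; memory worlds with 52 items and 30
participants. Under these conditions:

* the permutation threshold is calibrated (null exceedance ≈ alpha);
* null worlds give BF01 > 1 in ~95% of runs for both difference-score
  channels, and the segmentation *t*-test rejects at the nominal 5%;
* biased worlds (200 px gaze offset; 50% group-specific boundaries) are
  detected with essentially full power;
* a 0.8-point confidence bias is recovered to within rounding/clipping
  attenuation while the accuracy contrast stays flat.

One limitation surfaced by these experiments is worth stating plainly:
the participant-level *t*-test on **gaze** difference scores is mildly
anti-conservative under the null (empirical rejection ~10–12% at nominal
5%). The cause is structural, not numerical: all participants are scored
against largely shared reference maps at the same time points, so their
scores are weakly positively correlated (observed var inflation of the
mean ~1.5 at 16 observers), which the independence-assuming *t*-test
ignores. The effect is robust to stimulus duration, to the size and
temporal structure of idiosyncratic gaze variability, and to per-step
redrawing of the other-group sample. The segmentation channel does not
share the problem because its scores are evaluated at each participant's
own press times, which are independent across participants. Users should
read mildly significant gaze difference-score *t*-tests with this in
mind; the Bayes factor column is computed from the same *t* and inherits
the same caveat.

## Degenerate inputs and numerical choices

* Constant fixation maps are flagged invalid, never divided by zero;
  sample SD below 1e−12 counts as constant.
* Quartiles and tertile cuts use type-7 (interpolated) quantiles
  throughout.
* Boundary-peak ties resolve to the earlier time; boundary thinning is
  greedy by height.
* Zero-press participants are reported and skipped, not errors; groups
  smaller than `min_refs + 1` refuse the gaze analysis with a diagnostic.
* All generators and analyses are deterministic under a seed; generator
  seeds and analysis seeds are independent substreams, and run manifests
  record seeds, parameters, and every exclusion count.
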