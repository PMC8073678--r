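---
title: "Quantifying infant smile dynamics from Action Unit time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying infant smile dynamics from Action Unit time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smiletrace)
```

## The problem

Automated facial-behaviour tools such as OpenFace turn video of an
infant's face into per-frame estimates of Action Unit (AU) intensities
on a 0–5 scale, together with a tracking-confidence score C in [0, 1].
Two AUs carry the smile taxonomy used here: AU12 (lip-corner puller,
zygomaticus major) defines smiling, and AU06 (cheek raiser, orbicularis
oculi) distinguishes a *Social Smile* (SO; AU12 and AU06 co-active, the
communicative, "Duchenne-like" form) from a *Simple Smile* (SI; AU12
only). `smiletrace` turns those frame-level estimates into per-subject
behavioural measures — how long, how intense, and how often each smile
type occurs — and compares two groups (a clinical ASD group and
typically developing controls) with a conventional multivariate
battery. Because the home-video recordings such analyses are run on are
typically too sensitive to share, the package also ships a synthetic
cohort generator with ground truth, so that every stage of the pipeline
is testable end to end.

## The processing model

For each subject the pipeline applies, in order:

1. **Confidence gating.** Only frames with C strictly above 0.75 are
   treated as reliable. Frames are masked, never deleted, so that the
   recording's time accounting stays exact. The gate is strict
   (`>`, not `>=`): a frame at exactly 0.75 fails.
2. **Dropout handling.** Runs of gate-failing frames longer than
   `max_gap_s` (default 0.5 s) split the recording into segments and
   are excluded from usable time. Shorter interior runs are *bridged*:
   kept inside the segment with AU intensities linearly interpolated
   from the flanking valid frames. The gate says nothing about whether
   an expression continues across a brief tracking glitch; bridging at
   half the minimum event duration is our convention — it cannot
   manufacture a countable event on its own, because a bridged gap is
   at most 0.5 s and an event must last 1 s. Leading and trailing
   invalid runs have no flank on one side and are always trimmed.
   Usable duration — the denominator of the frequency measures — is
   the summed duration of retained frames.
3. **Smoothing.** Each AU signal is smoothed with a 4-frame boxcar
   (0.16 s at 25 fps). An even-width kernel has no centre frame; we fix
   the window at `{t-2, t-1, t, t+1}` and renormalize over in-bounds
   frames at the edges, so the operation is deterministic, bounded by
   the input range, and exact on constants.
4. **Event segmentation.** An *activation episode* is a maximal run of
   frames on which the smoothed signal is at or above the activation
   threshold `tau` (default 0.5 on the 0–5 scale) and the frame is
   valid. The reading of "activation peaks" as supra-threshold runs
   rather than local maxima is deliberate: a point maximum has no
   duration or mean intensity, and both are required measures. The
   threshold itself is not part of the published processing
   conventions this pipeline follows; 0.5 sits above the regression
   noise floor of AU intensity estimators and is configurable.
5. **Minimum duration.** AU12 episodes shorter than 1 s are discarded
   (strictly-shorter-than: a 25-frame episode at 25 fps, exactly
   1.00 s, is kept; 24 frames, 0.96 s, is not). Episodes too brief to
   be facial expressions are tracker noise.
6. **Classification.** Every surviving AU12 episode becomes exactly one
   smile event. It is Social when AU06 is active on at least 50% of its
   frames (`social_overlap_threshold`), else Simple. Co-activation
   needs a temporal-overlap criterion; a majority criterion is
   symmetric, scale-free, and configurable. AU06 episodes never
   generate events on their own, and AU06 is not duration-filtered —
   the taxonomy is anchored on AU12. Events never span a segment
   boundary.

## Per-subject features and the cohort table

Three measures are computed per smile type: mean event duration (s),
mean event intensity (the unweighted mean over events of each event's
mean smoothed intensity; AU12 for both types, additionally AU06 for
SO), and frequency, expressed as events per 120 s of usable recording —
the conventional basis for these short (~2 min) interaction videos.

When a subject has no events of a type, that type's duration and
intensity are *missing*, not zero (a mean over zero events is
undefined, and coding it 0 would bias intensity downward), while its
frequency is genuinely 0.

The multivariate analysis uses six dependent variables: `dur_SI`,
`dur_SO`, `freq_SI`, `freq_SO`, `int_SI_au12`, and `int_SO_composite`
(the mean of the SO AU12 and AU06 intensities). The univariate
follow-up family splits the composite back into its two components,
giving seven tests and hence the Bonferroni per-test threshold
0.05/7 = 0.00714. This six-DV/seven-test split reconciles a 6-variate
MANOVA with a 7-member follow-up family; both sets are configurable.

Subjects missing any multivariate DV are excluded listwise
(complete-case) by default and logged; a pairwise policy is available
for the univariate follow-ups. With two groups, N complete cases and p
DVs, the MANOVA F has (p, N − p − 1) degrees of freedom — e.g. 29
complete cases and 6 DVs give F(6, 22), and each univariate test
F(1, 27).

## The statistical battery

* **MANOVA.** One-way, two groups, Pillai's trace with its standard F
  approximation (via `stats::manova`). With two groups all four
  classical statistics give the same exact F — the choice of Pillai is
  for its conventional robustness, and the two-group F equals the
  Hotelling T² transform, an identity the test suite verifies against
  an independent textbook implementation. With a single DV the Pillai F
  reduces exactly to the univariate ANOVA F (and to the squared pooled
  t), computed that way in code.
* **Follow-up ANOVAs.** One per family member, with partial
  η² = SSB/(SSB + SSW) and Bonferroni-thresholded significance. Sums of
  squares are computed in closed form so that degenerate inputs have
  defined semantics: zero within-group variance yields F = 0 when the
  group means agree and an infinite-F flag when they differ. On
  non-degenerate data the result is identical to `anova(lm(...))`,
  which the tests check.
* **Assumption screen.** Shapiro–Wilk per DV per group (skipped with a
  note below n = 3), Levene's test per DV (mean-centred by default,
  median-centred available), Mahalanobis distance of each complete case
  to the pooled DV centroid against the conventional χ²(p) cutoff at
  p < 0.001, and the maximum absolute pairwise Pearson correlation
  among DVs, flagged above 0.9 as a multicollinearity warning.
* **Covariate screens.** Partial Spearman correlations of each DV with
  IQ (controlling sex) and with sex (controlling IQ) within the
  clinical group: all variables are rank-transformed, the two targets
  residualized on the covariate ranks by least squares, and the
  product-moment correlation of the residuals reported with a t-based
  p-value on n − 2 − k degrees of freedom. This is invariant under
  strictly monotone transforms of either target.
* **Demographics.** Equal-variance two-sample t-tests for continuous
  descriptors and a Pearson χ² (no continuity correction) for the sex
  table.

## The synthetic cohort generator

`sample_subject_trace()` draws, per smile type, a Poisson number of
events (rates per 120 s), places them uniformly without overlap
(rejection sampling with a 0.6 s guard gap so neighbouring events
cannot merge through smoothing or gap bridging), and renders each as an
AU12 plateau with 0.2 s half-cosine on/off ramps at a Gaussian
amplitude; Social events add a co-extensive AU06 plateau. Gaussian
noise (SD 0.05 by default) is added and clipped to [0, 5]; confidence
sits at 0.95 with Poisson-placed dropout runs at 0.5. Event durations
are log-normal (median 2 s, sdlog 0.25), truncated below at 1.2 s so
every true event survives the 1 s duration filter by construction.

The plateau-with-ramps shape (rather than spikes) guarantees
supra-threshold runs with well-defined duration, matching the run-based
event definition. Defaults emulate the recording conditions this kind
of study reports: ~122 s (SD 6) recordings at 25 fps (PAL home video),
18 clinical + 15 control subjects, heavily male samples, IQ known for
most clinical but few control subjects. The default group presets
differ *only* in the clinical group's AU12 amplitude (1.0 intensity
units lower) and Social-smile rate (40% lower) — the qualitative
pattern of reduced social smiling the analysis is designed to detect —
with durations and Simple-smile rates identical, so duration DVs act
as negative controls. Rates (5 SO and 6 SI per 120 s in controls) and
amplitudes (AU12 3.0, AU06 2.5, SD 0.4) are fixed once as plausible
values for engaged infant play interactions; no attempt is made to
tune them to any published test statistic, which depends on
unavailable raw data.

A master seed derives per-subject child seeds, so any subject is
regenerable in isolation from its metadata row, and regeneration is
byte-identical.

### What the generator does and does not emulate

It reproduces the *signal structure* the pipeline assumes: event-like
supra-threshold episodes, type-dependent AU06 co-activation, baseline
noise, confidence dropouts, group differences in rate and amplitude.
It does not model caregiver behaviour, temporal dependence between
smile types, gaze, amplitude drift within events, autocorrelated
tracker noise, or the heavy-tailed artefacts of real in-the-wild video.
Passing the recovery tests therefore shows the pipeline is correct and
well-calibrated *under its own assumptions* — not that those
assumptions hold for any particular real dataset.

## Numerical conventions and edge cases

* Frame rate is inferred as `1/median(diff(timestamps))`, tolerant of
  occasional dropped frames; an event of k frames lasts k/fps seconds.
* AU intensities outside [0, 5] on input are clipped, with a logged
  count; rows with non-finite required fields are dropped, also logged.
* A recording with no gate-passing frames yields zero segments and
  zero usable time — a downstream decision, not an error.
* **Ramp dilution.** An event's mean intensity is taken over its
  supra-threshold run, which includes ramp frames below the plateau;
  detected means therefore sit slightly below the generating
  amplitude. Over the generator's support the worst case (1.2 s event,
  amplitude 5) dilutes the mean by 17% of the plateau; typical events
  are diluted well under 10%. The amplitude-recovery tests use this
  computed 17% bound.
* Validation problem sizes, chosen to make the Monte-Carlo checks
  sharp while keeping the full battery runnable on a laptop in
  minutes: 1000 random traces for oracle equivalence, 1000 simulated
  null cohorts for type-I calibration (checked against the exact
  binomial 99% interval around α = 0.05), 200 cohorts under the
  default group presets for recovery, 50 random datasets for the
  MANOVA identities.

## Known limitations

* The gap-bridging rule and the run-based reading of "activation
  peaks" are this package's documented conventions; other choices
  (deleting masked frames, local-maximum peaks) would change event
  counts on noisy recordings.
* Listwise exclusion is the default for the MANOVA because it is the
  only policy consistent with complete-case multivariate analysis; it
  can discard subjects who simply never produced one smile type, which
  is itself informative. The exclusion log makes this visible.
* The partial Spearman screen treats sex as a 0/1 covariate and IQ as
  interval-scaled ranks; with very small groups its t-approximation is
  crude.
* The package consumes OpenFace *outputs*; face detection, landmark
  quality, and AU calibration are upstream concerns it cannot audit.
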