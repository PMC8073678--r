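# smiletrace

Quantitative analysis of infant smiling from automated facial Action
Unit (AU) estimates.

Tools such as OpenFace convert video of a face into per-frame AU
intensities (0–5) plus a tracking-confidence score C ∈ [0, 1]. Two AUs
carry the smile taxonomy: AU12 (lip-corner puller) defines smiling, and
AU06 (cheek raiser) separates **Social Smiles** (SO: AU12 + AU06
co-active, the communicative form) from **Simple Smiles** (SI: AU12
only). `smiletrace` is for researchers in developmental psychology and
behavioural phenotyping who want to turn those frame-level estimates
into per-subject smile measures and group comparisons — e.g. contrasting
infants later diagnosed with ASD against typically developing controls
in short, unconstrained caregiver–infant home videos.

## What it computes

Per subject, from gated (C > 0.75), dropout-segmented, boxcar-smoothed
AU traces, the pipeline detects AU12 activation episodes (smoothed
signal ≥ τ = 0.5 for ≥ 1 s), classifies each by AU06 co-activation
(≥ 50% of event frames ⇒ SO), and aggregates three measures per smile
type X ∈ {SI, SO}:

- duration: mean event duration (s),
- intensity: mean of event-mean smoothed AU intensities,
- frequency: events per 120 s of usable recording,
  `freq_X = 120 · n_X / usable_seconds`.

Group comparison is a one-way MANOVA (Pillai's trace V with its exact
two-group F on (p, N − p − 1) df), followed by univariate ANOVAs with
partial η² = SSB/(SSB + SSW) at the Bonferroni per-test threshold
α/m = 0.05/7 = 0.00714, plus assumption checks (Shapiro–Wilk, Levene,
Mahalanobis outlier screen, pairwise-correlation collinearity screen),
partial Spearman correlations of the DVs with IQ and sex within the
clinical group, and demographic t/χ² comparisons.

A synthetic-cohort generator (marked Poisson point process: plateau
events with half-cosine ramps, Gaussian amplitudes, AU06 co-activation
for SO only, tracker noise and confidence dropouts) provides ground
truth so the whole pipeline is testable without access to sensitive
recordings.

## Worked example

```r
library(smiletrace)

co  <- generate_cohort(seed = 42)                    # 18 ASD / 15 TD subjects
res <- analyze_cohort(co$traces, co$metadata, stats = TRUE)

print(res$stats$manova)
#> One-way MANOVA (Pillai): V = 0.9387, F(6, 24) = 61.286, p = 2.266e-13 (n = 31)
print(res$stats$anovas$int_SO_au12)
#> ANOVA int_SO_au12: F(1, 29) = 129.348, p = 3.298e-12 (Bonferroni threshold 0.00714, significant), partial eta2 = 0.817
print(res$stats$anovas$dur_SO)
#> ANOVA dur_SO: F(1, 29) = 0.224, p = 0.6398 (Bonferroni threshold 0.00714), partial eta2 = 0.008
event_recall(res$events, co$truth)
#> [1] 1
```

Reading: the default presets give the clinical group a 1.0-unit lower
AU12 amplitude and 40% lower Social-smile rate, so the multivariate
test and the intensity follow-up reject decisively (V near 1, huge F),
while Social-smile *duration* — identical between presets — stays at
its null (F ≈ 0.2, η² ≈ 0.008). Two of the 33 simulated subjects
happened to produce no Social Smile and were excluded listwise, hence
n = 31 and F(6, 24). Every ground-truth event was recovered by the
detector (recall 1.0).

On real data, point `run_pipeline()` at a directory of OpenFace CSVs
plus a `metadata.csv` (subject_id, group, sex, age_months, iq):

```r
cfg <- pipeline_config(input_dir = "recordings/", output_dir = "out/")
run_pipeline(cfg)   # writes events.csv, features.csv, exclusions.csv,
                    # stats.json, report.txt, manifest.yaml
```

A thin CLI with `simulate`, `detect`, and `run-all` subcommands lives
in `inst/cli/smiletrace.R`.

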