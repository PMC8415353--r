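---
title: "Methods: image, network and temporal phenotyping of social-media archives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image, network and temporal phenotyping of social-media archives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`instaphen` implements a case–control digital-phenotyping analysis for
image-centric social-media archives. One participant contributes a data
export: a set of posted images with timestamps, lists of connections
(followers, following, pending requests, hashtag follows, blocked, close
friends, restricted), and a demographic record with a group label (SSD,
schizophrenia spectrum disorder, or HV, healthy volunteer). The unit of
statistical analysis is the participant: all image metrics are averaged
within participant before any between-group test, which keeps participants
with thousands of posts from dominating the comparison and makes the rows
of the report exchangeable units.

The pipeline is: parse archives → inclusion filter → propensity matching →
feature extraction → gated two-sample comparisons with effect sizes →
robust between-within ANOVA of temporal profiles.

# Archive model and inclusion

Only one archive dialect is bundled (the *canonical* JSON layout documented
in `?archive-io`); real export schemas changed repeatedly over the years,
so `parse_archive()` dispatches on a dialect name and adapters can be added
without touching downstream code. Timestamps are stored as local wall-clock
strings and resolved in UTC with an optional fixed offset; all binning uses
the recorded local clock. Unreadable image files are flagged missing and
skipped in aggregation rather than failing the archive. Each image file
counts as one post record; multi-image posts therefore contribute one row
per image, a choice that has to be documented because the platform's export
format does not disambiguate them.

Participants enter the analysis when they have at least 5 posts spanning at
least 90 days. "Three months" is operationalized as 90 days because
calendar-month arithmetic is ambiguous across month lengths; the filter is
monotone (adding a post can only help inclusion).

# Image features

All pixel statistics treat the image as a complete population: variances
use the 1/n denominator and skewness is m₃/m₂^{3/2}, with the convention
skew = 0 when the channel is flat so that degenerate images produce no
missing values. HSV uses the hexcone transform with hue on [0, 180)
half-degrees and S, V on [0, 255] — the scaling pinned by the 0–179 hue
range convention of 8-bit image libraries. Hue is angular, so per-image
means and the participant-level aggregate both use the circular mean
(resultant vector of the doubled angles); when the resultant length falls
below 1e-8 the direction is undefined and the value is reported missing
rather than fabricated. Whether hue should be aggregated across images
circularly or arithmetically is genuinely open; the circular choice is
self-consistent with the per-image definition and coincides with the
arithmetic mean whenever the per-image hues sit inside a 45° arc.

Colorfulness is the opponent-channel score
√(σ²_rg+σ²_yb) + 0.3·√(μ²_rg+μ²_yb) with population SDs. Aspect-ratio
features use τ = 0.005 on |w/h − 1| to absorb one-pixel rounding at typical
resolutions, and posts timestamped before 2016-01-01 are excluded from
aspect aggregation (non-square uploads only became possible in mid 2015,
and late app updates blur the boundary).

Face counting is detector-pluggable. The bundled template detector slides a
synthetic frontal-face luminance template across the V channel with
normalized cross-correlation (acceptance threshold 0.8, greedy non-maximum
suppression at 3/4 template side). It is deterministic and exactly matched
to the synthetic generator, which composites the same template; it is a
template matcher, not a general face detector, and real-photo deployments
should plug in a trained detector behind the same interface. The stub
detector reads the generator's embedded ground truth and makes pipeline
tests exact.

# Network and temporal features

Connection features come in three families: absolute counts, counts per
month of usage, and scale-free ratios. Usage duration is the first-to-last
post span divided by 30.44 days — a single documented conversion used
everywhere. Ratios with a zero following count are reported missing (not 0,
not infinite) and dropped pairwise with a logged count: a ratio against an
empty denominator carries no information about popularity. The
follower/following ratio is invariant to multiplying both counts by a
constant, which is why it is less biased by usage duration than raw counts
— a property verified in the test suite and checked empirically by the
Spearman correlations the pipeline reports.

Time-of-day bins are half-open with inclusive lower bounds — night [0, 6),
morning [6, 12), afternoon [12, 18), evening [18, 24) — because interval
endpoints in prose ("12 a.m.–6 a.m.") are ambiguous; weekdays are ordered
Monday–Sunday (ISO).

# Statistical layer

**Gate.** For each feature, both group samples are screened with
Shapiro–Wilk at α = 0.05 and an extreme-outlier rule (any point beyond 3
interquartile ranges outside the quartiles). Only when both samples pass
both screens is the Welch t-test used; otherwise the Mann–Whitney U. The
3×IQR operationalization is a choice: "extreme outlier" needed a concrete
rule, and 3×IQR is the standard boxplot definition of *extreme* (vs 1.5 for
*mild*).

**Reporting conventions.** U is reported for the SSD group listed first
(U₁ = R₁ − n₁(n₁+1)/2 with midranks), so values far below n₁n₂/2 indicate
lower case-group values. The p-value is exact by enumeration when
n₁·n₂ ≤ 400 and tie-free, otherwise the tie-corrected normal approximation
with continuity correction. Cohen's d uses the (n−1)-weighted pooled SD and
the SSD − HV sign convention; Hedges g applies 1 − 3/(4N − 9). The d
confidence interval uses the normal approximation
SE = √((n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂))); other published CI constructions
exist and give visibly different intervals at n = 34/34, so the formula in
use is stated here and in `?d_confidence_interval`. No multiplicity
correction is applied in the primary report; a Benjamini–Hochberg column is
available behind `bh = TRUE`.

**Robust between-within ANOVA.** Temporal profiles violate normality and
covariance homogeneity, so the mixed (group × condition) design is tested
on 20 %-trimmed means with winsorized covariances. For group j with nⱼ
subjects, hⱼ = nⱼ − 2⌊0.2 nⱼ⌋ observations per cell survive trimming and
the covariance of the trimmed-mean vector is estimated as
(nⱼ−1)·S_wj/(hⱼ(hⱼ−1)) from the marginally winsorized data. An effect with
contrast matrix C (successive differences, Kronecker-composed across
factors) is tested with T = (Cθ̂)ᵀ(CVCᵀ)⁻¹(Cθ̂), referred to
F(q, q(q+2)/(3A)) after division by c = q + 2A − 6A/(q+2), where A is the
Johansen weighted trace over groups. Trimming is fixed at 20 %, the
standard default in the robust-methods literature; `trim = 0` recovers a
Welch–James test on means whose statistics track the classical mixed
ANOVA (verified by rank agreement in the test suite).

**Response choice.** The ANOVA response is the *posting rate* per condition
(posts per month falling in the bin), not the proportion vector. With exact
proportions every participant's row sums to 1, so the between-group
contrast — a contrast of row sums — is identically zero and its Q statistic
is 0/0. Rates keep the within-subject structure, are non-degenerate for the
group effect, and match the notion of "posting frequency" the design is
meant to probe. The proportion vectors remain available as descriptive
features.

**Matching.** Cases are matched 1:1 without replacement to controls by
greedy nearest-neighbour on the logit of a logistic propensity score over
age, sex and race dummies (4 race levels → 3 dummies), hardest-to-match
cases first, ties broken by input order. This is a deliberate
simplification relative to genetic/optimal matching packages: the
scientific content is the matched design and its balance report
(standardized mean differences before/after, pooled-SD denominator), and
the greedy algorithm is fully auditable. It is not presented as a
reimplementation of any published matcher.

# The synthetic generator

The generator emulates the *statistical structure* the analysis assumes,
not photographs. Defaults are the study conditions: 34 participants per
group; 30–320 posts over 12–84 months each (matching a cohort of roughly
12,000 posts spanning up to ~7.5 years); per-group HSV targets and
between-participant spreads, and face-count rates, taken from the bundled
reference group summaries (e.g. saturation 83.9 ± 9.88 vs 77.63 ± 13.53,
face rate 2.38 vs 1.46); follower/following counts lognormal with moments
matched to the heavily right-skewed reference summaries (HV follower SD
exceeds its mean); a weekend posting uplift (default 1.5× intensity on
Saturday/Sunday) and an evening-heavy time-of-day profile. Images are
sampled per-pixel in HSV around the participant's target (hue wrapped, S/V
clipped — clipping slightly biases means near the range edges, which is why
recovery tests allow ±2 units), faces are composited as luminance-template
patches at non-overlapping grid positions (hue and saturation under the
patch are preserved, so face count does not contaminate the color
features), and every generative parameter lands in a ground-truth manifest.
Everything derives from one seed; the same config reproduces byte-identical
cohorts.

What the generator does **not** emulate: photographic content, filters,
camera characteristics, selfie/foreground structure, within-participant
drift over time, or dependence between color preferences and network size.
Passing tests therefore demonstrate that the pipeline measures what it
claims on data with the assumed structure — not that the group differences
exist in any real population.

For simulations that need thousands of cohorts (calibration, power), the
participant-level model is sampled directly (`sample_cohort_features()`,
`sample_temporal_rates()`) without rendering images; these draws are the
same distributions the archive generator uses.

# Numerical choices and problem sizes

- Circular-mean resultant threshold 1e-8 (below: missing).
- Squareness tolerance τ = 0.005; month length 30.44 days.
- Template detector: threshold 0.8, suppression radius 0.75 template sides,
  zero-variance windows score 0.
- Trim 0.20; winsorized covariance via marginal winsorization; singular
  contrast covariances raise an informative error (the design needs more
  subjects per group than within-subject conditions after trimming, so
  K = 4 needs n ≥ 4 and K = 7 needs n ≥ 7 at trim 0).
- Simulation sizes: the test suite uses 2000 replicates for type-I
  calibration of the gated test and robust ANOVA, 100 cohorts for effect
  recovery and the weekend-uplift pattern, 400 replicates for the
  Gaussian-null ANOVA check, and exhaustive enumeration (all size-3
  multisets over a 4-value alphabet) for the rank-statistic oracles.

# Known limitations

- On bin-count-derived rates (multinomial counts with strongly varying
  totals), the trimmed Johansen interaction test is measurably
  conservative: the calibration the acceptance script computes puts its
  type-I error near 0.03 at nominal 0.05 with n = 34 per group, while the
  identical implementation calibrates to nominal on i.i.d. Gaussian data.
  Conservative means valid but with reduced power for interactions on such
  data.
- At the reference saturation offset (d ≈ −0.53), a two-sample test at
  n = 34 per group recovers the effect in roughly half of simulated
  cohorts (the acceptance script reports the measured rate). Single-study
  significance of effects of this size is fragile; the colorfulness
  (d ≈ −0.70) and face-count (d ≈ −1.0) offsets recover far more reliably.
- The template face detector only detects the bundled template; it
  exercises the detection *path*, and real deployments must supply a
  trained detector.
- The normal-approximation CI for d is one of several published
  constructions and can differ from other conventions by a few hundredths
  at these sample sizes.
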