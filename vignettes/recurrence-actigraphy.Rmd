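---
title: "Quantifying recurrent activity patterns in actigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying recurrent activity patterns in actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rqact)
```

## The problem

Wrist actigraphy yields weeks of minute-resolution activity counts per
person. Classical summaries — the mean count level and the nonparametric
circadian variables IS, IV and RA — describe *how much* someone moves and
*how regular* the daily rhythm is, but say nothing about the texture of
activity in between: whether movement arrives as unpredictable spikes
(restlessness) or as episodes that repeat with similar shape and duration
(a commute, a run, a swim). `rqact` measures exactly that texture with
recurrence quantification analysis (RQA) and compares it between a
depressed (D) and a non-depressed (N) group, where the working hypothesis
is that depression goes with *shorter* and *less diverse* recurrent
activity episodes.

## The analysis chain and its assumptions

1. **Non-wear trimming.** Maximal runs of exactly-zero counts at the start
   or end of the record, at least `trim_zero_run_minutes = 180` min long,
   are removed. Clinical studies often do this by eye; a reproducible
   pipeline needs a mechanical rule, and 3 h of literal zeros at the ends
   of a multi-week recording is far longer than any plausible nap of the
   device on a wrist. Interior zeros are data (sleep) and are kept.
2. **Binning.** Counts are averaged over non-overlapping 10-minute windows
   aligned to the series start; an incomplete trailing window is dropped
   rather than padded, since padding would inject artificial stasis into
   the recurrence structure.
3. **Length harmonisation.** Binned series longer than `max_len = 4000`
   points keep their *first* 4000 (about 28 days); this mimics a fixed
   monitoring window starting at enrolment. Subjects with fewer than
   `min_len = 3000` points (about 21 days) are excluded as "insufficient
   data". Recurrence quantifiers are ratio statistics over N² pairs, so a
   roughly common N keeps their sampling variability comparable.
4. **Rank transform.** Each value becomes its midrank divided by N. This
   (i) is invariant to any monotone rescaling of counts, so devices and
   subjects with different count scales become comparable, (ii) caps the
   leverage of extreme spurts, and (iii) keeps *ties tied*: identical
   counts remain exactly recurrent, which the clutter rule below relies
   on. Ordinal tie-breaking would silently destroy both properties.

## Recurrence plots at a fixed recurrence rate

With `embedding_dim = 1` (the default), two time points recur when their
rank amplitudes differ by at most ε. Rather than choosing ε directly, the
**recurrence rate** RR(ε) — the fraction of ordered pairs within ε, main
diagonal included — is pinned at `target_rr = 0.05`: ε is the smallest
attained pairwise distance whose RR reaches the target (the *first
crossing*; on discrete rank data the target is essentially never hit
exactly). Fixing the rate rather than the threshold makes the quantifiers
comparable across subjects whose amplitude distributions — after ranking —
are identical by construction.

On a tie-free rank series the crossing is analytic: distances live on the
lattice k/N, pairs within lag-ε distance number
`N + 2·Σ_{d≤k}(N−d)`, and at N = 4000 the first count ≥ 0.05·N² occurs at
ε = 101/4000 with achieved rate 801698/16·10⁶ ≈ 0.050106. This worked
example is frozen in the test suite and recomputed by
`scripts/acceptance.R`.

**Clutter exclusion.** If the tied pairs alone already reach the target —
RR(0) ≥ 0.05, which happens when a large fraction z of the series is a
single repeated value (z² ≥ 0.05, i.e. z ≳ 22% after binning) — no
positive threshold can realise a 5% plot and the subject is excluded as
"cluttered". `calibrate_epsilon()` reports this as a flag
(`epsilon = 0`) rather than an error, and the pipeline converts it into an
exclusion via `check_clutter()`; this keeps the calibration function total
while the policy decision stays in one place.

**Conventions** (each configurable): minimum diagonal and vertical line
lengths `l_min = v_min = 2`; entropies in nats; DET's denominator is the
*off-diagonal* recurrence count while LAM's includes the line of identity
(the usual toolbox asymmetry — the LOI is a trivial "diagonal" but a
genuine contributor to vertical stasis); no Theiler window beyond the LOI;
maximum norm for embeddings with `embedding_dim > 1`, which matters only
if the delay-embedding route is switched on — the default compares raw
amplitudes, as is standard for slowly sampled behavioural series, and no
embedding parameters need estimating.

**Numerics.** Threshold search is a bisection over attained distances
using two-pointer pair counting on the sorted series (O(N log N)); line
histograms are accumulated in compiled code directly from the series, so
no N×N matrix is ever built in the pipeline (at N = 4000 the matrix route
exists for plotting and cross-checking and the two routes are asserted
equal in the tests). Distance comparisons carry an absolute slack of
1e-12 — about eight orders of magnitude below the rank-lattice spacing
1/(2N) — because k/N floating-point arithmetic otherwise drops a small
number of exactly-lattice-distance pairs and corrupts the first crossing.

A degenerate but legal corner: an all-ones recurrence plot has two corner
diagonals of length 1, so with `l_min = 2` DET equals 1 − 2/(N² − N), not
exactly 1; LAM is exactly 1. The tests treat DET → 1 as the large-N limit
it is.

## Circadian measures

IS, IV and RA are computed on hourly means of the *raw* (trimmed,
pre-rank) counts over whole days — ranking is an RQA-specific step and
would distort amplitude-based rhythm measures.

* `IS = (N·Σ_h (x̄_h − x̄)²) / (24·Σ_i (x_i − x̄)²)` over the 24 clock-hour
  class means: 1 for a perfectly repeated daily profile, ≈ 1/(number of
  days) for i.i.d. noise.
* `IV = (N·Σ (x_i − x_{i−1})²) / ((N−1)·Σ (x_i − x̄)²)`: ≈ 0 for a smooth
  rhythm, ≈ 2 for white noise (E[MSSD] = 2σ²), exactly 4 for strict
  alternation. For an hourly sinusoid of 24-h period,
  IV → 2(1 − cos(2π/24)) ≈ 0.068 — a closed form the tests verify.
* `RA = (M10 − L5)/(M10 + L5)` with M10/L5 the most/least active 10/5
  *consecutive* hours of the average 24-h profile, searched circularly so
  windows may wrap midnight. A per-day M10/L5 variant exists in the
  literature; the average-profile form is used here and the circular
  search is verified against exhaustive window enumeration.

Both IS and IV are undefined (returned as `NA`, carried with a reason
through the pipeline) for a constant series; RA when the profile is all
zero.

## Group statistics

Welch's unequal-variance t-test with Welch–Satterthwaite degrees of
freedom is computed from group summaries (n, mean, sample SD), so printed
summary tables can be re-tested directly; `t = (mean_D − mean_N)/SE`, so a
deficit in the depressed group appears as negative t. Cohen's d uses the
pooled sample SD with the opposite sign convention (positive when the
non-depressed mean is higher), matching how case-control actigraphy
tables are usually printed. Both SDs zero is resolved by convention
(t = 0 for equal means, ±Inf flagged otherwise). Bonferroni correction
defaults to m = 7, the number of recurrence quantifiers tested.
Logistic regression (ML, with intercept) is summarised by McFadden's
pseudo-R² = 1 − ℓ_model/ℓ_null; perfect separation is detected from
fitted probabilities at the 0/1 boundary and flagged rather than hidden.
Spearman's ρ is the Pearson correlation of midranks with the
t-approximation p-value.

## The synthetic cohort generator

Real clinical actigraphy of this kind is not publicly shareable, so the
generator is a first-class module that emulates the statistical structure
the analysis assumes, with defaults chosen once as a plausible study
configuration:

* **Design:** 25 N + 21 D subjects, 28 days of 1-min epochs (4032 10-min
  bins, truncated to 4000 by the pipeline).
* **Circadian envelope:** a half-sine over a 16-h wake window opening at
  07:00, peak `base_rate = 250` counts/min — giving whole-record mean
  activity around 180–190 counts/min, the order of magnitude wrist
  devices report for ambulatory adults.
* **Nights:** each rest-window epoch is exactly 0 with probability 0.7,
  otherwise a small exponential residual (mean 8) — producing the genuine
  zero runs the clutter rule needs to see, without (at default settings)
  tripping it after binning.
* **Bouts:** Poisson arrivals in the wake window; durations are gamma
  (nonnegative, mean and CV independently controllable — the natural
  two-parameter choice for duration data); within-bout counts follow a
  half-sine template scaled by `bout_gain·base_rate`, so bouts are
  *repeated local shapes* that can produce diagonal recurrence lines, not
  flat plateaus that would only produce stasis. N: mean 60 min, CV 0.6 at
  0.5/wake-hour; D: mean 35 min, CV 0.35 at 0.857/wake-hour — rates scaled
  so expected total bout minutes are equal, isolating *pattern* from
  *amount*.
* **Restlessness:** with probability 0.005 per epoch an exponential spike
  (mean 4·base_rate) is added — noise that should *not* register as
  recurrent structure.
* **Reproducibility:** all draws flow from one spec seed through
  deterministic per-subject seeds; the caller's RNG state is preserved.

What the generator does *not* emulate: weekday/weekend structure, rhythm
phase differences between groups, device-specific count noise, interior
missingness, or any calibration to real per-subject count distributions
(no public quantitative description of them exists to calibrate against).
Passing tests therefore demonstrate that the pipeline recovers differences
in bout duration/diversity under realistic noise — not that real depressed
cohorts will show effects of this size; with these clean defaults the
synthetic effects are far larger than anything a clinical sample shows.
One deliberate side effect to be aware of: equalising total bout time
makes the D group's activity arrive in more, shorter packets, which lowers
hour-to-hour variance and *raises* simulated IS — so the traditional
measures are not all null in the default configuration even though the
circadian parameters are shared.

## Problem sizes and runtime choices

The test suite exercises: the exact N = 4000 calibration crossing; line
extractors against naive scan oracles on 100 random symmetric matrices
(N ≤ 50); determinism ordering across pure sine / SNR 5 / SNR 1 / white
noise at N = 2000 over 10 seeded replicates; direction recovery on 20
replicate 25 + 21 cohorts at full 28-day length; a 20-replicate null
configuration (identical group parameters, 10 + 10 subjects) requiring
|mean t| < 0.5 for all 11 quantifiers; and a 1000-replicate type-I check
of the comparison layer at n = 25/21. These sizes keep the default run in
the low minutes while leaving the Monte-Carlo tolerances (10–20%)
comfortable.

## Known limitations

* "Non-wear" and "clutter" rules are deterministic stand-ins for what
  clinical studies do partly by inspection; their thresholds are exposed
  but their defaults are conventions, not fitted values.
* The 4000-point truncation keeps the earliest data; keeping the last
  window instead would be equally defensible and is a one-line config
  change away conceptually, but is not currently offered.
* Mean activity is computed after trimming and before ranking; studies
  differ on this and rarely say.
* At `embedding_dim = 1`, RQA sees only amplitude recurrences; dynamical
  structure that needs state-space reconstruction requires choosing an
  embedding, which is supported but not auto-selected.
* The LAM/DET ratio is undefined when DET = 0 (pure-noise limit at small
  N); the pipeline flags rather than imputes it.
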