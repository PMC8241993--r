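# rqact — recurrence quantification analysis of actigraphy

`rqact` quantifies the *recurrent structure* of wrist-actigraphy
activity-count series and compares it between a depressed and a
non-depressed group. The motivating question is what, beyond mean activity
level and circadian rhythm strength, distinguishes the physical-activity
patterns of depressed individuals — specifically the **duration** and
**diversity** of recurrent activity episodes (walking, biking, sport), which
classical actigraphy summaries cannot see.

## Method

Each subject's minute-resolution counts are trimmed of end-of-record
non-wear, averaged into 10-minute bins, harmonised to 4000 points (subjects
with fewer than 3000 are excluded), and **rank transformed**
(`x_i -> midrank(x_i)/N`), which makes the analysis invariant to activity
spikes and puts all subjects on a common (0, 1] amplitude scale.

A **recurrence plot** marks every time pair whose amplitudes fall within a
threshold ε: `R_ij = 1 iff |x_i − x_j| ≤ ε`. Instead of fixing ε, the
**recurrence rate is fixed at 5%**: ε is the smallest pairwise distance at
which the fraction of marked pairs (main diagonal included) first reaches
0.05. Subjects whose tied values alone exceed the target (long stretches of
identical inactivity — a "cluttered" plot) are excluded.

Seven quantifiers summarise the plot (minimum line length 2, natural-log
entropies):

| quantifier | meaning |
|---|---|
| DET | fraction of off-diagonal recurrence points on diagonal lines — deterministic, repeating activity |
| LAM | fraction of recurrence points on vertical lines — lingering, static activity |
| L_avg, L_ent | mean / Shannon entropy of diagonal line lengths — duration and diversity of recurrent activity patterns |
| V_avg, V_ent | the vertical-line analogues for static patterns |
| LAM/DET | stasis relative to deterministic structure |

Alongside these, the traditional measures are computed on the raw (pre-rank)
counts: mean activity, interdaily stability (IS), intradaily variability
(IV) and relative amplitude (RA = (M10 − L5)/(M10 + L5) over the circular
average 24-h profile). Groups are compared with Welch's t (sign convention
`t = (mean_D − mean_N)/SE`), Cohen's d (pooled SD, sign `N − D`), Spearman
correlations, and logistic regression summarised by McFadden's pseudo-R²;
Bonferroni-corrected significance is reported alongside raw p-values.

Because the original clinical actigraphy data are not public, the package
ships a **synthetic cohort generator**: 28 days of 1-minute counts per
subject built from a circadian wake/rest envelope with nightly zero runs,
Poisson-arriving activity bouts with gamma-distributed durations and a
half-sine within-bout template, and rare impulsive "restlessness" spikes.
Group structure enters through bout duration mean and diversity (default:
25 "N" subjects with 60 ± 36 min bouts vs 21 "D" subjects with 35 ± 12 min
bouts, arrival rates balanced so expected total bout time is equal).

## Worked example

```r
library(rqact)

spec <- cohort_spec(n_per_group = c(8, 8), seed = 2026)
res  <- run_pipeline(spec)
print(res)
```

```
<pipeline_result> 16 subjects: 16 analyzed, 0 excluded
      quantifier  mean_N  mean_D        t        p       d
1            det   0.460   0.407 -11.2375 4.43e-08  5.6188
2          l_avg   2.937   2.719 -11.8005 5.09e-07  5.9003
3          l_ent   1.258   1.124 -12.7192 6.48e-09  6.3596
4            lam   0.556   0.502  -9.6740 1.87e-07  4.8370
5  lam_det_ratio   1.208   1.232   2.5588 2.31e-02 -1.2794
6          v_avg   3.355   3.119 -10.6911 5.31e-08  5.3455
7          v_ent   1.526   1.403  -9.3676 2.60e-07  4.6838
8  mean_activity 192.204 189.861  -1.0830 3.06e-01  0.5415
9            is_   0.568   0.674  10.2410 2.82e-07 -5.1205
10            iv   0.695   0.696   0.0609 9.52e-01 -0.0304
11            ra   0.957   0.960   1.0504 3.20e-01 -0.5252
```

The simulated depressed group, whose bouts are shorter and less varied by
construction, shows lower `l_avg`, `l_ent` and `det` (negative t: depressed
mean below non-depressed) and a higher `lam_det_ratio`, while mean activity,
IV and RA do not separate the groups — the recurrence quantifiers pick up
structure the traditional measures miss. (IS also separates the simulated
groups: shorter, more frequent bouts leave less hour-to-hour variance, so
day-to-day stability rises mechanically — a known side effect of the
generator's equal-total-activity constraint, discussed in the vignette.)

Single-subject view:

```r
rec <- gen_subject(spec, "N", "N01", seed = 11)
x   <- rank_transform(preprocess_series(rec$series)$binned)
cal <- calibrate_epsilon(x)          # epsilon = 0.02525, rr = 0.0501
rqa_measures(x, epsilon = cal$epsilon)
```

```
<rqa_measures> N = 4000, epsilon = 0.02525, RR = 0.0501
  DET = 0.457  LAM = 0.543  LAM/DET = 1.189
  L_avg = 2.900  L_ent = 1.228  V_avg = 3.287  V_ent = 1.476
```

`plot(recurrence_plot(x, cal$epsilon))` or `render_rp(..., "rp.png")` draws
the plot. A command-line wrapper lives at `inst/cli/rqact-cli.R`
(`simulate` and `run-all` subcommands).

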