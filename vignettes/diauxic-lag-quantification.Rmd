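---
title: "Quantifying diauxic lag times from plate-reader growth curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying diauxic lag times from plate-reader growth curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diauxr)
```

## The measurement

When *Escherichia coli* grows on a mixture of a preferred PTS sugar
(glucose) and a secondary carbon source (lactose, maltose, glycerol, ...),
the culture grows exponentially until glucose is exhausted, arrests while
gene expression is reprogrammed, and then resumes exponential growth on the
secondary sugar. On a logarithmic plot of OD600 against time this produces
three nearly straight stretches: a first growth line, a plateau, and a
second growth line.

`diauxr` quantifies the shift exactly as that geometric picture suggests.
Three line segments are fitted to the log2 OD600 trace; extending the
fitted lines, `Xi` is the time where the first growth line crosses the
plateau line and `Xf` where the plateau line crosses the second growth
line. The diauxic lag is

$$t_{\mathrm{lag}} = X_f - X_i,$$

and because fast-growing cells would be expected to traverse the shift
faster for trivial reasons, the lag is normalized to the generation time
$g$ during first-sugar growth:

$$\mathrm{ratio} = t_{\mathrm{lag}} / g, \qquad g = 1/\mu_1 ,$$

with $\mu_1$ the first-segment slope in doublings per hour. The
dimensionless ratio is the per-well statistic everything downstream
(boxplots, pairwise tests, strain hierarchies) is computed from.

Working in log base 2 means segment slopes are read directly in
doublings/hour and $g$ is the doubling time; any other base would give
identical `Xi`, `Xf`, lag and ratio, since the statistic is a ratio of
times.

## Segmentation by exhaustive least squares

How the original straight lines were drawn (by eye, by regression, over
which windows) is not recorded anywhere we could reconstruct it from, so
the package commits to a fully explicit rule:

* every breakpoint pair $(b_1, b_2)$ leaving at least `min_pts` points per
  segment is enumerated;
* each segment is fitted by ordinary least squares **independently** — the
  three lines need not meet at the breakpoints;
* the pair minimizing the total squared error wins; ties go to the earlier
  $b_1$, then the earlier $b_2$.

A 12-h run at 10-min intervals has 73 points, so the search space is a few
thousand candidates and exhaustive enumeration is exact and effectively
instant (prefix-sum closed-form OLS makes each candidate O(1)). The test
suite cross-checks the search against an independently written brute-force
enumeration built on QR least squares.

Fitting segments independently and intersecting the *extrapolated* lines is
deliberate: the curved retardation and acceleration phases flanking the
plateau belong to none of the three straight stretches, and because a
misassigned curved point inflates the squared error, the optimal
segmentation tends to keep the straight parts pure. The transition
curvature is thereby excluded from the line estimates without any special
mechanism. The middle segment's slope is left free rather than pinned to
zero — the plateau looks flat but nothing guarantees it, and the flatness
(criterion (b) below) is then usable as evidence.

Defaults, and why:

| parameter | default | meaning |
|---|---|---|
| `floor` | 0.01 OD | points at/below are masked (log of near-blank noise would dominate the sse); masked, not clamped |
| `ceiling` | none | optional mask for saturating plates (see below) |
| `min_pts` | `max(3, floor(0.05 n))` | 3 points are the minimum to define a line with a residual; 5% scales with denser grids |
| `r_min` | 5 | criterion (a): one-line sse must be at least 5x the three-line sse |
| `slope_frac` | 0.25 | criterion (b): plateau slope at most a quarter of the first slope |
| `min_lag` | 2 sampling intervals | criterion (c): shorter lags are below grid resolution |

`min_pts` uses the floor, not the ceiling, of 5% — on the 73-point grid that
is 3, which matters: a 0.5-h lag spans only 3–4 grid points, and demanding
4 points per segment would make the shortest biologically interesting
plateaus unrepresentable.

## Classifying diauxie

Shifts between two PTS sugars produce essentially monophasic curves; these
must be recognized, not forced through the lag formula. `detect_diauxie()`
applies criteria (a)–(c) above in order and reports the first failure.
Non-diauxic wells still report a growth rate — from the single-line fit —
but no ratio.

Numerical guard: when a single line already fits to machine precision
(noiseless single exponential), the sse ratio in (a) is 0/0. An absolute
tolerance of 1e-10 on the one-segment sse resolves this: below it the curve
is monophasic by construction, reason (a).

## What the simulator emulates — and what it does not

`simulate_diauxic_curve()` draws from the piecewise-exponential model

$$\mathrm{OD}(t) = \mathrm{blank} + m(t)\,e^{\varepsilon_t},\qquad
  \varepsilon_t \sim N(0, \sigma^2)\ \text{i.i.d.},$$

where $m(t)$ grows at $\mu_1$ doublings/h to $t_1$, is exactly flat to
$t_2$, then grows at $\mu_2$, optionally capped at a carrying capacity.
Multiplicative lognormal noise (additive on log-OD) reflects how
plate-reader error scales with signal and keeps OD positive. The default
schedule is the experimental one: 73 readings, every 10 min over 12 h.

The strain presets encode the study conditions: inoculum OD600 0.05,
first-phase rate 0.46 dbl/h (the measured glucose–lactose rate; succinate
addition raises it to 0.66), noise sd 0.02, six wells per strain (three
runs with duplicate wells). The three presets are labelled by their ppGpp
synthetase content — `sR` (wild type), `R` (RelA-only, SpoT synthetase
point mutant) and `s` (SpoT-only, RelA deletion) — and differ only in
plateau duration. Published data establish the *ordering* of their
normalized lags (wild type quickest, SpoT-only slowest, RelA-only
intermediate) but not the magnitudes, so the default true ratios
`c(sR = 0.5, R = 1, s = 2)` are a choice that respects the ordering with
comfortable separation; they are set once and all recovery statements are
relative to them.

The generator's plateau is exactly flat and its transitions are sharp
corners. Real curves bend smoothly into and out of the lag, saturate
gradually, and carry structured noise (edge effects, condensation,
drift). Passing the recovery tests therefore shows the estimator is correct
*for the stated model* and robust to its noise level — it does not certify
behavior on every real plate. The fitter never assumes the flatness the
generator has.

Two related design points:

* **Carrying capacity.** `diauxic_params()` and `strain_presets()` default
  to no cap so the second-phase slope is well defined across the whole
  window. A real 0.025% glucose + 0.4% lactose well does saturate late in
  the run; `strain_presets(cap = 1.0)` emulates that. A saturating curve
  has *four* phases, and a three-segment fitter pointed at it will happily
  use the stationary plateau as its middle segment. The remedy is the
  analysis-side `ceiling` argument of `log_transform()` /
  `analyze_plate()`: masking the stationary tail (e.g. `ceiling = 0.5`
  with a 1.0 cap) restores the three-phase picture, and the lag statistic
  only ever needed the early second-phase slope. This is the package's
  equivalent of fitting lines to the informative window of the plot.
* **Blanks.** How blank wells were used on the original instrument is not
  recorded; `read_plate_table()` returns blanks separately and the
  bundled CLI applies per-timepoint mean blank correction when blank wells
  exist, logging that it did so. This is a convention, not a
  reconstruction.

## Supporting quantifications

**Fractions of total G.** Nucleotide spot intensities are normalized per
sample to total G = GTP + ppGpp + pppGpp. The three fractions sum to one by
construction; the timecourse templates (`wt_rise`, `relA_spike`,
`spoT_drop`) are piecewise-linear shapes parameterized by the observed fold
changes (a ~30% rise to plateau; a fivefold pentaphosphate spike at
mid-lag; a precipitous drop with slow recovery), because only the
qualitative dynamics are constrained — no functional form is on record.

**Decay kinetics.** After translation arrest, ppGpp fraction-of-total-G
decays exponentially; `decay_rate()` fits OLS of $\ln f$ on time over the
window from `t_start`, giving $k$ (per minute at the default 30-s
sampling) and half-life $\ln 2 / |k|$. Natural log is used internally —
"semilogarithmic" fixes no base — and a log2-equivalent slope is also
reported for consistency with growth rates. Nonpositive fractions in the
window are masked with a warning rather than failing the fit; whether the
original fits excluded late near-zero points is unknown, so masking is a
stated convention. Non-negative slopes are flagged non-decaying instead of
reporting a negative half-life.

**Standard curves and 2^-ddCt.** Assay standards (acetate 1–10 nmole/well;
ATP 0.1–10 mM) are fitted by OLS; interpolation refuses readings mapping
outside the standards' range and instructs dilution, mirroring bench
practice, and rescales by the dilution factor. Comparative-Ct expression
fixes amplification efficiency at 2 and averages technical replicates on
the Ct scale before $\Delta C_t$ — standard comparative-Ct practice; the
aggregation rule is not otherwise recorded. Acetyl-phosphate per-protein
values re-expressed "relative to wild type" divide by the *mean* of the
reference sample's values (`relative_to_reference()`); the anchoring
statistic is again an assumption, noted here.

## Reporting statistics

Boxplot summaries use type-7 (linear-interpolation) quantiles with Tukey
1.5 IQR fences: whiskers reach the most extreme non-outlier values and
outliers are listed singly. The published figure legend describes whiskers
as "minimum and maximum" *and* shows outlier circles — those coexist only
under the Tukey convention, which is what the package implements.

Pairwise comparisons default to Welch's t (robust to unequal variance at
n = 6), with an exact permutation test (all label assignments enumerated
when pooled n is at most 12; seeded Monte-Carlo beyond) as the fallback for
degenerate zero-variance groups and as an assumption-free alternative. The
test behind the published asterisks is unnamed, so the default is a choice.
Star tiers follow the published caption: `**` for p < 0.001, `*` for
p < 0.05, `ns` otherwise. No multiple-testing correction is applied to the
stars (matching per-pair reporting); a Holm-adjusted column is emitted
alongside for transparency. `hierarchy_report()` calls the strain order
concordant only when the observed median ordering matches the expected one
*and* every adjacent pair is significant at the `*` tier.

## Problem sizes and runtime

All simulation-based checks run at the study's own scale: 73-point curves,
18-well plates (3 presets x 6 replicates), 100 repeated plates for the
concordance rate, 20 randomized parameter draws for noiseless recovery,
1000-draw property sweeps for the algebraic invariants. The full test
suite runs in well under a minute on a single core; `scripts/acceptance.R`
regenerates every headline quantity from scratch in a few seconds.

## Known limitations

* Exactly two breakpoints: triauxie or other multi-phase curves are out of
  scope, as are smooth growth models (Gompertz, Baranyi, logistic).
* The lag estimate inherits grid resolution: breakpoints live on the
  sampling grid, so lags shorter than about two sampling intervals are
  unresolvable and are classified away by criterion (c).
* Short plateaus at realistic noise carry a mild upward bias in the
  estimated lag (the three-point middle segment can tilt), visible as a
  few-percent bias of the median ratio for the fastest preset; at the
  study's replicate structure this does not disturb the hierarchy.
* The simulators are phenomenological: no Monod kinetics, no mechanistic
  ppGpp regulation, no TLC densitometry model — intensities and OD arrive
  as numbers.
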