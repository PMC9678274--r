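---
title: "Measuring algorithm-induced criterion shifts in face matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring algorithm-induced criterion shifts in face matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facebias)
```

## The problem

In screening settings a face recognition algorithm proposes an identity
decision — "same person" or "different people" — and a human reviewer
confirms or overrides it. The reviewer is meant to be an independent check,
but prior exposure to the algorithm's decision can bias their judgment.
`facebias` quantifies that bias from panels of reviewers who each rated a
small set of face pairs on a 7-point similarity-confidence scale (coded
−3 "absolutely certain different people" … 0 "not sure" … +3 "absolutely
certain same person") after seeing a randomly assigned algorithm label,
with or without face masks digitally applied to one image of each pair.

## The signal detection model

Ratings are binarized at a threshold θ: ratings above θ confirm the pair as
the same person. The standard decision threshold is θ = 0.5, i.e. ratings
≥ 1. From each reviewer's mated and non-mated trials we count a true
positive rate (TPR) and a false positive rate (FPR), average these with
equal weight across the reviewers of a condition, and summarize the
averaged rates under the equal-variance Gaussian model:

- sensitivity $d' = \Phi^{-1}(\mathrm{TPR}) - \Phi^{-1}(\mathrm{FPR})$,
- criterion $c = -\tfrac12\left(\Phi^{-1}(\mathrm{TPR}) +
  \Phi^{-1}(\mathrm{FPR})\right)$.

The cognitive-bias statistic is the criterion shift between trials labeled
by the algorithm as different versus same,

$$\Delta c = c_{\mathrm{different}} - c_{\mathrm{same}},$$

positive when the label pulls responses in its own direction. Rate shifts
are reported same-minus-different so that positive values carry the same
reading. Sweeping θ over the six half-integer thresholds of the scale
yields a rating-scale ROC (anchored at (0,0) and (1,1), trapezoidal AUC),
and the pair of criteria measured at one θ bounds an *isobias band* in ROC
space: the region between the constant-criterion curves
$(\Phi(-d/2 - c),\ \Phi(d/2 - c))$. Because isobias curves for distinct
criteria never intersect, band overlap is decided exactly in criterion
space — two bands overlap iff their criterion intervals intersect — which
avoids any polyline tolerance issues; a geometric oracle in the test suite
confirms the equivalence.

## Numerical choices

**Extreme rates.** A rate of exactly 0 or 1 has no probit. Such rates are
replaced by $(h + 0.5)/(n + 1)$. The adjustment is applied at the point
where the probit is taken, i.e. to the condition-level averaged rate (with
its total trial count). Applying it per reviewer before averaging is
offered as an option (`adjust = "reviewer"`) but is not the default: with
only three mated and three non-mated trials per reviewer in each label
cell, zero and one rates are common, and nudging each of them inflates the
averaged FPR by two or more percentage points, visibly biasing $d'$ and
$\Delta c$. The aggregated rates, by contrast, are essentially never
extreme in panels of realistic size, so the default leaves interior data
untouched.

**Aggregation.** Per-reviewer rates are averaged with equal weight. With
the balanced roster (every reviewer contributes the same trial counts)
this is identical to pooled counting; it differs only if records are
missing, in which case equal weighting keeps each reviewer's influence
constant.

**Rounding.** Values are carried at full precision; only display
formatting (`make_table()`) rounds to 2 decimal places, the resolution of
the published tables this layout mirrors.

**Degenerate inputs.** A reviewer with no mated or no non-mated trials
under a label stops the computation with an error naming the reviewer; a
face pair never rated under both labels is skipped by the per-pair
significance count; a paired test on a zero-variance difference vector is
flagged `degenerate` rather than erroring, since it arises naturally in
toy data.

## Inference

Reviewers are the exchangeable unit. All confidence intervals are
percentile bootstrap intervals over reviewers with `B = 10000` replicates
by default; the shift tests resample reviewers jointly across the two
label cells (labels are within-subject), and cross-condition comparisons
resample each condition independently. Two-sided p-values are the doubled
tail fraction of replicates crossing zero, clipped to [0, 1], with
significance fixed at 0.05. One master seed governs a run; every stage
derives its own stream from the master seed plus string tags
(`derive_seed()`), so results do not depend on execution order.

The panel-level ANOVAs use `stats::aov`/`stats::lm`: a split-plot (mixed)
two-way ANOVA on accuracy with condition between subjects and decision
label within subjects (between effect tested against subjects-within-
groups; within and interaction against the label × subject residual), and
a one-way between-subjects ANOVA on per-reviewer mean |rating|. The test
suite checks the mixed ANOVA against an independent hand-written
sums-of-squares oracle on randomly generated balanced panels. Post-hoc
confidence comparisons use Welch two-sample t-tests without multiplicity
correction — the emulated studies report bare pairwise p-values without
naming a procedure, so the least-assuming standard test is used and named.
Pair-level comparisons across conditions use a paired t over the 12 common
face pairs (df = 11).

## The synthetic reviewer generator

Real panel data are not bundled, so the package carries a generative
equal-variance observer that makes every stage testable end to end
(`simulate_panel()`). Reviewer $r$ in a condition with population
sensitivity $d$ receives $d_r \sim \max(0,\ \mathcal N(d, 0.3^2))$ and a
criterion offset $o_r \sim \mathcal N(0, 0.2^2)$; the heterogeneity
defaults give bootstrap-over-reviewers realistic variance. The six rating
criteria sit at $d_r/2 + o_r + \beta_k$ with base offsets
$\beta = (-1.0, -0.6, -0.2, 0.2, 0.6, 1.0)$, centered on the reviewer's own
midpoint $d_r/2$ (the standard unbiased placement). The offset spacing of
0.4 latent-axis units was calibrated once so that simulated panels
reproduce the mean absolute similarity-confidence the studies report
(≈ 1.9 of a possible 3); a coarser spacing under-uses the scale ends and
understates reviewer confidence. Algorithm-label coupling is a pure
criterion translation: all six criteria move by $+\Delta c/2$ under a
DIFFERENT label and $-\Delta c/2$ under SAME. This is the minimal
mechanism consistent with the finding that labels shift the criterion at
every threshold while leaving sensitivity and accuracy untouched, and it
makes $\Delta c$ recoverable by construction at any θ. Latent familiarity
is $\mathcal N(d_r, 1)$ for mated and $\mathcal N(0, 1)$ for non-mated
pairs; the rating is the number of effective criteria below the draw,
minus 3.

Each simulated task uses the 14-pair roster of the emulated studies: 8
GFMT-style and 4 MEDS-style scored pairs (6 mated / 6 non-mated, balanced
within source) plus 2 celebrity attention pairs. Within a survey variant,
half the scored pairs carry each label, so each reviewer contributes 3
mated and 3 non-mated trials per label; the two variants flip the
assignment. Inattentive reviewers (probability `attention_error_rate`)
answer both attention pairs with flipped sign and are caught by
`attention_filter()`, which applies the same θ = 0.5 correctness rule as
scoring — the studies do not define attention correctness numerically, so
the scoring rule is reused. Defaults for condition parameters echo the
emulated studies' measurements: $d' ≈ 1.7$ with $\Delta c = 0.21$ unmasked,
$d' ≈ 0.9$ with $\Delta c = 0.45$ masked, $\Delta c = 0.16/0.25$ under the
65%/95% accuracy framing, and $d' ≈ 1.55$ for the label-free control.

### What the generator does and does not emulate

It reproduces: condition-level sensitivity and bias, uniform criterion
shifts across thresholds, reviewer heterogeneity, balanced variant/label
design, attention failures, and the studies' overall confidence level. It
does **not** model per-pair difficulty idiosyncrasy (all scored pairs are
exchangeable; the per-pair significance machinery is exercised but real
pairs differ sharply in difficulty), response times, learning or fatigue
across the 14 trials, super-recognizers, or any dependence of bias on pair
difficulty. Passing tests therefore show the *pipeline* is correct under
the stated observer model, not that the model captures every feature of
human data.

Two estimator-level consequences of heterogeneity are worth knowing. The
probit of an averaged rate shrinks towards zero relative to the average of
probits, so condition-level $d'$ under-recovers the generator value by
roughly 3% at the default heterogeneity (the parameter-recovery test
bounds this at ±0.05 for $d' = 1.7$ at 5000 reviewers per arm); and the
truncation of $d_r$ at zero lifts the effective sensitivity of a $d' = 0$
population to about $0.3/\sqrt{2\pi} \approx 0.12$, which the null-model
tests disable heterogeneity to avoid.

## Problem sizes used by the test suite

Closed-form checks run on the published rate tables directly. Simulation
checks use: 5000 reviewers per arm for parameter recovery (±0.05 on $d'$,
±0.03 on $\Delta c$), 500 study-sized panels (50 reviewers per condition,
B = 1000) for bootstrap coverage of the 95% interval, 2000 such panels for
the type-I rate of the shift test (band 0.03–0.07), and 11 seeds for the
qualitative band-overlap contrast between masked and unmasked conditions.
These sizes put Monte-Carlo noise well inside each acceptance band while
keeping the default test run to a couple of minutes on one core.

## Known limitations

- The equal-variance model is assumed, as in the emulated analyses; an
  unequal-variance or dual-process observer is out of scope.
- AUC is the trapezoidal area of the 6-point empirical ROC and therefore
  slightly underestimates the smooth binormal value
  $\Phi(d'/\sqrt 2)$.
- Isobias bands use the empirical per-threshold criteria, not a smoothed
  fit.
- The bootstrap is percentile-based; at very small panels (tens of
  reviewers) its shift test runs mildly anticonservative, measured at
  about 0.06 type-I for 50 reviewers per condition.
- The column dialect of deposited data files varies; `panel_dialect()`
  remaps headers but the semantic layout (one row per trial) is assumed.
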