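# facebias

Signal detection analysis of how prior face-recognition-algorithm
decisions bias human similarity-confidence judgments in unfamiliar face
matching — with and without face masks.

In human–algorithm teams a face recognition algorithm proposes "SAME
PERSON" or "DIFFERENT PEOPLE" and a human reviewer confirms the decision
after rating the face pair on a 7-point similarity-confidence scale
(−3 … +3, 0 = unsure). `facebias` implements the full analysis pipeline
for such review panels:

- **SDT summaries.** Ratings binarized at a threshold θ (default 0.5,
  i.e. ratings ≥ 1 confirm "same"); per-reviewer TPR/FPR averaged per
  condition; equal-variance Gaussian sensitivity
  `d' = Φ⁻¹(TPR) − Φ⁻¹(FPR)` and criterion
  `c = −(Φ⁻¹(TPR) + Φ⁻¹(FPR))/2`.
- **The cognitive-bias statistic.** The criterion shift between algorithm
  labels, `Δc = c_different − c_same`: how far the algorithm's decision
  moves the reviewer's internal criterion.
- **ROC and isobias geometry.** Rating-scale ROC curves across all six
  thresholds with trapezoidal AUC; constant-criterion (isobias) curves
  `(Φ(−d/2 − c), Φ(d/2 − c))` and the bands spanned by the two label
  criteria at each threshold, with exact overlap detection in criterion
  space.
- **Inference.** Percentile bootstrap over reviewers (CIs, within- and
  cross-condition shift tests with doubled-tail p), mixed two-way ANOVA
  on accuracy (condition × decision label), one-way ANOVA and Welch
  post-hocs on mean absolute confidence, per-pair and pair-level t-tests,
  and trust-question proportions.
- **A synthetic reviewer generator.** A seeded equal-variance observer
  whose rating criteria shift by ±Δc/2 with the presented label,
  emulating every condition of the two studies this pipeline targets
  (14-pair rosters with celebrity attention checks, survey variants,
  reviewer heterogeneity), so the whole chain is testable without any
  raw study data.

## Worked example

Simulate a study-sized panel (50 reviewers per condition, a 5% planted
inattention rate), run the pipeline, and format the study table:

```r
library(facebias)

cfg <- simulation_config(n_per_condition = 50,
                         conditions = c("control", "no_mask", "mask"),
                         attention_error_rate = 0.05, seed = 42)
report <- run_pipeline(run_config(cfg, B = 2000, seed = 42))
report
#> <study_report>
#>   5 summary rows, 6 shift rows, 8 reviewers excluded
#>   criterion shifts (delta_c):
#>     no_mask  0.300 (p = 0)
#>     mask     0.372 (p = 0)

make_table(report, "study1")
#>  Condition    Mask Algorithm Decision  n % Correct (95% CI)     FPR (95% CI)     TPR (95% CI)      d' (95% CI)        c (95% CI)
#>    control No Mask               NONE 45   0.76 (0.73-0.79) 0.19 (0.14-0.23) 0.70 (0.64-0.77) 1.43 (1.24-1.65)  0.18 (0.05-0.31)
#>    no_mask No Mask          DIFFERENT 49   0.78 (0.73-0.82) 0.12 (0.07-0.16) 0.67 (0.59-0.74) 1.63 (1.32-1.98)  0.38 (0.22-0.56)
#>    no_mask No Mask               SAME 49   0.79 (0.75-0.84) 0.18 (0.13-0.24) 0.77 (0.69-0.84) 1.64 (1.32-1.97) 0.08 (-0.08-0.26)
#>       mask    Mask          DIFFERENT 48   0.65 (0.59-0.70) 0.19 (0.14-0.25) 0.49 (0.40-0.57) 0.83 (0.53-1.12)  0.45 (0.29-0.61)
#>       mask    Mask               SAME 48   0.67 (0.61-0.73) 0.31 (0.22-0.39) 0.64 (0.55-0.72) 0.86 (0.55-1.21) 0.08 (-0.09-0.25)
```

Reading the output: masks cut sensitivity roughly in half (d' ≈ 0.85 vs
≈ 1.63) while accuracy drops about 12 points, and the criterion sits much
higher under a DIFFERENT label than a SAME label — the reviewers drift
with the algorithm. The shift table quantifies that drift per condition
with bootstrap CIs:

```r
subset(report$shifts, metric == "c")
#>   condition metric  estimate    ci_low   ci_high p significant  n
#> 1   no_mask      c 0.2997258 0.1103107 0.4920340 0        TRUE 49
#> 4      mask      c 0.3717289 0.1781462 0.5684024 0        TRUE 48

report$anova_accuracy
#>        effect            F df_num df_den            p
#> 1     between 23.635568698      1     95 4.596892e-06
#> 2      within  0.524963506      1     95 4.705127e-01
#> 3 interaction  0.005378906      1     95 9.416889e-01
```

Here masks significantly reduce accuracy (the between effect) while the
algorithm label itself does not (within and interaction effects) — even
though the same labels shift the criterion strongly.

Existing task data in the standard one-row-per-trial CSV dialect flow
through the same path via `run_config("path/to/task.csv", ...)`, with
`panel_dialect()` remapping nonstandard column names. A thin command-line
wrapper with `simulate` / `analyze` / `report` verbs ships in
`inst/scripts/facebias-cli.R`.

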