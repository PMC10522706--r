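# segnoninfer

Non-inferiority evaluation of 3D segmentation agreement.

## The problem

For structures whose true extent experts themselves disagree about — the
motivating case is the hypodense ischemic core on non-contrast head CT —
judging an automatic segmentation model against a single "ground truth"
rater conflates model error with ordinary inter-rater variability. The
scientifically meaningful claim is **non-inferiority**: for each agreement
metric, the model-to-expert agreement is no worse than the expert-to-expert
agreement, up to a margin δ that represents the normal variation among
experienced raters.

`segnoninfer` provides the full evaluation stack for that claim:

* **Agreement metrics** for co-registered 3D binary masks on anisotropic
  voxel grids: volumetric similarity (VS), absolute volume difference
  (AVD, ml), Dice, precision, recall, 95th-percentile Hausdorff distance
  (HD95, mm), and surface Dice at tolerance (SDT, default τ = 5 mm), with
  explicit, flagged conventions for empty masks. Surface distances use an
  exact anisotropic Euclidean distance transform (compiled), pinned in the
  test suite against a literal all-pairs implementation.
* **The statistical framework**: per metric, paired oriented differences
  `d_i = (model-expert) − (inter-expert) + δ` (sign-flipped for
  lower-is-better metrics), a Shapiro-gated one-sided test (paired t if the
  differences look normal, Wilcoxon signed-rank otherwise, exact for small
  n), Holm–Bonferroni adjustment across the battery, percentile-bootstrap
  95% CIs for medians, and Spearman volume correlation. Default margins:
  0.2 for unit-interval metrics, 3 ml for AVD, 3 mm for HD95;
  `derive_margins()` re-derives them from inter-expert variability.
* **A synthetic multi-rater cohort generator**: irregular ellipsoidal
  lesions (5–30 ml) plus simulated annotators parameterised by boundary
  jitter, systematic volume bias, and sensitivity — so calibration, power,
  and reproducibility of the whole pipeline are testable without any
  clinical data.
* **NIfTI I/O and a CLI** (`inst/cli/segnoninfer.R`) with
  `simulate`, `evaluate`, and `noninferiority` subcommands driven by a YAML
  config.

## Worked example

```r
library(segnoninfer)

cases     <- generate_cohort(32, seed = 1)      # 3 raters + model, 32 cases
agreement <- evaluate_cohort(cases)             # B vs A and B vs model
battery   <- run_noninferiority_battery(agreement)
tidy(battery)[, c("metric", "n_cases_used", "median_inter", "median_model",
                  "margin", "test_used", "p_adjusted", "non_inferior")]
```

```
     metric n_cases_used median_inter median_model margin test_used p_adjusted non_inferior
1        VS           32        0.890        0.885    0.2  paired_t   1.72e-13         TRUE
2       AVD           32        3.538        4.063    3.0  paired_t   2.06e-05         TRUE
3      Dice           32        0.620        0.613    0.2  paired_t   2.00e-21         TRUE
4 Precision           32        0.590        0.568    0.2  paired_t   3.44e-14         TRUE
5    Recall           32        0.632        0.631    0.2  paired_t   1.22e-17         TRUE
6      HD95           32       10.572       11.209    3.0  paired_t   7.24e-09         TRUE
7       SDT           32        0.750        0.762    0.2  paired_t   2.70e-21         TRUE
```

Per metric: the median agreement of the inter-expert pairing (test rater B
vs reference rater A) and of the model-expert pairing (B vs model), the
non-inferiority margin, which test the Shapiro gate selected, and the
Holm-adjusted one-sided p-value. Here the simulated model shares the
reference rater's characteristics, so every metric is declared non-inferior
at α = 0.05 — e.g. for Dice, the model-expert median 0.613 is within the
0.2 margin of the inter-expert median 0.620, with p ≪ 0.05 for the
one-sided test of the margin-shifted paired differences. `glance(battery)` summarises the run;
`autoplot(battery)` draws the medians with their bootstrapped CIs, and
`plot_volume_agreement(cohort_volumes(cases), "A", "model")` shows per-case
volume agreement with its Spearman R.

The command-line equivalent:

```sh
Rscript inst/cli/segnoninfer.R simulate --out cohort/ --seed 1
Rscript inst/cli/segnoninfer.R evaluate --cohort cohort/ --out agreement.csv
Rscript inst/cli/segnoninfer.R noninferiority --agreement agreement.csv --out report.json
```

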