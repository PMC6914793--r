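# bpequant

Quantification of breast **background parenchymal enhancement (BPE)** and
**fibroglandular tissue (FGT)** from pre/post-contrast DCE-MRI volume pairs,
with the cohort statistics used in treatment-response studies, and a synthetic
phantom with exact ground truth for validating every stage.

## What it computes

For an early-phase pre/post-contrast pair, each voxel's relative enhancement
is

    R = (I_post − I_pre) / I_pre

and the package reports, over an operator-delimited breast region:

* **FGT%** = 100 · V_FGT / V_Breast — the fibroglandular fraction of the
  breast, with FGT segmented by two-class fuzzy C-means;
* **BPE20%** = 100 · V_BPE / V_FGT — the fraction of FGT volume enhancing at
  or above 20% (the threshold is inclusive);
* **ΔBPE20%** — the signed percent change of BPE20% between two studies of
  the same patient.

The per-study pipeline (`run_patient()`) chains bias-field correction,
registration of the post volume onto the pre-contrast grid, supervised
chest-wall delimitation, FGT segmentation, and the ratio-map metrics. A
cohort runner (`run_cohort()`) batches studies, pairs timepoints into
ΔBPE20%, and collects per-patient failures without aborting. A statistics
layer covers diagnostic accuracy with confidence intervals, Cohen's and
Fleiss' kappa, Pearson correlation, Student's t, and a Cox
proportional-hazards model for recurrence-free survival with
`tidy()`/`glance()` accessors.

## Worked example

The phantom generator builds a bilateral-breast volume pair whose true BPE20%
and FGT% are exact by construction, then degrades it with a 30% bias field,
2 mm of inter-scan motion and 5% noise:

```r
library(bpequant)

ph <- generate_phantom(phantom_params(seed = 42, noise_sigma = 0.05,
                                      bias_amplitude = 0.3,
                                      motion_translation = c(2, 0, 0)))
c(ph$truth$bpe20_true, ph$truth$fgt_pct_true)
#> [1] 50.01081  9.999568
```

Chest-wall delimitation is supervised; here the operator's control points lie
on the known wall plane:

```r
d <- ph$params$grid_shape; sp <- ph$params$spacing
pts <- expand.grid(x = seq(1, d[1], length.out = 6) * sp[1],
                   z = seq(1, d[3], length.out = 6) * sp[3])
pts$y <- ph$truth$chest_wall_y * sp[2]
chest <- chest_wall_spec(control_points = pts)

rec <- run_patient(ph$pre, ph$post, chest)
rec[, c("bpe20_pct", "fgt_pct", "v_breast", "v_fgt", "v_bpe", "n_invalid")]
#>   bpe20_pct  fgt_pct v_breast v_fgt v_bpe n_invalid
#> 1  51.35077 9.999568    46272  4627  2376         0
round(rec$reg_translation_mm[[1]], 3)
#> [1]  1.999 -0.005  0.026
```

BPE20% is recovered within 1.4 points of truth and FGT% to four decimals; the
simulated 2 mm motion is recovered to ~0.03 mm.

The statistics layer works on plain tables. Sensitivity/specificity with Wald
intervals from a 2×2 response table:

```r
diagnostic_accuracy(tp = 25, fn = 2, fp = 12, tn = 63)[, 5:10]
#>   sensitivity specificity sens_ci_lo sens_ci_hi spec_ci_lo spec_ci_hi
#> 1        92.6          84       82.7        100       75.7       92.3
```

and a recurrence model on a simulated cohort with a known hazard structure:

```r
set.seed(9)
co <- simulate_recurrence_cohort(n = 120, beta_bpe = 1.2,
                                 baseline_hazard = 0.01)
fit <- fit_recurrence_model(co, "bpe20_post")
tidy(fit)
#>         term log_hr hazard_ratio hr_ci_lo hr_ci_hi std_error p_value
#> 1 bpe20_post  0.915          2.5     1.13     5.51     0.404  0.0237
glance(fit)
#>     n n_events lrt_statistic lrt_df lrt_p_value concordance
#> 1 120       31          5.09      1       0.024       0.602
```

## Command line

A thin CLI wraps the same functions
(`Rscript inst/cli/bpequant.R <subcommand>`; after installation,
`system.file("cli", "bpequant.R", package = "bpequant")`):

```sh
bpequant.R phantom  --out phantom_dir --seed 7
bpequant.R quantify --pre pre.nii.gz --post post.nii.gz \
                    --chest wall_points.csv --out results/
bpequant.R cohort   --manifest manifest.csv --out cohort_results/
bpequant.R stats    --table clinical.csv --covariates bpe20_post --out cox.csv
```

Volumes are NIfTI-1; configuration is YAML (`default_config()`,
`write_config()`); every run writes its resolved config next to its outputs.

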