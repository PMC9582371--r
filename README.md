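# scfmri

Simulation and analysis of value-based dietary self-control fMRI
experiments, end to end and fully testable offline.

## The problem

In the classic food-choice self-control paradigm, participants rate ~50
food items on healthiness and tastiness (5-point scales coded −2..+2) and
then decide, on the same scale, whether to eat each item instead of a
neutral reference food — the decision rating is the item's **goal value**.
Declining a liked-but-unhealthy food (or choosing a disliked-but-healthy
one) is an act of self-control; people who manage it on at least half of
the trials that demand it are **self-controllers (SC)**, the rest
**non-self-controllers (NSC)**. The neural analysis asks where goal value,
health and taste are encoded (vmPFC), whether dlPFC is more engaged during
successful self-control, and whether dlPFC and vmPFC are functionally
coupled (PPI). The analysis pipeline itself — parametric modulators with
sequential orthogonalization, per-subject peak-voxel ROI extraction,
two-stage PPI — is statistically delicate, and one of this package's jobs
is to quantify those pitfalls (notably the circularity of non-independent
peak selection) on data where the truth is known.

`scfmri` therefore ships, as first-class tested code:

* **`sim_config()` / `generate_dataset()`** — a BIDS-like synthetic
  dataset generator: behaviour from an ordered-choice model
  u = w_h·H + w_t·T + ε, BOLD from a forward model
  (HRF-convolved regressors × region amplitudes + cosine drift + AR(1)
  noise) on a labelled 3 mm voxel grid with a guaranteed-null white-matter
  region, motion traces, masks and a ground-truth sidecar.
* **`classify_participant()`, `choice_regressions()`,
  `group_choice_table()`, `robust_regression()`** — trial categorization,
  the three-criteria and one-criterion SC/NSC classifiers, and the
  behavioural statistics.
* **`build_design()`, `fit_first_level()`, `contrast_map()`,
  `group_ttest()`, `threshold_map()`** — five first-level GLMs
  (reaction-time boxcars, mean-centred sequentially orthogonalized
  parametric modulators, 128 s discrete-cosine high-pass, AR(1)
  prewhitening), group t tests, uncorrected and Benjamini–Hochberg FDR
  thresholds with cluster tables.
* **`select_peak_voxel()`, `extract_roi_signal()`,
  `selection_bias_experiment()`** — peak-voxel vs. mask-mean ROI
  extraction and the white-matter circularity control.
* **`extract_seed()`, `deconvolve_neural()`, `run_ppi()`** — seed
  localization, ridge/GCV hemodynamic deconvolution, and the
  psychophysiological-interaction regression, reseedable for a second
  stage.
* **`read_dataset()`, `run_pipeline()`, `report_pipeline()`** — the
  one-call driver that chains every stage over a dataset directory and
  writes tidy CSVs plus a hashed run manifest.

See the methods vignette (`vignettes/methods.Rmd`) for the models,
parameter choices and their rationale.

## A worked example

Simulate an 80-subject behavioural cohort at the default study conditions
(15 SC-truth subjects) and classify it:

```r
library(scfmri)
set.seed(42)
cfg      <- sim_config()
stimuli  <- simulate_stimuli(cfg)
classes  <- rep(c("SC", "NSC"), c(15, 65))
profiles <- lapply(classes, function(cl) simulate_subject(cfg, stimuli, cl))
labels   <- vapply(profiles, function(p)
  classify_participant(p, "one_criterion")$label, "")
table(truth = classes, classified = labels)
#>      classified
#> truth NSC SC
#>   NSC  65  0
#>   SC    1 14

tab <- group_choice_table(profiles, labels)
round(tab$proportions[, c("mean_sc", "mean_nsc", "t", "df", "p")], 4)
#>   mean_sc mean_nsc       t df      p
#> 1  0.8504   0.9005 -1.8586 78 0.0669   # liked_healthy
#> 2  0.1879   0.6796 -8.4096 78 0.0000   # liked_unhealthy
#> 3  0.5833   0.1605  6.3348 77 0.0000   # disliked_healthy
#> 4  0.0643   0.0685 -0.1185 78 0.9060   # disliked_unhealthy
```

The classifier recovers the ground-truth groups almost perfectly, and the
choice table shows the signature of self-control: SC subjects accept
liked-unhealthy foods far less often (0.19 vs. 0.68, t(78) = −8.4) while
the groups agree on the uncontroversial categories. For the imaging side,
`generate_dataset(cfg, path)` followed by
`run_pipeline(pipeline_config(path, out))` produces the group goal-value
map, the per-level vmPFC profiles, the health/taste order-robustness
extractions, the SC/NSC comparison, the white-matter circularity control
and the two-stage PPI, each as a CSV table under `out/`.

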