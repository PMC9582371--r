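---
title: "Models and methods behind scfmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scfmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`scfmri` implements, end to end, the analysis of a value-based dietary
self-control fMRI experiment: participants rate 50 food items on healthiness
and tastiness (5-point scales coded −2..+2), then decide on the same scale
whether to eat each item instead of a neutral reference food (the decision
rating is the item's *goal value*). Participants who decline liked-unhealthy
foods or choose disliked-healthy foods exercise self-control; classifying
people by how often they do so splits the sample into self-controllers (SC)
and non-self-controllers (NSC). The neural questions are where goal value,
health and taste are encoded (vmPFC is the canonical valuation region),
whether dlPFC is more active during successful self-control, and whether
dlPFC and vmPFC are functionally coupled. Because the statistical pitfalls
of this analysis style — non-independent peak-voxel selection above all —
are themselves part of the subject matter, every stage runs on synthetic
data with known ground truth.

## The behavioural model

Each stimulus carries latent healthiness H\* and tastiness T\*. H\* is a
two-component normal mixture (junk vs. healthy component, weights 0.56/0.44,
means −1.5/+1.15, sd 0.5) and T\* is normal(0.63, 1.2); after adding
subject-level rating noise (sd 0.35) and discretizing at fixed cut-points
±0.5, ±1.5 (clamped to ±2), the simulated rating distributions match the
published descriptive statistics of snack-food stimulus sets of this kind
(mean health ≈ −0.35, SD ≈ 1.41; mean taste ≈ 0.57, SD ≈ 1.10). A
correlation parameter (default 0) couples the two latents through a shared
Gaussian factor.

Decisions follow an ordered-choice model on the utility
u = w~h~·H + w~t~·T + ε with logistic noise (scale 1.2) and the same fixed
cut-points, where H and T are the subject's own discretized ratings. SC
ground truth uses (w~h~, w~t~) = (1.8, 0.6) and NSC the mirror (0.6, 1.8).
Two constraints fixed these values, both decided before any test was run:

* **Closure.** With all noise off, an SC-truth subject must be classified
  SC with probability one. Success on every self-control trial is
  guaranteed exactly when w~h~ ≥ 2·w~t~ + 0.5 (the worst case is a
  liked-unhealthy item rated H = −1, T = +2); the default pair sits just
  inside that bound.
* **Realism.** With noise at its default, an 80-subject cohort at the
  default SC fraction (15/80) reproduces the behavioural landscape such
  experiments report: roughly 15/65 SC/NSC under the one-criterion rule and
  liked-unhealthy acceptance proportions near 0.19 (SC) vs. 0.7 (NSC).

The classifier implements both rules: the three-criteria rule (success rate
strictly above 50%; a larger standardized health than taste coefficient in
the multiple regression of decisions on both ratings; a larger simple-
regression R² for health) and the relaxed one-criterion rule (success rate
at least 50%). Two points were genuinely open and are decided here:
criterion 2 compares *absolute standardized* coefficients (H and T share
the −2..+2 scale, so this is nearly the raw comparison, but it is invariant
to sign conventions), and a neutral decision on a self-control trial counts
as a failure, since it is neither a decline of a liked-unhealthy item nor a
choice of a disliked-healthy one. Missing decisions leave both numerator
and denominator of the success rate.

`robust_regression()` is a plain Huber M-estimator (tuning 1.345, IRLS with
MAD scale, convergence when no coefficient moves by more than 1e-8, at most
50 iterations) with heteroscedasticity-robust sandwich standard errors; it
backs the brain-behaviour regressions, and the test suite cross-checks it
against an independent M-estimation implementation.

## Trial timing

Stimuli appear for at most 4 s and the regressor boxcar lasts the reaction
time; 0.5 s of feedback follows the response, then an inter-trial interval
uniform on 4–15 s. Reaction times are truncated log-normal (median 1.2 s,
log-sd 0.4, resampled above 4 s) — the RT distribution is not constrained
by any published value and is a free modelling choice here; it only sets
boxcar durations. Feedback is deliberately left unmodelled so it falls into
the implicit baseline. One run per block (health, taste, decision; rating
block order counterbalanced across subjects, decision always last), 343
volumes per run at TR 2 s.

## The forward BOLD model

For every voxel, signal = Σ amplitude(region, regressor) ×
HRF-convolved regressor + low-frequency drift + AR(1) Gaussian noise. The
canonical HRF is the usual double gamma (peak 6 s, undershoot 16 s, ratio
6, truncated at 32 s), scaled here to unit peak so amplitudes read directly
in signal units. Drift is a random combination of the first three
discrete-cosine components below the 1/128 Hz cutoff — by construction the
high-pass basis removes it exactly, which makes the filter itself testable.
Noise is stationary AR(1) (default ρ = 0.3, sd 1). Motion traces are six
slowly varying AR(1) excursions bounded by ±1 mm/deg with no coupling to
the task; they exist to exercise the nuisance-regression paths. Region
ground truth lives on a 20×20×20 grid of 3 mm voxels (RAS affine, grid
centre at the origin) with six disjoint box regions: vmPFC (goal value in
everyone, health additionally in SC-truth subjects, taste in both),
caudate (weak goal value), left dlPFC (response to unhealthy foods — the
seed localizer signal), left IFG (the connectivity target), white matter
(all amplitudes zero, enforced by a validator — the null region every
circularity analysis relies on), and background. For the decision run a
latent seed fluctuation can couple into the target region during
unhealthy-food trials with configurable amplitude; that is the generative
PPI effect.

## First-level GLMs

Five models cover the analysis: (1) block boxcars with a goal-value
parametric modulator per block plus a missing-ratings boxcar; (2) one
boxcar per decision level; (3a/3b) block boxcars with health and taste
modulators in either entry order; (4) decision trials partitioned into
successful self-control, unsuccessful self-control, self-control not
required, neutral response, and missing ratings; (5) the same partition
with the self-control trials split by type (liked-unhealthy vs.
disliked-healthy). Model 4 carries an explicit unsuccessful-self-control
boxcar because the downstream peak-selection analyses contrast successful
against unsuccessful trials per subject; leaving those trials in the
baseline would make that contrast inexpressible. A localizer variant
(`ppi_seed`) with healthy/unhealthy boxcars supports seed selection.

Parametric modulators are mean-centred within condition, sequentially
orthogonalized (Gram–Schmidt against the condition boxcar and earlier
modulators, on the microtime grid, *before* convolution) and convolved at
16 bins per TR, sampling the middle bin. Orthogonalization never changes
the span of the model — total fit is identical for 3a and 3b — it only
pushes shared variance toward earlier-entered regressors, which is exactly
the order-dependence the two model versions quantify. Whether model 3 uses
all runs or only the decision run is analysis-dependent; both are
supported (`all_trials`), with all runs as the default.

High-pass filtering is implemented as per-run discrete-cosine nuisance
columns (cutoff 128 s) inside the design rather than as a separate
projection; the task betas are identical either way and the residual df
come out automatically as n − rank(X). Six motion columns (stacked across
runs) and per-run constants complete the design. Conditions with zero
trials are dropped, never zero-filled, and recorded; contrasts that
reference a dropped column raise an error rather than silently returning
zero.

Fitting uses one pooled AR(1) estimate: OLS residuals give a lag-1
autocorrelation pooled over all in-mask voxels (computed run-wise so runs
never mix), a (1, −ρ̂) prewhitening transform is applied to data and
design, and the GLS pass yields betas, residual variance and df. A single
global ρ̂ is a deliberate simplification — it is testable (the estimate
recovers the generating ρ to ±0.05 on filtered-free designs) and adequate
when the noise is homogeneous, as here; voxelwise AR models are out of
scope. When residuals are numerically zero the estimator returns ρ̂ = 0
instead of a ratio of rounding errors. Smoothing (isotropic Gaussian, FWHM
8 mm, separable implementation) is applied to the BOLD volumes before
fitting in the full pipeline and switched off (`fwhm = 0`) in unit tests
and parameter-recovery simulations, where spatial blur would only couple
the regions the tests need independent.

Group inference is a voxelwise one-sample t against zero or a
pooled-variance two-sample t (df = n₁ + n₂ − 2, the convention that
produces t(78)-style df for 15 vs. 65 subjects). Thresholding supports
uncorrected p < .001 and p < .005 and Benjamini–Hochberg FDR at q = .05
over in-mask voxels; surviving voxels are grouped into 18-connected
components with peak mm coordinates from the affine.

## ROI extraction and the circularity control

Two extraction strategies are first-class: per-subject *peak voxel*
(argmax of a selection-contrast beta inside a mask, ties broken by lowest
linear index for determinism) and *mask mean*. Selection and test
statistics are subject-level betas, matching the bar-plot conventions of
this literature. When the selection contrast and the test contrast share
noise, peak extraction is circular: it reads the maximum of many noisy
values at a threshold meant for one. `selection_bias_experiment()`
quantifies this on the simulator's white matter, where zero effect is
guaranteed: a cohort of decision-run designs is drawn once, each
simulation draws fresh AR(1) noise, each subject's peak is selected on the
successful-minus-unsuccessful contrast, and the successful-vs-unsuccessful
betas at those peaks enter a paired t test, against the same test on mask
means. At the default noise preset with a 60-voxel null mask and 20
subjects the mean strategy rejects at the nominal 5% while the peak
strategy rejects in essentially every simulation — the quantitative form
of the warning against non-independent ROI selection.

## PPI

The seed localizer (healthy/unhealthy boxcars + nuisance, decision run
only) picks the voxel with the strongest positive unhealthy-food response
inside the supplied mask; the BOLD series averaged over a 4 mm sphere
around it is cleaned of motion (and mean) by projection. Deconvolution to
a neural series inverts the causal HRF Toeplitz operator at acquisition
resolution with a ridge penalty chosen by generalized cross-validation
(fallback λ = 1). TR resolution rather than a microtime grid is a
deliberate choice: at 16 bins per TR the inversion is 16-fold
underdetermined and the extra unknowns are pure regularization artifacts;
at TR resolution the round-trip property (relative error below 5% on
band-limited signals, monotonically improving as noise vanishes) is
directly testable. The PPI regression has the interaction (neural ×
centred unhealthy indicator, +½/−½ coding over unhealthy/healthy trial
windows, stimuli with neutral health ratings excluded by default),
the convolved indicator, and the observed seed series, plus motion,
high-pass and constant columns; only the first two are convolved, since
the seed series is already hemodynamic. Centring the indicator reduces
main-effect collinearity; a VIF above 30 on the interaction column
triggers a warning. Including the main effects makes the interaction beta
invariant to constant shifts of the seed series, and the test suite checks
that invariance explicitly. A second-stage PPI reseeds from the largest
first-stage group cluster inside the target region's label and repeats
the regression.

## Pipeline, determinism and problem sizes

`generate_dataset()` writes a BIDS-like tree (events/motion TSVs, gzipped
NIfTI BOLD, label masks, a ground-truth JSON sidecar) fully reproducible
from the configuration seed; `read_dataset()` validates and reloads it;
`run_pipeline()` chains classification, the group goal-value map, the
goal-value level profiles, the order-robustness extractions, the
brain–behaviour regression, the SC/NSC comparison, the white-matter
control and the two-stage PPI, caching first-level fits per model,
recording per-stage status and wall clock in a manifest with file hashes,
and skipping downstream stages when a dependency fails. Every stochastic
step funnels through the configuration seed, so rerunning a configuration
reproduces every output hash.

Simulation-backed checks use deliberately scaled problem sizes chosen to
make Monte-Carlo error small relative to the margins being tested:
parameter recovery uses 20 repetitions of 30-subject cohorts on the
region voxels it measures; the circularity experiment uses 1,000
simulations; FDR calibration 500; PPI recovery 20 simulations of
10-subject cohorts on a 12³ grid. The full pipeline demonstration in the
test suite runs four subjects on a 10³ grid. What passing these tests
shows — and what it does not — deserves one honest sentence: the
synthetic data share the analyses' statistical structure (their
regressors, noise model and null regions) but none of real fMRI's
spatial noise correlation, physiological confounds, motion-signal
coupling or registration error, so the tests validate the estimators and
their calibration, not the biology.

## Known limitations

Preprocessing beyond smoothing and high-pass filtering (slice timing,
motion correction, normalization) is out of scope; the generator emits
"preprocessed" data. The AR(1) model is global, not voxelwise. Masks are
supplied on the common grid; no resampling or atlas construction is
provided. The deconvolution is a transparent ridge inverse, not an
empirical-Bayes scheme, and equivalence with any particular software's
deconvolution is not claimed — only the qualitative properties the tests
state.
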