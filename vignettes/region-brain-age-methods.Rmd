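---
title: "Region-wise multimodal brain-age modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-wise multimodal brain-age modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Brain-age prediction trains a regressor of chronological age on neuroimaging
features of healthy subjects; applying it to a clinical group and subtracting
chronological age yields the *brain-age gap*, a summary of apparent
accelerated (positive gap) or delayed (negative gap) aging. Whole-brain
models yield a single gap per subject and modality; this package instead
fits one model per atlas region and per modality — gray-matter (GM)
intensity maps over 90 cerebral regions, voxel-wise average functional
connectivity (FC) maps over the same 90 regions, and fractional anisotropy
(FA) maps over 48 white-matter tracts, 228 models in all — so that aging
trajectory deviations can be localised and related, region by region, to
clinical characteristics such as illness duration in schizophrenia.

The cohorts this design targets are confidential, so the package ships a
synthetic cohort generator that emulates the data structure (a training
cohort of 230 healthy controls aged 20–84; test cohorts of controls and
patients; parcellated voxel maps per modality) with machine-readable ground
truth. Every pipeline stage is exercised and validated against that ground
truth.

## Pipeline and model

1. **Maps** (`generate_region_maps`, `fc_maps_from_bold`,
   `parcellate_volume`). Each subject contributes one voxel-value vector per
   region and modality. FC values are Fisher-z transformed average
   correlations: for voxel $v$, $\mathrm{FC}_v = \frac{1}{V-1}\sum_{u \ne v}
   \operatorname{arctanh}(r_{uv})$ over the analysed volume. Correlations
   are clamped to $\pm(1-10^{-7})$ before `arctanh` so degenerate perfect
   correlations stay finite; correlations with a zero-variance series are
   defined as 0 and logged.
2. **Key-voxel selection** (`select_features`). For each region: draw half
   the training subjects without replacement, rank voxels by $|r|$ with age,
   keep the top 50%; repeat 100 times and intersect; repeat that round 100
   times and keep voxels appearing in more than 10 rounds. This resampled
   intersection-stability filter discards voxels whose age correlation is
   not reproducible across subsamples.
3. **Per-region GP model** (`train_region_model`). A Gaussian-process
   regression of age on the selected voxels with five-fold cross-validation:
   out-of-fold predictions for every training subject, a linear bias fit
   $\widehat{\text{age}} = \alpha\,\text{age} + \beta$ on those pooled
   predictions, corrected predictions
   $\text{corrected} = \text{raw} + [\text{age} - (\alpha\,\text{age} +
   \beta)]$, and CV MAE / Pearson r on the corrected predictions. The final
   regressor is refit on all training subjects; $(\alpha,\beta)$ are stored
   and reused unchanged on every test cohort.
4. **Gaps and inference** (`compute_gap`, `group_compare_regions`). Gap =
   corrected brain age − chronological age. Per region, an ANCOVA
   (`gap ~ group + age + sex + MMSE + education`) tests the group effect via
   the extra sum of squares, with partial $\eta^2 =
   SS_\text{group}/(SS_\text{group}+SS_\text{error})$ as effect size;
   Benjamini–Hochberg FDR is applied across regions. For significant
   regions, a joint linear regression of the patient gaps on clinical
   characteristics (PANSS subscales, illness duration, age of onset,
   nicotine use, BMI; controls: age, sex) and a separate dose regression
   (chlorpromazine-equivalent dose, undosed patients excluded first) yield
   standardized betas, each FDR-corrected per predictor across regions.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_hc_train` | 230 | subjects | training cohort size of the emulated study |
| `age_range` | (20, 84) | years | study range; ages drawn uniformly |
| `n_regions` | 90/90/48 | regions | GM/FC atlas and white-matter tract counts |
| `voxels_per_region` | 200 | voxels | real counts vary and are irrelevant to the algorithms; 200 keeps desk scale |
| `signal_fraction` | 0.2 | – | fraction of informative voxels per region |
| `signal_slope`, `noise_sd` | per modality | units/yr, units | chosen so informative voxels have population age correlation $|r| \approx 0.6$ (moderate, realistic for single voxels) |
| `n_inner`, `n_outer` | 100, 100 | trials, rounds | the selection procedure's resampling depths |
| `count_threshold` | 10 | rounds | strict ">" cut on round counts |
| `k_folds` | 5 | folds | cross-validation folds |
| `alpha` | 0.05 | – | significance level on adjusted p values |

The closed form behind the signal calibration: an informative voxel
$x = b + s\,\text{age} + \varepsilon$, $\varepsilon \sim N(0,\sigma^2)$, has
population correlation $r = s\,\mathrm{sd}(\text{age}) / \sqrt{s^2
\mathrm{var}(\text{age}) + \sigma^2}$; with ages uniform on (20, 84),
$\mathrm{sd}(\text{age}) \approx 18.5$ y, the defaults give $|r| \approx
0.6$ for all three modalities (slopes are negative: GM intensity, average
connectivity and FA all decline with age).

## What the generator emulates — and what it does not

The generator reproduces the *statistical* structure the pipeline consumes:
age-linear informative voxels among noise voxels, disjoint atlas regions,
FA values bounded in [0, 1], band-limited BOLD series whose shared-signal
weight declines with age, patient groups with clinical covariates drawn
from the published cohort summaries, and region-specific injected
"accelerated aging" offsets (`offset = gap_years × signal_slope`,
optionally scaled by illness duration relative to its mean). It does *not*
emulate anatomy, spatial smoothness, scanner or site effects, motion, or
nonlinear aging trajectories, and covariates are drawn independently of age
within group. Passing tests therefore demonstrate that the algorithms
recover known structure under clean conditions — not that real data meet
the generator's assumptions. In particular, real voxels are spatially
correlated, so selection counts of neighbouring voxels are not independent
as they effectively are here.

Because pathology is injected only into informative voxels, an injected gap
of $g$ years maps one-to-one onto the predicted-age scale, and parameter
recovery can be checked exactly in expectation
(mean patient gap − mean control gap $= g$).

## Numerical choices

- **GP kernel.** Isotropic squared-exponential over per-voxel z-scored
  features plus white noise. The marginal likelihood is maximised over
  (log length-scale, log noise-to-signal ratio) with the signal variance
  profiled out in closed form ($\hat\sigma_f^2 = y^\top M^{-1} y / n$),
  analytic gradients, L-BFGS-B, and three deterministic starts (length-scale
  at 0.33×, 1×, 3× the median pairwise distance). Feature standardization
  uses training statistics stored in the model.
- **Bias-fitting sample.** $(\alpha, \beta)$ are fitted on the pooled
  out-of-fold training predictions and reused for all test cohorts; fitting
  them on a held-out control set instead is a defensible alternative, but
  the pooled-CV choice uses all training subjects and keeps test cohorts
  untouched.
- **Fold assignment.** Random permutation under a derived sub-seed, no
  stratification.
- **Selection ranking.** Absolute $|r|$ by default (GM/FC/FA age
  correlations are predominantly negative; signed ranking would discard
  them); `signed_ranking = TRUE` switches to signed. Ties at the top-50%
  boundary break deterministically to the lower voxel index. Half-samples
  are $\lfloor n/2 \rfloor$ without replacement, fresh per trial.
- **Empty selections.** If no voxel exceeds the round-count threshold the
  10 highest-count voxels are kept with a warning — downstream models need
  at least one feature.
- **FDR family.** Per modality (90/90/48 tests separately) by default;
  `fdr_family = "joint"` corrects across all 228 tests at once.
- **Seeding.** One master seed; every stage, region and round derives its
  own sub-stream (`substream_seed`) so any part can be re-run in isolation
  and whole runs are bit-reproducible.
- **Output format.** All tables are TSV with 6-decimal floats in fixed
  column order, so same-seed runs are byte-identical and diff-able.

## A caution on corrected-age performance metrics

The correction formula adds $\text{age} - (\alpha\,\text{age} + \beta)$ to
the raw prediction. When $(\alpha, \beta)$ come from the OLS fit of raw
predictions on age in the same sample, the corrected prediction equals
chronological age plus the OLS residual. Consequently the correlation
between corrected predictions and age is high *by construction* whenever
the residual is small relative to the age spread — including for an
uninformative model whose raw predictions are nearly constant. The
corrected-age MAE / r reported by `train_region_model` (`cv_mae`, `cv_r`)
follow the stated evaluation convention, but the package also reports
`raw_cv_mae` / `raw_cv_r` on uncorrected out-of-fold predictions; only the
latter measure how much age signal the features carry, and the null-model
tests assert on them. This inflation is a general property of this class of
bias correction, worth keeping in mind when comparing corrected-age r
values across studies.

## Problem sizes used by the test-suite and acceptance runs

The structural run uses the full 90/90/48 atlases at 200 voxels per region
with 230 training controls and 100 subjects per test group. Selection in
end-to-end runs uses 30 resampling rounds (30 trials each); the selection
recovery analysis uses 30 rounds of the default 100 trials; the group
recovery analysis uses the 90 GM regions at the default 200 voxels per
region; the
error-control analysis uses 200 global-null replicates of 20 regions with
30 subjects per group, exercising the inference stage on null gaps
directly. These sizes are the package's chosen desk-scale study conditions;
the generator's scientific defaults (cohort sizes, age range, signal
calibration) are never reduced.

## Known limitations

- The GP is exact (O(n³) per fit), fine for cohorts of a few hundred but
  not for biobank-scale training sets.
- The generator's voxels are independent given age; spatial correlation,
  site effects and nonlinear aging are out of scope.
- FC maps in the default end-to-end run are generated directly at region
  level in Fisher-z units (same data model as the BOLD-derived maps); the
  BOLD → average-connectivity → parcellation path is exercised at reduced
  volume sizes, since whole-volume voxel-pair correlation is quadratic in
  voxel count and contributes nothing further to the downstream method.
- Corrected-age r is inflated by construction (see above); cross-study
  comparisons should rely on raw-prediction metrics.
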