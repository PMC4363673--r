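---
title: "Normalization of spinal cord cross-sectional areas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization of spinal cord cross-sectional areas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordnorm)
```

## The problem

Total cross-sectional area (TCA) and gray matter (GM) area of the
spinal cord, measured on axial MRI at the C2-C3, C3-C4, T8-T9 and
T9-T10 disc levels, vary across healthy adults with a relative standard
deviation (%RSD = 100·SD/mean) of roughly 8–10%. Much of this spread
tracks overall anatomy — head size, vertebra size, age and sex — rather
than anything neurological, and it masks the atrophy signals one wants
to detect in disease. `cordnorm` implements a regression-based
*residual normalization*: model the areas on anatomical covariates in
healthy controls, then replace each measurement by its value adjusted
to the group-mean covariates.

## The residual method

For a subject $i$ with measured area $A^i_\text{meas}$ and covariates
$X^i, Y^i, \dots$, the normalized area is

$$A^i_\text{pred} = A^i_\text{meas} + a\,(\bar X - X^i) + b\,(\bar Y - Y^i) + \dots$$

with coefficients $a, b, \dots$ from an ordinary least-squares fit of
$A$ on the covariates, and $\bar X, \bar Y, \dots$ the covariate means
of the reference group, frozen into the model at fit time
(`fit_norm_model()` stores them; `apply_normalization()` accepts
external reference means for applying a packaged model to a new
cohort). Three exact consequences of OLS algebra are worth keeping in
mind, and are asserted in the test suite at tolerance 1e-10:

* a subject at the covariate centroid is returned unchanged;
* in-sample, normalization preserves the mean:
  $\overline{A_\text{pred}} = \overline{A_\text{meas}}$;
* in-sample, $\%\text{RSD}_\text{norm} = \%\text{RSD}_\text{meas}\sqrt{1 - R^2}$
  with the *unadjusted* $R^2$ of the fit — normalized values are just
  residuals re-centred at the outcome mean.

That last identity means the %RSD reduction, defined as
$100\,(1 - \%\text{RSD}_\text{norm}/\%\text{RSD}_\text{meas})$, is a
monotone function of the fitted $R^2$; reported reductions are
in-sample quantities and carry the usual small-sample optimism of an
OLS fit (at $n = 30$ and $p = 3$ an honest population $R^2$ of 0.41
yields fitted $R^2 \approx 0.47$ and an expected reduction near 27%).

Model building follows two fixed rules. Candidate covariates are
screened by Pearson correlation against TCA or GM at the reference
level, retaining those with $r > 0.45$ (strict inequality), restricted
to skull- and vertebra-derived metrics — brain tissue volumes correlate
at least as strongly but are themselves altered by the diseases one
wants to study, so they are excluded from normalization by design.
Fitted models are retained when adjusted $R^2 > 0.35$. When a model is
transferred to another disc level it is *refitted* there (coefficients
are level-specific); `transfer_model(drop_nonsignificant = TRUE)` drops
covariates whose refitted coefficient is not significant at two-sided
0.05 — the threshold is a package choice, made explicit because "not
significant" is otherwise undefined — which is how an age + head-size
TCA model collapses to a head-size-only GM model.

## Group comparisons

`ls_means()` computes covariate-adjusted (least-square) means: the
model prediction for each factor level with every covariate at its
grand complete-case mean. The equal-slopes model (no
factor-by-covariate interaction) is used throughout, matching the
single adjusted mean per group that the comparison is meant to
summarize. Group differences are tested two-sided on the residual
degrees of freedom with matching 95% t intervals. `median_split()`
assigns subjects exactly at the median to the upper ("≥ cutoff") group.
`covariate_screen()` runs the age/sex/height/weight multiple
regression per outcome and flags covariates at the exploratory p < 0.1
threshold; no multiplicity correction is applied by default (a
Bonferroni option exists) because these screens are exploratory, and
the choice is surfaced as an argument rather than resolved silently.
Sex enters all models coded F = 0, M = 1; that coding lives in one
place (`resolve_var()`).

## The synthetic cohort generator

No subject-level data ship with the package; the generator exists so
the full pipeline can be exercised, tested and calibrated against the
summary statistics of a 32-subject healthy-control study (14 men,
18 women, ages 28–78). Generation order per subject:

1. sex from a Bernoulli draw (18/32 female);
2. (age, TICV, ap_vertebra_diameter, sagittal_vertebra_area) from a
   sex-conditional multivariate normal, the whole vector redrawn until
   age lies in [28, 78];
3. auxiliary brain volumes and skull metrics as noisy regressions on
   TICV (they make the covariate tables realistic but carry no pathway
   to the areas); height and weight likewise, with no area pathway —
   so the expected behaviour of the demographic screen on these
   cohorts is a null at the nominal rate;
4. vertebra heights consistent with the drawn sagittal area: the
   anterior/posterior heights average exactly to
   sagittal_vertebra_area / ap_vertebra_diameter, and the middle height
   gets its own small perturbation so the trapezoidal area proxy stays
   distinct from the rectangular one;
5. the eight (level, measure) areas as linear predictors in the core
   covariates plus a sex offset plus a correlated Gaussian residual
   vector (one 8-dimensional draw per subject, Cholesky-factorized),
   redrawn in the rare case `0 < gm < tca` fails; more than 10%
   redraws across the cohort is treated as a configuration error;
6. the missingness pattern: two subjects lack the thoracic levels and
   the *same* two lack the covariate record. Making them the same
   subjects is deliberate — it keeps every complete-case model fit,
   cervical or thoracic, at n = 30, which is the only pattern
   consistent with all of the emulated study's stated sample sizes.

Each subject consumes an RNG stream derived from (seed, subject index),
so enlarging a cohort never perturbs earlier subjects, and identical
(config, n, seed) yield identical cohorts.

### Calibration: what is targeted and what emerges

`default_config()` is a computation, not a table of hand-tuned
constants. Its fixed inputs are the study's printed summary statistics:
per-level area means and SDs; age-adjusted sex differences (4.60 and
3.05 mm² for TCA at the cervical and thoracic reference levels, 1.51
and 1.26 mm² for GM; the unreported intermediate levels borrow their
neighbour's value); sex-adjusted marginal age slopes (−0.20 and −0.13
mm²/year for TCA); cohort covariate means (TICV 1 434 165 mm³,
ap_vertebra_diameter 15.63 mm, sagittal_vertebra_area 199.93 mm²); the
full 8×8 cross-level area correlation matrix; and per-model population
R² targets. All required population quantities — mixture means,
covariances, OLS projections, model R² — are closed-form functions of
the configured moments, so the calibration solves exact equations
rather than simulating.

Per outcome the solver works as follows. The head-size coefficients
keep the *ratios* of the reported regression coefficients but are
scaled by a single solved factor until the population R² of the
reported model equals its target (an adjusted R² is an approximately
unbiased estimate of population R², so reported adjusted R² values
serve as the targets). The age coefficient and sex offset are then
solved linearly for the marginal-slope and sex-difference targets, the
intercept matches the mean, and the residual SD absorbs the remaining
variance so the total SD is exact. This "scale the pathway, pin the
SD" scheme is a deliberate choice: the reported coefficient values,
total SDs and adjusted R² values are mutually inconsistent if all are
taken as generative truth simultaneously, and the quantities that the
downstream analyses actually measure are the SDs, effects and R², not
the raw coefficients. The alternative scheme — keep coefficients
verbatim and solve the residual SD for a target R², sacrificing the
total SD — is implemented and tested as `calibrate_residuals()`.

Two free structural blocks remain, both documented in the packaged
config rather than derived:

* the within-sex covariate correlation matrix. The negative age rows
  (−0.40 against each head/vertebra metric) are what reconcile the
  conditional age coefficient of the multi-covariate models (about
  −0.105 mm²/year) with the much steeper marginal slope (about −0.20):
  in this cohort older subjects had somewhat smaller head metrics, and
  the calibration must encode that or the two printed age effects
  contradict each other. The positive block (TICV-vertebra 0.30–0.40,
  vertebra-vertebra 0.40) encodes a common body-size factor and was
  chosen so the *emergent* covariate-area correlations land on the
  reported values (TCA-TICV ≈ 0.63, TCA-sagittal_vertebra_area ≈ 0.52,
  TCA-ap_vertebra_diameter ≈ 0.38 at C2-C3);
* per-sex covariate mean gaps (TICV 150 000 mm³, ap_vertebra_diameter
  0.8 mm, sagittal_vertebra_area 15 mm², typical sexual dimorphism),
  constrained to recombine to the printed cohort means.

The generative pathway per outcome uses the covariate set of the
best-reported model for that outcome: age + TICV +
sagittal_vertebra_area for cervical TCA, age + TICV +
ap_vertebra_diameter for thoracic TCA (where that model was reported
as the stronger one), and TICV + ap_vertebra_diameter for GM (age
contributes no direct GM pathway; the small observed marginal GM-age
slope, ~0.3 mm²/decade, emerges entirely through the age-covariate
correlations). R² values of *other* covariate sets on the same outcome
are then emergent, not targeted — e.g. the age + TICV +
ap_vertebra_diameter model on cervical TCA comes out near 0.44, close
to its reported 0.41.

One calibration target deserves a note. The reported GM model
statistics imply an in-sample %RSD reduction near 30%, while the
reported summary reduction for GM is 25%; the two cannot both hold
given the √(1−R²) identity. The calibration follows the summary
reduction: the GM pathway targets population R² = 0.40, which yields
an expected in-sample reduction of ≈25% at n = 30 and an adjusted R²
in the lower half of the reported model range. Similarly, the reported
statistics for the transferred TCA model at C3-C4 are internally
inconsistent (adjusted R² 0.36 vs %RSD columns implying 0.48); there
the C3-C4 Model-2 R² is left emergent (≈0.38) and the three-level
average reduction lands near the reported 32%.

Cross-level dependence is calibrated last: the residual correlation for
each outcome pair is solved from the target area correlation after
subtracting the structural (shared-covariate and shared-sex-offset)
covariance, clamped to [−0.95, 0.95], and the resulting matrix is
projected to the nearest positive semi-definite correlation matrix
(`Matrix::nearPD`). The projection moves entries by less than 0.01
here; configurations supplied by users are validated strictly
(eigenvalues below −1e−8 are an error, tiny numerical negatives are
repaired).

### Age truncation

Ages are truncated to [28, 78] by resampling (not clipping, which
would pile mass at the bounds). A hard window this narrow caps the
achievable SD: no truncated normal inside [28, 78] reaches the nominal
per-sex SDs of 13.4/15.1 years (the uniform limit is 14.4). The
generator therefore fixes the latent SD at 1.3× nominal, solves the
latent mean so the truncated *mean* is exact, and — crucially — uses
the achieved truncated SD (≈12 years) as the within-sex age SD
throughout the calibration engine, so every slope, R² and correlation
is exact with respect to the distribution actually generated. The
covariate block is adjusted for the truncation in closed form
(slab-truncation of a joint normal), so TICV and vertebra moments are
unaffected. The one visible consequence: the realized cohort age SD
(~12.5 pooled) understates the nominal 14.3.

## What the simulation does and does not emulate

Passing tests on these cohorts demonstrate that the pipeline recovers
the statistical structure it assumes: joint (mixture-of-)normal
covariates, areas exactly linear in covariates, homoscedastic Gaussian
residuals, missingness as a fixed count unrelated to the values. Real
cohorts deviate from all of these: segmentation error is not modelled
separately from biological residual variance, covariate-area relations
may be nonlinear at the extremes, and missingness in practice follows
scanner logistics. Results on synthetic cohorts therefore validate the
*implementation* and the internal consistency of the reported summary
statistics — not the biological model itself.

## Numerical choices

* SDs use the n−1 denominator everywhere, including inside %RSD and
  the pooled-moment decomposition (`pooled_moments()` is exact total
  sum-of-squares pooling, equivalent to concatenating the raw data).
* Correlation tables use pairwise deletion with per-cell n reported;
  p-values are two-sided throughout.
* Disc level labels are canonical (`"C2-C3"`, ..., `"T9-T10"`);
  anything else is an error with the offending row number, never a
  guess. Missing data are absent rows or empty cells, never zeros.
* Cohort CSVs serialize numbers with 17 significant digits, so a
  write/read round trip is exact.
* Normality assessment delegates to `stats::shapiro.test()`; the
  contract (3 ≤ n ≤ 5000, constant input is an error) is enforced at
  the package boundary.
* `fit_norm_model()` requires at least p + 3 complete cases and
  signals rank deficiency rather than silently dropping aliased terms.
* Replicate experiments in the tests and the acceptance script use 500
  cohorts of n = 32 (the study design) and one n = 20 000 cohort for
  large-sample calibration checks; both finish in seconds.

## Limitations

* The calibration reproduces first and second moments and linear-model
  behaviour; higher-order features (skewness of areas, outliers) are
  not calibrated.
* Ratio ("proportion") normalization, lumbar-enlargement or thecal-sac
  covariates, and disease-effect injection are out of scope.
* The packaged reference models apply a healthy-control calibration;
  applying them to patient cohorts assumes skull/vertebra metrics are
  disease-stable, an assumption the user must judge per disease.
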