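---
title: "In vivo tau-PET staging of PSP: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In vivo tau-PET staging of PSP: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pspstage)
```

## The problem

Progressive supranuclear palsy (PSP) is a 4-repeat tauopathy whose
postmortem pathology follows a stereotyped cumulative sequence: globus
pallidus first, then frontal cortex and cerebellum, and finally the
occipital lobe. A six-stage postmortem scheme grades this progression by
which regions are involved and how severely. `pspstage` implements the
analytic pipeline needed to attempt the same staging *in vivo* from
regional ^18^F-flortaucipir PET binding, together with the statistics used
to judge whether the resulting stages mean anything — agreement with
postmortem stage in donors, and association with clinical severity
(PSPRS). Because patient-level PET data of this kind are not publicly
distributable, the package ships a seeded synthetic-cohort generator with
the same statistical structure, so every stage of the pipeline is
exercisable and testable end to end.

## Regional quantification

Binding is quantified as the nondisplaceable binding potential (BP~ND~)
from dynamic time–activity curves (TACs) using a basis-function
implementation of the simplified reference tissue model (SRTM), with
cerebellar cortex gray matter as the reference region:

$$C_T(t) = R_1\,C_{ref}(t) + \left(k_2 - R_1 k_{2a}\right)\,
  C_{ref}(t) \otimes e^{-k_{2a} t},
  \qquad k_{2a} = \frac{k_2}{1 + BP_{ND}}.$$

`fit_srtm_basis()` grids $k_{2a}$ and solves a two-parameter linear
least-squares subproblem per grid point; the grid point minimizing the
residual sum of squares wins, and $BP_{ND} = k_2 / k_{2a} - 1$.

Numerical choices, made once and fixed:

* **Basis grid**: logarithmic, $k_{2a} \in [0.006, 0.6]$ min⁻¹, 100
  points (`basis_config()`). This spans physiological washout for
  flortaucipir-class tracers; the induced BP~ND~ resolution near
  $BP_{ND} = 0.5$ is about 0.07, and a noise-free on-grid simulation is
  recovered to machine precision (see the test suite).
* **Convolution**: recursive trapezoidal scheme on a 0.05-min internal
  grid, frame-averaged, with the reference signal interpolated linearly
  through frame midpoints and anchored at zero at $t=0$. The convolution
  error is far below the fit tolerance (checked against an independent
  FFT-based convolution at 0.01-min resolution).
* **Weights**: unweighted by default; frame-duration weights can be
  passed. No weighting scheme is assumed by the rest of the pipeline.
* **Negative binding**: $\theta_2 < 0$ (BP~ND~ slightly below zero) is
  permitted, as happens with real tracers in low-binding regions; an
  implied $BP_{ND} \le -1$ is treated as a failed fit. Ties in RSS
  resolve deterministically to the smallest $k_{2a}$.

Before kinetic modeling, regional PET data are corrected for CSF partial
volume by dividing by the regional gray-plus-white-matter fraction
(`pvc_correct()`); the fraction is treated as frame-constant, since
tissue segmentation yields a single per-region value. Left and right
values are averaged bilaterally (`bilateral_average()`); when one
hemisphere is missing the other is used, with a warning, rather than
discarding the subject.

The staging analysis proper consumes per-region BP~ND~ tables, so
precomputed tables can enter the pipeline directly and skip the kinetics
step.

## w-scores

`fit_wscore_model()` fits, per region, an ordinary least-squares model of
control BP~ND~ on age and a PET/MRI-vs-rest scanner indicator;
`compute_wscore()` then maps any subject's value to
$w = (\text{observed} - \text{predicted}) / \hat\sigma$. The covariate
set is fixed to age plus the binary scanner indicator — the two
systematic effects the acquisition design introduces — and the scanner is
deliberately a single PET/MRI-vs-rest contrast, not a three-level factor,
because the PET/MRI system's sensitivity advantage (and halved injected
activity) is the harmonization-relevant difference. The residual SD uses
the $n - p$ denominator; this is switchable (`df_method = "n-1"`) because
either convention is defensible, and the choice only rescales w-scores by
$\sqrt{(n-1)/(n-p)}$. A control cohort smaller than 10, a rank-deficient
design, or zero residual variance are hard errors: a normative model that
cannot standardize is worse than none.

One consequence worth knowing: the w-scores of the fitting controls
themselves have mean exactly 0 and SD exactly
$\sqrt{(n-p)/(n-1)}$ (≈ 0.973 at $n = 39$, $p = 3$) — a property of OLS
residuals, not a statement about new data.

## Abnormality thresholds

`find_threshold()` reproduces the behavior of a conditional-inference
tree's first split with a binary diagnosis response and the regional
w-score as sole predictor: candidate cut points are midpoints between
consecutive sorted unique w-scores; the split maximizing the chi-square
of the 2×2 group-by-side table is selected; significance is judged by
permuting group labels and comparing the *maximal* statistic over all
candidate splits (max-T), which is what gives the procedure its
family-wise stopping behavior. Defaults: `alpha = 0.05`,
`n_perm = 9999`, seed mandatory. Only the first split is ever used —
the scheme needs one cut point per region — and ties resolve to the
smallest midpoint.

Where no significant split exists, `resolve_threshold()` falls back to
the fixed w-score critical value 1.645, the one-sided standard-normal
quantile at $P = 0.05$ — in practice this is what happens for occipital
subregions, which separate patients from controls only weakly. The
alternative SD-based scheme (`sd_threshold()`) marks abnormality at a
preselected number of control SDs; on the w-score scale that threshold
*is* the multiplier itself. Its default `k_sd = 2` is a conventional
choice, configurable, and not anchored to any published value. With
`k_sd = 1.645` the SD scheme and the fallback coincide exactly.

The tree direction (diagnosis as response, w-score as predictor) is the
presumed reading of the original analysis; the converse regression would
not yield a cut point at all, which is why we consider the presumption
safe.

## The two-step staging automaton

`severity_score()` codes each subregion 0/1/2 against its threshold
$\tau$: absent ($w \le \tau$), mild/moderate ($\tau < w \le 2\tau$),
moderate/severe ($w > 2\tau$) — both boundaries land on the lower
category. Composites (cerebellum = white matter + dentate; occipital =
lingual + cuneus) take the maximum over their subregions: involvement of
either subregion constitutes involvement of the composite, matching how
the postmortem scheme reads regional pathology. Thresholding per
subregion with max-aggregation (rather than thresholding a combined
occipital w-score) is the implemented default; the alternative only
matters if the two occipital subregions disagree strongly.

Step 1 maps the presence pattern over (GP, CER, FR, OCC) to a coarse
stage by the cumulative rules: nothing involved → no stage; anything
involved without GP → unclassifiable (the pattern violates the cumulative
sequence); GP only → I/II; GP plus FR or CER, occipital spared → III/IV;
occipital involvement on top → V/VI. Step 2 refines each pair using the
3-level severity of its defining region (GP for I/II, max(FR, CER) for
III/IV, OCC for V/VI; severity 1 → the lower substage, 2 → the higher).

Two edge policies are deliberate:

* **Atypical patterns** — occipital involvement with frontal and
  cerebellar sparing — are staged V/VI by the cumulative rule (highest
  supported level) and flagged `atypical = TRUE` rather than rejected;
  real cohorts contain such discordant patterns and discarding them
  would silently shrink the staged sample.
* **Missing regions** make a subject `unclassifiable_missing` *only if*
  the missing value could change the outcome (the assignment is computed
  under both severity-0 and severity-2 imputations and kept only when
  they agree). This is distinct from `unclassifiable`, which is an
  observed violation of the sequence, not a data problem.

Numeric coding for correlation analyses: no stage = 0, I–VI = 1–6,
step-1 pairs at their midpoints (1.5/3.5/5.5) when substaging is off,
unclassifiable excluded. By construction the numeric stage is monotone in
every region's severity and step 2 always refines step 1; both properties
are verified exhaustively over all $3^4 = 81$ severity vectors in the
test suite.

## Validation statistics

`anova_by_stage()` is a fixed-effects one-way ANOVA of PSPRS across stage
groups. `spearman_agreement()` is Spearman's rank correlation with
midranks; for nine donors, n is small enough that the exact p-value is
used when there are no ties (asymptotic otherwise — at n ≤ 9 with ties
neither is exact, and the estimate itself is unaffected).
`residualized_correlation()` regresses each numerically coded staging
variable on PSPRS and the PET-to-death interval by OLS and correlates the
residuals — linear regression on ordinal codes is statistically coarse,
but it mirrors the original procedure exactly, and fidelity wins here.
`proportion_le()` reports the fraction of donors whose in vivo stage is
at or below their postmortem stage, the pattern expected when pathology
progresses between scan and death.

## The synthetic cohort generator

`cohort_config()` / `generate_cohort()` emulate the cohort structure the
analysis assumes: 39 controls (age 65.8 ± 8.2 y), 42 patients (age
70.3 ± 7.0 y; PSPRS 36.6 ± 14.2), scanner mix ≈ 24/7/8 (controls) and
22/13/7 (patients) across PET/MRI, PET/CT and PET, a 9/42 donation
fraction, and PET-to-death intervals of 2.45 ± 0.98 y (truncated at 0.1 y
— truncation rather than resampling keeps the draw count, and hence
reproducibility per seed, fixed). Regional pathology is cumulative by
construction: the stage-effect matrix's rows are required to be
non-decreasing across stages, so a patient at stage $s+1$ is at least as
elevated as at stage $s$ in every region.

Values the source analysis does not determine were chosen once as
field-realistic and are documented here, not tuned:

* Control regional BP~ND~ baselines 0.15–0.55 with SD 0.10 — pallidal
  binding sits high because of known off-target signal, cortical regions
  low.
* Stage elevations: mild = 0.25, severe = 0.50 BP~ND~ units (2.5 and 5
  control SDs). Patient regional distributions are free parameters of the
  generator, not estimates of any cohort's data.
* Age slope 0.004 BP~ND~/y and PET/MRI offset 0.05 — small systematic
  effects of the size the w-score model exists to remove.
* Postmortem stage = stage at scan + Poisson increment with mean 0.4 ×
  interval (years), capped at VI, encoding "in vivo ≤ postmortem" as the
  typical but not universal case.
* PSPRS is independent of stage by default
  (`psprs_stage_coupling = 0`), reproducing the null stage–severity
  association as a *scenario*; setting the coupling positive produces the
  alternative world for power checks.
* Regional noise is Gaussian and independent across regions, with an
  optional shared subject-level random effect
  (`subject_effect_sd`) for robustness experiments, and small left/right
  asymmetry noise (SD 0.02).

What the generator does **not** emulate: spatial correlation beyond a
single subject effect, heavy-tailed or skewed binding distributions,
off-target binding structure, phenotype-dependent topography, scanner
differences beyond one additive offset, and progression of the *pattern*
(only the stage index progresses). Passing tests therefore demonstrate
that the pipeline's logic and statistics behave as specified under the
assumed data model — not that flortaucipir PET can stage PSP in the
clinic; on real data the original analysis found it could not.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on synthetic data
at deliberately modest sizes: cohorts of 39 + 42 (the emulated design)
up to 100 + 60 for recovery checks, 999 permutations per threshold
search, 100 null replicates for the threshold type-I check, and 1000
replicates of a 60-patient ANOVA for the severity-null calibration.
These sizes give Monte-Carlo error comfortably inside the asserted
bands while keeping a full run in the tens of seconds.

## Known limitations

* The permutation search needs both groups and at least two distinct
  w-score values; regions with essentially constant w-scores error out
  rather than guessing.
* The SD-based threshold multiplier (`k_sd`) has no anchored published
  value; treat comparisons across `k_sd` choices as sensitivity
  analyses.
* Substage VI is reachable by the automaton but rare under realistic
  effect sizes (it requires moderate/severe occipital binding), matching
  the empirical scarcity of stage-VI assignments in vivo.
* The residualized correlation applies OLS to ordinal codes by design
  (fidelity to the original procedure); a proportional-odds or rank-based
  residualization would be the statistically cleaner alternative.
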