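# pspstage

In vivo staging of progressive supranuclear palsy (PSP) tau pathology
from regional ^18^F-flortaucipir PET, for neuroimaging researchers
running PET-to-autopsy validation analyses.

PSP tau pathology accumulates in a stereotyped cumulative sequence —
globus pallidus (GP), then frontal cortex (FR) and cerebellum (CER),
then occipital lobe (OCC) — and a six-stage postmortem scheme grades
that progression. `pspstage` implements the full analytic chain needed
to attempt the same staging during life, plus the statistics used to
validate (or, on real data, falsify) the attempt:

1. **Kinetics** — BP_ND per region from dynamic time–activity curves by
   a basis-function SRTM,
   `C_T(t) = R1·C_ref(t) + (k2 − R1·k2a)·(C_ref ⊗ e^(−k2a·t))` with
   `k2a = k2/(1 + BP_ND)`, after CSF partial-volume correction
   (value / GM+WM fraction) and bilateral averaging.
2. **w-scores** — per-region z-scores adjusted for age and scanner type
   (PET/MRI vs non-PET/MRI) against an OLS normative model fitted on
   controls: `w = (observed − predicted) / residual SD`.
3. **Thresholds** — per-region abnormality cut points from the first
   split of a binary recursive partition (max chi-square over candidate
   midpoints, max-T permutation stopping rule), with a fixed fallback of
   w > 1.645 (one-sided normal, P = 0.05) where no significant split
   exists, or alternatively a preselected SD multiplier.
4. **Staging** — a two-step automaton: step 1 maps the binary regional
   presence pattern to stage I/II, III/IV or V/VI by the cumulative
   rules (no GP signal with signal elsewhere = unclassifiable); step 2
   refines each pair with a 3-level severity code (0: w ≤ τ; 1:
   τ < w ≤ 2τ; 2: w > 2τ) of the stage-defining region.
5. **Validation** — ANOVA of PSPRS clinical severity across stages,
   Spearman agreement between in vivo and postmortem stage, the same
   correlation after residualizing both stage variables on PSPRS and the
   PET-to-death interval, and the fraction of donors with in vivo ≤
   postmortem stage.

A seeded synthetic-cohort generator (`cohort_config()` /
`generate_cohort()`) emulates the study design this pipeline targets —
39 controls, 42 patients, stage-dependent cumulative regional binding,
age and scanner effects, a 9-donor postmortem subset — so everything is
testable without patient data. `simulate_tac()` provides the matching
SRTM forward model for the kinetics layer.

## Worked example

```r
library(pspstage)

cohort <- generate_cohort(cohort_config(seed = 42))
res <- run_pipeline(cohort, threshold_method = "data_driven",
                    n_perm = 999, seed = 7)
print(res)
```

```
<psp_pipeline>
  thresholds:
    globus_pallidus  tau = 1.752 (data_driven)
    cerebellar_wm    tau = 1.792 (data_driven)
    dentate          tau = 2.041 (data_driven)
    middle_frontal   tau = 2.108 (data_driven)
    lingual          tau = 1.645 (fallback)
    cuneus           tau = 1.645 (fallback)
  patient step-2 stages:  I=3, II=3, III=5, IV=25, V=3, VI=3
<agreement_report>
  in vivo vs postmortem pairs: 9
  Spearman r = 0.653 (p = 0.0564)
  residualized r = 0.150 (p = 0.7)
  in vivo <= postmortem: 1.00
  PSPRS ANOVA: F = 0.731 (p = 0.605)
```

Reading it: the permutation-tested split search found data-driven
w-score thresholds for the pallidal, cerebellar and frontal regions but
not for the occipital subregions, which fell back to the fixed 1.645
critical value — the same structural pattern the method produces on real
cohorts, where occipital binding separates patients from controls only
weakly. Patients concentrate in stages III/IV (pallidal plus
frontal/cerebellar involvement). Every donor's in vivo stage was at or
below the postmortem stage, as expected when pathology progresses
between scan and death, and the PSPRS ANOVA is null because this
synthetic cohort generates clinical severity independent of stage.

The kinetics layer works the same way from TACs:

```r
ref <- default_reference_curve(90, 20)            # reference-region TAC
tgt <- simulate_tac(srtm_params(R1 = 1, k2 = 0.1, bp_nd = 0.5), ref, 0)
fit_srtm_basis(tgt, ref)
#> <srtm_fit> R1 = 0.9979, k2 = 0.1010 /min, k2a = 0.0674 /min,
#>   BP_ND = 0.4988 (rss 5.34e-06)
```

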