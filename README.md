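# ithstrat

Molecular risk stratification of metastatic clear cell renal cell
carcinoma (mccRCC) under intratumoural heterogeneity (ITH).

Prognostic biomarkers for advanced kidney cancer have historically failed
to replicate, and one suspected culprit is ITH: different regions of the
same tumour give different molecular readouts, so a score computed from
one biopsy need not agree with a score computed from another.
`ithstrat` implements an analysis pipeline for multiregion reverse phase
protein array (RPPA) studies that asks exactly this question, end to end:

1. **Variance screen** (`screen_ith`): find proteins whose within-tumour
   expression variance is inflated in treatment-exposed tumours, using
   pooled one-way-ANOVA mean squares, an F test gated on Lilliefors
   normality and Fligner–Killeen homogeneity, and variance log-ratio
   ranking for proteins failing the gate.
2. **Model selection** (`backward_eliminate`): Cox proportional-hazards
   wrapper selection on overall survival with backward elimination
   regularised by BIC (−2 logPL + p·log m), with a full audit trace.
3. **The NEAT score** (`neat_model`, `neat_loghr`): the four-variable
   prognostic model on N-cadherin (CDH2), EPCAM, Age and mTOR,

   HR = exp(8.927·NCad + 3.800·EPCAM + 0.129·Age − 18.385·mTOR),

   centred at the development-cohort covariate means so that logHR = 0 is
   average risk and the predetermined threshold splits patients into
   high/low risk groups.
4. **Evaluation** (`stratification_metrics`, `concordance_index`,
   `net_reclassification_improvement`, `os_mixture_modes`): Kaplan–Meier
   and log-rank, group hazard ratios, Harrell's C with bootstrap CIs,
   2-year confusion-matrix metrics including Matthews correlation, NRI
   against IMDC/MSKCC clinico-pathological groupings, and
   BIC-selected Gaussian-mixture clustering of overall survival.
5. **Tumour subsampling** (`subsampling_experiment`): the core ITH
   experiment. For a maximum number of tumour samples per patient
   (MNTS = 1, 2, 3), unique sample combinations across all patients are
   drawn by Sobol quasi-random sampling of the combination space (one
   dimension per patient), each combination is re-scored, and the
   distributions of cohort logHR and log-rank p quantify how
   stratification performance depends on sampling depth. Per-patient
   exhaustive logHR ranges (`per_patient_loghr_range`,
   `risk_flip_fraction`) show which patients' risk group is an accident
   of the biopsy taken, and `grade_variance_analysis` links that
   instability to Fuhrman grade.
6. **Synthetic cohorts** (`simulation_config`, `generate_cohort`): a
   seeded generator of two-arm multiregion studies (latent tumour means,
   grade- and treatment-dependent within-tumour noise with occasional
   divergent regions, bimodal overall survival linked to the NEAT linear
   predictor) so the whole pipeline is testable without patient data.

The package is aimed at biostatisticians studying biomarker
reproducibility and at method developers who need a fully synthetic but
structurally realistic multiregion survival benchmark.

## Worked example

```r
library(ithstrat)

cfg <- simulation_config(inflated_proteins = c("CA9", "CDH2", "EPCAM", "MTOR"),
                         variance_inflation = 2, region_outlier_factor = 1)
co  <- generate_cohort(cfg, seed = 1)
co
#> <ith_cohort> 44 patients, 168 samples, 55 proteins
#>   cohorts: development=22, validation=22

head(screen_ith(co)[order(-screen_ith(co)$log_ratio),
     c("protein", "log_ratio", "p", "assumptions_ok", "selected")], 5)
#>  protein log_ratio        p assumptions_ok selected
#>    EPCAM     1.634 1.08e-09           TRUE     TRUE
#>     MTOR     1.547 6.70e-09           TRUE     TRUE
#>     CDH2     1.280 1.15e-06           TRUE     TRUE
#>      CA9     1.162 9.12e-06           TRUE     TRUE
#>   NUIS31     0.883 6.57e-04           TRUE     TRUE

dev   <- cohort_arm(co, "development")
val   <- cohort_arm(co, "validation")
model <- neat_from_cohort(dev)          # fixed coefficients, dev-cohort centering
sc    <- neat_score_cohort(val, model)
stratification_metrics(sc$risk_group, sc$os_months, sc$event)
#> high/low = 18/4; log-rank p = 0.0307; HR = 7.7; C = 0.60; MCC = 0.24

for (m in 1:3) print(subsampling_experiment(val, model, m, 5000, seed = 2))
#> <subsampling_result> MNTS=1: 5000 datasets (space 1.14e+12), median logHR 0.751, median log-rank p 0.212, 0 degenerate
#> <subsampling_result> MNTS=2: 5000 datasets (space 7.2e+13), median logHR 1.450, median log-rank p 0.0499, 0 degenerate
#> <subsampling_result> MNTS=3: 5000 datasets (space 1.03e+11), median logHR 1.708, median log-rank p 0.0499, 0 degenerate

risk_flip_fraction(val, model)$fraction
#> sample choice flips the risk group for 17/22 patients (77%)
```

Reading the output: the screen ranks the four variance-inflated proteins
first and selects them; NEAT risk groups separate validation survival
(log-rank p ≈ 0.03 at n = 22); and the subsampling distributions show
median stratification power rising steadily with the number of samples
analysed per tumour, while for most patients the per-sample logHR range
crosses the decision threshold — a single biopsy would often have
assigned the opposite risk group.

A full pipeline run (simulate → screen → select → score → evaluate →
subsample) is available as `run_pipeline(config, out)` with a YAML/list
config, stage toggles and one root seed; it writes CSV/JSON outputs plus
a `report.json` per stage.

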