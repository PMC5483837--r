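---
title: "Methods: risk stratification under intratumoural heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk stratification under intratumoural heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ithstrat)
```

This vignette documents the statistical models behind `ithstrat`, the
assumptions they rest on, the parameters a user may want to move, and
the choices we made where the design was genuinely open. Nothing here
states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The prognostic model

The NEAT score is a fixed-coefficient Cox proportional-hazards linear
predictor on four variables: N-cadherin (CDH2), EPCAM, age at diagnosis
in years, and mTOR (MTOR), with protein values on the log2 scale of
normalised RPPA intensities:

$$\log \mathrm{HR}_i \;=\; 8.927\,(x_{i,\mathrm{CDH2}}-\bar x_{\mathrm{CDH2}})
 + 3.800\,(x_{i,\mathrm{EPCAM}}-\bar x_{\mathrm{EPCAM}})
 + 0.129\,(a_i-\bar a)
 - 18.385\,(x_{i,\mathrm{MTOR}}-\bar x_{\mathrm{MTOR}}).$$

A patient with $\log \mathrm{HR} > 0$ is high risk, otherwise low risk
(a patient exactly at 0 is low; the boundary convention is logged in the
documentation of `assign_risk_groups`).

**Centering.** Stated as a raw formula, the predictor with these
coefficients and age in years is never near zero, yet the decision
threshold is "average risk". The only reading under which the threshold
is meaningful — and the standard convention for Cox partial-likelihood
predictors — is to centre each covariate at its fitting-cohort mean. We
therefore centre at the development-cohort means
(`neat_from_cohort`); the means are data-derived artifacts stored with
the model object, not constants of the formula.

Protein inputs are the **median** over a patient's selected tumour
samples, per protein. The median is the pipeline's only aggregation;
the mean exists behind an explicit flag in
`aggregate_patient_expression` for sensitivity analysis.

## Cox estimation and model selection

`fit_cox` delegates the partial-likelihood maximisation to
`survival::coxph` with Efron tie handling (Breslow by flag); the test
suite verifies the single-covariate case against a hand-written Efron
partial likelihood maximised by golden-section search. Monotone partial
likelihoods (perfect risk separation) are flagged on the returned
object, never silently passed downstream.

`bic` uses $-2\log\mathrm{PL} + p\,\ln m$ with the effective sample size
$m$ defaulting to the **number of events** — the usual choice for
censored data, where events carry the information — with the number of
patients available as an option.

`backward_eliminate` starts from the full candidate model and, at each
step, refits every single-feature-removal submodel (including the null
model from a one-feature model). The feature whose removal gives the
lowest BIC is dropped iff that BIC strictly improves the current one;
ties break in favour of the earliest feature in input order and are
logged. The full candidate-by-candidate BIC table at every step is
returned as a trace, so any selection path is auditable. Failed
submodel fits are skipped with a warning rather than aborting the
search.

The proportional-hazards assumption is checked with the
Grambsch–Therneau scaled-Schoenfeld score test (`survival::cox.zph`),
identity time transform by default.

## The variance screen

For each protein and cohort, within-tumour variance is the pooled
within-group mean square of a one-way ANOVA with tumours as groups
($\mathrm{MSE} = \sum_i\sum_j (x_{ij}-\bar x_i)^2 / \sum_i (n_i - 1)$,
patients with fewer than two samples excluded). Cohorts are compared by
$F = \mathrm{MSE}_\mathrm{exposed}/\mathrm{MSE}_\mathrm{naive}$ on the
pooled degrees of freedom, with a two-tailed p as twice the smaller
tail.

The F test is only trusted when its assumptions hold: Lilliefors
normality of per-tumour-centred residuals in both cohorts, and
Fligner–Killeen homogeneity of variance across tumours within each
cohort, each at $\alpha = 0.05$. Proteins failing the gate keep their
log-ratio but report no p-value. Candidates are the gated proteins with
raw $p < 0.05$ and positive log-ratio, plus gate-failing proteins whose
log-ratio exceeds the smallest log-ratio in that significant set. No
multiplicity correction is applied inside the screen by default (the
selection rule is defined on raw p); Benjamini–Hochberg is available
behind a flag. Only positive log-ratios (variance higher under
treatment) qualify — the screen looks for treatment-associated
inflation, not any difference.

## Stratification metrics

* `log_rank`, `kaplan_meier`: standard two-group log-rank (chi-square,
  1 df) and product-limit estimator via the survival package.
* `group_hazard_ratio`: Cox fit on the high/low indicator with Wald CI;
  monotone likelihoods are flagged and the CI marked unreliable.
* `concordance_index`: Harrell's C by explicit pair counting — a pair is
  usable when censoring leaves the failure order determined; score ties
  count ½ — with a percentile bootstrap CI over patients (2000
  resamples, seeded).
* `two_year_classification`: the positive class is death observed
  before the horizon (24 months by default). Patients censored before
  the horizon count as negatives; with roughly half a validation-like
  cohort censored this is the only convention under which the four
  confusion-matrix cells sum to the full cohort, and it is optimistic —
  the output carries the count of early-censored patients as a caveat.
  An MCC with a zero denominator is reported as 0 with an explicit
  flag.
* `net_reclassification_improvement`:
  $[P(\mathrm{up}\mid \mathrm{event}) - P(\mathrm{down}\mid
  \mathrm{event})] + [P(\mathrm{down}\mid \overline{\mathrm{event}}) -
  P(\mathrm{up}\mid \overline{\mathrm{event}})]$ against the same
  2-year outcome (the horizon is configurable), patients lacking either
  classification excluded with the analysed n reported, percentile
  bootstrap CI (2000 resamples, seeded).
* `os_mixture_modes`: univariate Gaussian mixtures, $k = 1\ldots5$,
  fitted by EM and selected by BIC through `mclust` (unequal-variance
  models). Censored times enter as observed values, matching how the
  survival distribution of a partly censored cohort is usually
  displayed; the reported modes are component means of the selected
  model. We read "regularised" mixture selection as BIC cardinality
  control; mclust's initialisation and degenerate-solution handling
  replace a hand-rolled restart/variance-floor scheme.

## The subsampling experiment

A *dataset* at MNTS $k$ selects, for every patient, $\min(k, n_i)$ of
their $n_i$ samples; the combination space has
$\prod_i \binom{n_i}{\min(k, n_i)}$ elements. Unique datasets are drawn
by a Sobol low-discrepancy sequence with one dimension per patient:
coordinate $u_i$ maps to combination index
$\lfloor u_i C_i \rfloor + 1$ in lexicographic sample-id order,
duplicates are discarded and further points consumed, and when the
requested count reaches the space size the exhaustive enumeration is
used instead. Seeding applies a per-dimension digital XOR shift, which
preserves the base-2 equidistribution that makes the stream cover the
space evenly; the Sobol generator itself is implemented in-package from
the published Joe–Kuo direction numbers (512 dimensions) and tested
against the sequence's published first points and its dyadic balance
property.

Each dataset is re-aggregated (median per protein), scored, split at
logHR = 0, and summarised by the cohort-level group log hazard ratio
and log-rank p. Because millions of two-group Cox fits may be needed,
the experiment uses an in-package Newton solver for the
single-binary-covariate Efron partial likelihood, vectorised across
datasets, plus a vectorised log-rank; both are tested for numerical
equality against `coxph`/`survdiff`, and the experiment as a whole
against a brute-force enumeration on a small space. Datasets whose risk
split is degenerate (one group empty) are recorded with logHR = 0 and
p = 1 and flagged rather than dropped — dropping them would bias the
medians upward. Summaries are medians over datasets; runs are chunked
internally and the result is independent of the chunking.

Per-patient instability is quantified exhaustively:
`per_patient_loghr_range` enumerates every $k$-subset of one patient's
samples for all $k$, and a patient is flagged when the union of those
logHRs spans the threshold. `grade_variance_analysis` compares, across
patients, the variance of single-sample logHRs among low-grade
(Fuhrman 1–2) versus high-grade (3–4) samples — requiring at least two
graded samples per class within a patient (the within-patient-first
reading of "per-patient HR variance") — by fold ratio of medians and a
two-sided Mann–Whitney test. The low/high dichotomy at 1–2 vs 3–4 is
configurable.

## The synthetic cohort generator

`generate_cohort` emulates a two-arm multiregion RPPA study:

* **Design**: two cohorts of `n_patients = 22`; samples per tumour drawn
  from a law on 1–10 with median 4; a 55-protein panel (six candidate
  markers CA9, CDH2, EPCAM, MTOR, MLH1, BCL2 plus numbered nuisance
  proteins) with per-protein centres spread over $[-8.6, -5.6]$ log2
  units so values land in the $[-9, -5.2]$ window typical of normalised
  RPPA data.
* **Between vs within tumour**: latent tumour mean
  $\mu_{ip} \sim N(c_p, 0.06^2)$; samples scatter around it with
  baseline SD 0.12 (log2 units). These two SDs are calibration choices,
  not literature values: the ratio (within ≈ 2× between) is what makes
  a single biopsy a poor estimate of the tumour mean while the median
  of ~4 samples remains informative — the regime the analysis is about.
* **Divergent regions**: with probability 0.2 a sample deviates with 3×
  the usual SD, coherently across the panel, renormalised so total
  within-tumour variance stays at the configured value. Morphology-
  guided multiregion sampling deliberately includes distinct regions,
  and region-level divergence is what makes the median a meaningfully
  better aggregator as samples accumulate; under pure iid Gaussian
  scatter the median of three samples is barely more efficient than the
  mean of two and the monotone gain from deeper sampling is not
  reliably expressed. Setting `region_outlier_factor = 1` recovers pure
  Gaussian noise — the screen-calibration tests use that setting, since
  the F-test gate is exactly a check of Gaussian assumptions.
* **Grade**: per-sample Fuhrman grades from a fixed law; low-grade
  samples (1–2) get $\sqrt{3.5}\times$ the within-tumour SD, so the
  per-patient single-sample risk variance is 3.5-fold higher in
  low-grade tissue by construction.
* **Treatment effect**: in the exposed (development) arm, the
  within-tumour SD of designated proteins is multiplied by
  `variance_inflation` — the inflated-ITH fixture for screen power
  checks; the default of 1 (no inflation) is the null fixture.
* **Survival**: a proportional-hazards model on the *latent* covariates
  (not the noisy samples): baseline survival is a two-component
  lognormal mixture with modes at 11 and 27 months (weights 0.55/0.45,
  sdlog 0.18/0.15), times drawn by inverse transform of
  $S_0(t)^{e^{\mathrm{lp}}}$ on a dense log-time grid; the true
  coefficient vector defaults to the NEAT coefficients; age is uniform
  on [38, 79] and independent of the proteins (no joint law is known).
  Censoring is exponential with rate 0.030/month, calibrated so roughly
  half the validation-like arm is censored. Linking survival to latent
  rather than sampled values is deliberate: sampling noise then
  degrades prediction exactly as the ITH mechanism asserts, and deeper
  sampling recovers performance.
* **Clinical classes**: IMDC and MSKCC classes are drawn with logistic
  probabilities increasing in the latent linear predictor and realistic
  missingness (9% / 15%), so comparisons of NEAT against the
  clinico-pathological groupings are non-trivial. This is an emulation
  convenience, not a model of how those scores are computed — the
  scoring rules themselves live in `imdc_class` / `mskcc_group`.

Everything is deterministic given the seed, and the caller's RNG state
is left untouched.

**What the generator does not emulate**: spatial geometry and clonal
phylogeny; correlated protein–protein structure beyond the coherent
region deviations; assay-level artifacts (batch, slide, antibody
effects — inputs are taken as already normalised); informative
censoring; and any dependence of age on tumour biology. Tests passing
on these cohorts therefore validate the statistical machinery and its
qualitative ITH behaviour, not the biology of any particular marker
panel.

## Numerical choices

* Cox fitting: `coxph` defaults (Newton to its internal tolerance);
  monotone-likelihood detection by warning capture, |β| capped at 15 in
  the vectorised solver with a divergence flag.
* Survival inversion grid: 4096 log-spaced points on [0.01, 2000]
  months; monotone interpolation of $\log t$ against $S_0$.
* Two-tailed F p-value: twice the smaller tail (the doubling
  convention), capped at 1.
* Mann–Whitney comparisons use the exact distribution where R's
  heuristics allow (small samples without ties) and the normal
  approximation otherwise.
* Bootstrap CIs: percentile, 2000 resamples, explicit seeds.
* CSV writers emit doubles at 17 significant digits so round-trips are
  bit-lossless.

## Problem sizes in the test suite

The suite generates everything it tests. The heavier checks use, as
their own design choices: 300 replicates of n = 500 single-arm cohorts
for coefficient recovery (2-SE coverage has a 95.45% nominal rate, so
hundreds of replicates are needed to measure "≥95%" meaningfully);
20 seeds × 500 datasets × MNTS 1–3 on 300-patient arms for the
monotone-information property (at n = 22 the per-realisation medians
are dominated by which individual patients sit near the threshold, and
the property holds on average rather than per seed); 200 seeded null
cohorts for log-rank and proportional-hazards calibration; and a
64-dataset exhaustive space for the brute-force subsampling
cross-check.

## Known limitations

* At the study's actual size (22 patients per arm) every metric carries
  wide sampling error; single-seed outputs of `scripts/acceptance.R`
  vary accordingly, which is itself the reproducibility point the
  analysis makes.
* The screen's assumption gate is strict: under the default
  divergent-region noise most proteins fail Lilliefors normality, and
  candidate selection then rests on the log-ratio ranking rule. That is
  the intended behaviour of an assumption-gated test facing non-Gaussian
  ITH, but users simulating screen behaviour should choose the noise
  model to match the question.
* `two_year_classification` treats early-censored patients as
  non-events (optimistic labelling, flagged in the output).
* The NRI outcome horizon defaults to the same 2-year definition; other
  horizons are a parameter, not a validated default.
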