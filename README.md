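# dosestrat

Dose-pattern stratification of head-and-neck radiotherapy patients from
multi-organ dose-volume histograms (DVHs).

Late patient-reported symptoms after radiotherapy — dry mouth, swallowing
difficulty, excess mucus, voice dysfunction — reflect the joint dose
pattern across many organs at risk, not any single organ's dose.
`dosestrat` is for outcomes researchers and medical physicists who want a
reproducible pipeline that:

1. extracts dose-at-volume features from cumulative DVHs (`organ:Vx` =
   dose in Gy received by ≥ x% of the organ volume), with paired organs
   encoded as ipsilateral/contralateral by the higher-dose side;
2. clusters patients with a 3-component variational Bayesian Gaussian
   mixture and identifies the **high-dose (HD) cluster** (highest average
   summed organ mean dose);
3. distills HD membership into a minimal conjunction of dose-threshold
   rules by mutual-information beam search — the **simplified high-dose
   (SHD) group**, e.g. `contralateral_parotid:V25 > 62 Gy`, with
   precision/recall against HD;
4. tests both stratifications against nine clinical confounders with
   likelihood-ratio tests (p, odds ratio, ΔAIC, ΔBIC; a BIC drop ≥ 6 is
   "strong" evidence);
5. compares them against a recalibrated NTCP logistic model (clinical
   covariates + organ mean doses) under stratified 5-fold
   cross-validation, scored by pooled AUC-ROC and Matthews correlation
   (MCC).

Binary endpoints are a 6-month rating > 4 ("late severe") and a 6-month
change from baseline > 4 ("severe change") on 0–10 symptom scales; missing
baselines are imputed with a denoising autoencoder trained on the full
longitudinal rating table. A synthetic cohort generator with planted dose
groups, covariate enrichment and a configurable dose–outcome model makes
every stage testable without patient data.

## Worked example

```r
library(dosestrat)

cfg    <- cohort_config(n_patients = 300, seed = 42)   # planted 20/45/70 Gy groups
gen    <- generate_cohort(cfg)
bundle <- build_bundle(gen)                            # lateralize, features, endpoints

fit <- dose_strat(bundle$features, bundle$organ_means, seed = 43)
summary(fit)
#> Dose-pattern stratification
#>   patients: 300, components: 3
#>  component size weight avg_sum_mean_dose_gy role
#>          1   73  0.244                350.5   HD
#>          2  123  0.410                 99.7
#>          3  104  0.347                224.0
#> SHD group: 72 patients
#> <rule_set> simplified high-dose group
#>   contralateral_parotid:V25 > 62.18 Gy  [display: > 62]
#>   precision 1.000, recall 0.986, MI 0.770 bits (n_SHD=72, n_HD=73)
```

Component 1 is the high-dose cluster (average summed organ mean dose
350 Gy over the five dry-mouth organs); a single rule on the
contralateral parotid V25 reproduces it with precision 1.00 and recall
0.99.

```r
lrt_report(bundle$endpoints$late_severe, bundle$covariate_design,
           fit$labels, fit$hd_cluster, fit$shd)
#>   model      p_value odds_ratio  delta_aic  delta_bic
#> 1   All 8.429903e-07         NA -23.972621 -16.565056
#> 2    HD 3.170950e-04   3.148554 -10.966614  -7.262831
#> 3   SHD 6.867394e-04   2.946256  -9.524797  -5.821015
```

Adding the HD indicator to the covariate-only model multiplies the odds
of late severe symptoms by 3.1 (p = 3e-4) and drops BIC by 7.3 — strong
evidence the dose pattern adds information beyond stage, subsite, age,
performance status and the parotid dose limit.

```r
cross_validate(bundle$features, bundle$endpoints$late_severe,
               bundle$organ_means, bundle$ntcp_design, k = 5, seed = 44)
#> <cv_result> 5-fold stratified CV, n=300 (28.0% positive)
#>  model   auc   mcc
#>    All 0.692 0.211
#>     HD 0.629 0.269
#>    SHD 0.635 0.280
#>   NTCP 0.688 0.173
```

The one-bit SHD rule matches the HD cluster's discrimination and beats
the refit NTCP model on MCC. `run_pipeline(outdir, seed)` runs the whole
chain and writes `features.csv`, `labels.csv`, `rules.csv`, `lrt.csv` and
`cv.csv`; identical seeds give byte-identical reports.

Real cohorts enter through `read_dvh_table()` (long-format DVH CSV),
`read_symptom_table()` (patient/timepoint/symptom/rating CSV) and a
covariate data frame passed to `encode_covariates()`; the same reporting
functions then apply unchanged.

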