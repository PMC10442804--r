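---
title: "Dose-pattern stratification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-pattern stratification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosestrat)
```

## The problem

Head-and-neck radiotherapy irradiates many organs at risk at once — parotid
and submandibular glands, pharyngeal constrictors, larynx, esophagus — and
late patient-reported symptoms (dry mouth, swallowing difficulty, excess
mucus, voice dysfunction) arise from the *joint* dose pattern across these
organs, not from any single organ's dose in isolation. `dosestrat`
implements an unsupervised stratification of patients by their multi-organ
dose pattern, distills the resulting high-dose group into a handful of
dose-threshold rules a planner can act on, and quantifies how much the
stratification adds to clinical covariates and to conventional NTCP
(normal tissue complication probability) models.

The pipeline has five stages:

1. **DVH features.** Each organ's cumulative dose-volume histogram (DVH)
   is summarized by dose-at-volume values: `organ:Vx` is the dose (Gy)
   received by at least x% of the organ volume. Per symptom, a fixed organ
   set and Vx window is used (e.g. dry mouth: both parotids, both
   submandibulars and the hard palate over V25–V60 in 5% steps — a
   40-dimensional vector per patient). Paired organs are encoded
   side-neutrally: the side with the higher total mean dose over all
   paired organs is the patient's *ipsilateral* side.
2. **Clustering.** A 3-component variational Bayesian Gaussian mixture
   (full covariances, Dirichlet weight prior) is fitted to the
   standardized feature matrix; patients are assigned to the maximum
   posterior-responsibility component. The *high-dose (HD) cluster* is the
   component whose members have the highest average of the per-patient sum
   of organ mean doses.
3. **Rule mining.** A beam search over `feature > threshold` splits,
   scored by empirical mutual information (MI) with HD membership, returns
   a minimal conjunction of exceedance rules; patients exceeding all
   thresholds form the *simplified high-dose (SHD)* group, whose fidelity
   is reported as precision and recall against HD.
4. **Association testing.** Likelihood-ratio tests compare logistic
   models of each binary endpoint with and without the cluster indicators
   on top of nine clinical confounders (T-stage > 2, N-stage > 1, HPV
   status, base-of-tongue and tonsil subsites, age ≥ 65, ECOG 1 and 2,
   and the parotid mean-dose limit), reporting p, the indicator's odds
   ratio, and AIC/BIC changes (a BIC drop of 6 or more is read as strong
   evidence).
5. **Predictive evaluation.** Stratified 5-fold cross-validation compares
   rank-based cluster risk scores (1 / 0.5 / 0 by training-fold outcome
   counts; SHD membership scores 1 / 0) against an NTCP logistic model on
   covariates plus organ mean doses, using pooled AUC-ROC and Matthews
   correlation (MCC).

Endpoints are binary: a 6-month symptom rating above 4 ("late severe"),
and a 6-month change from baseline above 4 ("severe change"). Ratings are
0–10 integers over ten time slots (baseline, seven weekly ratings during
treatment, 6-week and 6-month follow-up); during-treatment ratings are
used only as inputs to baseline imputation, never as endpoints.

## A note on the two readings of "Vx"

Clinical literature uses Vx both for *dose at volume* (the dose received
by x% of the organ: a dose in Gy) and *volume at dose* (the percent of
the organ receiving at least x Gy). Cluster features use the first
reading (`dose_at_volume()`); published organ limits such as the larynx
edema limit "V50 > 27 (%)" use the second (`volume_at_dose()`). Both are
provided and both are exercised by the dose-limit flags
(`dose_limit_flags()`). With this convention a rule like "contralateral
parotid V45 > 0 Gy" means "at least 45% of the gland receives any dose at
all", which is why dose-at-volume returns 0 when less than x% of the
organ is irradiated.

Curves are stored on arbitrary strictly increasing dose grids with linear
interpolation and zero volume beyond the last grid point; a (0 Gy, 100%)
point is prepended when missing. Features are invariant to grid
refinement by construction.

## The mixture model and its numerical choices

The variational mixture follows the standard mean-field treatment of a
Gaussian mixture with a symmetric Dirichlet prior (concentration 1/k per
component) on the weights and Gaussian–Wishart priors on component
parameters. Features are standardized internally; labels, means and
covariances are reported on the original Gy scale. Two choices matter in
practice and were made deliberately:

* **Wishart prior scale = empirical covariance.** Vx features are
  strongly correlated within and across organs, so the data live near a
  low-dimensional manifold. An isotropic prior scale is enormous compared
  with the near-singular within-cluster scatter and drags every component
  towards the global covariance, collapsing the mixture. Setting the
  prior scale matrix to the empirical covariance of the standardized
  features (plus a 1e-4 diagonal ridge) keeps the prior commensurate with
  the data geometry; this matches the default of the widely used
  variational mixture implementation in scikit-learn.
* **Converged k-means initialization, k centers.** Restarts are
  initialized from a multi-start k-means solution (best of 10 by
  within-cluster sum of squares) and the best restart is kept by the full
  variational lower bound (ELBO). The bound is also the convergence
  criterion (relative change below 1e-5, 200-iteration cap, warning with
  the best-so-far model on non-convergence). With 40 correlated features
  and a few hundred patients the marginal-likelihood Occam penalty of a
  full-covariance component (~820 covariance parameters) genuinely
  exceeds the data-fit gain of splitting two close groups, so the bound
  can rank a merged solution above the true split; a well-converged
  k-means start keeps the optimizer in the correct basin, exactly as
  k-means++ seeding does for the reference implementation. A practical
  consequence, verified against that implementation: on *low*-dimensional
  features the Dirichlet prior empties superfluous components (weights
  below 0.05 when the data hold fewer groups than k), while on the
  40-feature matrix both implementations prefer splitting a true group
  instead.

Assignment ties resolve to the lower component id; an empty component is
excluded from HD identification with a warning. Averaging (not summing)
the per-patient mean-dose sums within a cluster makes HD identification
invariant to cluster size; adding a constant dose to every organ leaves
the argmax unchanged.

## Rule mining

Candidate thresholds per feature are midpoints between consecutive
distinct sorted values, thinned to at most 64 at evenly spaced quantiles.
Depth 1 keeps the top-25 splits by MI (base 2, plug-in estimate,
0·log 0 = 0); each further depth extends every beam conjunction by every
split, scores the *full conjunction on the full cohort*, and keeps the
global top 25. The search stops at depth 2 by default (matching the
two-rule sets the method reports) or as soon as no extension strictly
increases MI; the best conjunction overall is returned, with ties broken
by higher recall, then fewer rules, then lexicographic feature names,
then lower thresholds. Keeping ties at the beam cutoff makes the
full-width beam provably equal to exhaustive search, which the test suite
asserts on random matrices. The direction is fixed to ">" because the
target is the high-dose cluster; maximum-dose features join the candidate
pool where a symptom configuration asks for them (voice).

Exact recovery of a planted rule (`precision = recall = 1`) is only
well-posed when the feature resolution leaves a clean gap around the
planted boundary: with hundreds of distinct continuous values the
64-candidate thinning need not offer a threshold inside the gap. The
recovery tests therefore plant rules on features tabulated at 2-Gy
resolution, which is how DVH exports typically arrive; thresholds are
reported at full precision alongside a rounded display form.

## Baseline imputation

Missing baseline questionnaires are imputed with a denoising autoencoder
trained on patients with a fully observed baseline and at least 70% of
all their ratings: inputs are all ratings at all time points scaled to
[0, 1] (missing as 0), corrupted during training by multiplicative
Bernoulli zeroing at rate 0.5; the network is two fully connected hidden
layers (32 and 16 units) with ReLU followed by batch normalization, a
linear output, mean-squared error on observed cells, Adam at learning
rate 0.001 in minibatches of 32, up to 2000 epochs with early stopping
(patience 50) on a held-out 10% split scored with a fixed corruption
mask. After training, batch-normalization statistics are recalibrated
with one pass over the *uncorrupted* training inputs — imputation-time
inputs are mostly clean, and statistics accumulated on half-zeroed
batches bias the outputs noticeably. Outputs are rescaled to 0–10,
clipped and rounded; observed values are never overwritten; with fewer
than 30 trainable patients the imputer falls back to per-symptom medians
with a warning. Everything is deterministic given the seed.

## Evaluation choices

Folds are stratified by outcome with sizes differing by at most one;
clustering and rule mining are refit inside each training fold (the
leakage-safe reading; `frozen_clusters = TRUE` reproduces the weaker
variant that fits once on the full cohort). Fold scores are pooled before
computing AUC (Mann–Whitney with half-credit for ties) and MCC; per-fold
AUCs are retained for dispersion. Three-level risk scores are binarized
at risk ≥ 1 (HD membership) for MCC, and NTCP probabilities at 0.5. When
a training fold's HD split admits no rules (degenerate stratification),
the simplified group falls back to HD membership for that fold.
Separation in a logistic fit triggers a ridge-penalized refit (penalty
1e-6) with a warning rather than an error; aliased design columns are
dropped for estimation but kept in the parameter count, so an
uninformative added indicator costs the full +2 AIC.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` plants three latent dose groups (default weights
0.40/0.35/0.25) with per-group organ mean-dose targets of 20/45/70 Gy and
3 Gy patient-level spread, half of which is shared across a patient's
organs (inter-organ correlation 0.5). Each (patient, organ) mean dose is
realized as a logistic-tail cumulative DVH on a 1-Gy grid whose midpoint
is solved by bisection to match the target within 0.5 Gy. Paired organs
receive a ±2–8 Gy left/right asymmetry so lateralization is non-trivial.
Covariates are enriched in the high-dose group in the direction seen in
real cohorts (more T4 and N2c/N3, more base-of-tongue primaries, more
modulated treatment, less prior surgery); severe 6-month outcomes follow
a logistic model on the centred average organ mean dose (0.06 per Gy by
default) plus small covariate effects, and the 0–10 rating is drawn as
Binomial(10, q) with q inverted so that dichotomizing at > 4 matches the
configured probability. Baselines are missing completely at random for
17% of patients.

The default dose effect is deliberately stronger than the clinical
effects the method reports on real cohorts (odds ratios near 3): at desk
scale the generator's job is to make recovery properties testable —
planted groups recoverable at ARI ≥ 0.9, planted rules exactly, LRT
p-values far below 0.01 — not to reproduce a particular cohort's effect
sizes. What passing tests show is that the pipeline recovers structure
that is genuinely present and reports chance-level performance when
outcomes are permuted; they do not show that real DVH data contain three
dose groups, that real missingness is random, or that MDASI ratings are
binomial. The generator also makes no attempt at anatomically realistic
3-D dose painting or at the real cohort's exact margins.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data:
feature oracles on hundreds of random piecewise-linear curves; rule-miner
equivalence on 50 random 200 × 10 matrices; cluster recovery on 50
cohorts of n = 300; LRT calibration on 1000 null replicates at n = 300;
cross-validation on cohorts of n = 300–600; imputer comparisons on 20
masked 150-patient tables. These sizes were chosen so every property is
measured with useful power while a full run stays comfortable on a
laptop. Given a real cohort export (DVH CSV, symptom CSV, covariate
table), the same functions emit the rule, association and
cross-validation reports without code changes.

## Known limitations

* The variational mixture inherits the reference implementation's
  initialization sensitivity in high dimension; the shipped defaults
  (multi-start k-means, 5 restarts, ELBO selection) are robust on
  separated dose groups but k is fixed by design — no model selection
  over the number of components is attempted.
* MI-based rule mining is greedy beyond depth 1 within a beam; it returns
  a single best conjunction, not alternatives, and only exceedance
  ("greater than") rules.
* The eligibility filter uses across-window item completeness (a single
  fraction over all symptoms and time points), one of two defensible
  readings of the inclusion rule.
* Raw p-values are reported without multiple-testing correction,
  matching the reporting convention of the underlying method.
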