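---
title: "Quantifying physician agreement on sepsis versus SIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying physician agreement on sepsis versus SIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisagree)
```

## The problem

Early in critical illness, sepsis and non-infectious systemic inflammation
(SIRS) look alike. Different physicians, seeing the same patient at
different times and with different amounts of information, frequently
disagree on which is present. `sepsisagree` provides the machinery to
measure that disagreement: the call vocabulary and consensus rules of a
multi-evaluator adjudication design, chance-corrected multirater agreement
statistics, stratified comparisons, reclassification-risk summaries, the
significance tests used for group contrasts, logistic discriminant scoring,
and a synthetic cohort generator so that every stage is testable without
access to protected patient data.

## Calls, categories, and consensus rules

Each evaluator makes a 4-level infection call — `none`, `possible`,
`probable`, `definite` — which maps onto three diagnostic categories:

```{r}
map_call(c("none", "possible", "probable", "definite"))
```

Agreement is always judged on the mapped 3-category scale, so a
probable-vs-definite split counts as agreement on sepsis. The design has
four evaluation methods: the attending physician's admission impression,
a site investigator's admission impression, the two site investigators'
consensus discharge evaluation, and a three-member external expert panel
(the retrospective physician diagnosis, RPD).

Two consensus rules operate on mapped categories:

* **Discharge consensus** (`consensus_discharge`): if the two
  investigators' categories agree, that is the consensus; otherwise a
  third adjudicator's call is required and the majority of the three
  categories wins; a three-way split — or "possible" from all three — is
  indeterminate. A missing adjudicator where one is required is an error
  carrying the patient id, because the design guarantees adjudication.
* **Panel consensus** (`consensus_rpd`): any 2/3 category majority wins
  (including a majority for indeterminate); a three-way split is
  indeterminate. We treat a 2/3 majority on "possible" as indeterminate;
  the alternative reading (no agreement) lands on the same category, so
  the rule is total either way.

`unanimous_diagnosis` implements the strictest evaluation: SIRS or sepsis
only when the discharge consensus and all three individual panelists
agree exactly; anything less — including unanimous "indeterminate" — is
indeterminate. Whether the discharge investigators' pre-adjudication
agreement should be judged on the 4-level or the 3-level scale is not
fixed by the design we model; we judge it on the 3-level scale, which is
the scale on which every reported statistic lives.

## Agreement statistics

For N items rated by n raters into k categories with counts
$n_{ij}$, the overall percent agreement is the fraction of agreeing rater
pairs averaged over items,

$$P_o = \frac{1}{N}\sum_{i=1}^N \frac{\sum_j n_{ij}(n_{ij}-1)}{n(n-1)},$$

and the two chance-corrected statistics differ only in the chance model:

* **free-marginal** (Randolph) kappa assumes all k categories equally
  likely a priori, $P_e = 1/k$, so
  $\kappa_{free} = (P_o - 1/k)/(1 - 1/k)$ — for k = 3 simply
  $(3P_o - 1)/2$;
* **fixed-marginal** kappa estimates chance from observed marginals:
  Cohen's form for two raters (rater-specific marginals), Fleiss's pooled
  form $P_e = \sum_j p_j^2$ otherwise.

Because $\sum_j p_j^2 \ge 1/k$, the pooled fixed-marginal kappa never
exceeds the free-marginal kappa, and the gap widens with marginal skew —
`kappa_ratio_profile()` traces this dependence against sample size.
Cohen's two-rater form can in principle exceed $\kappa_{free}$ when the two
raters' marginals disagree strongly (its $p_e$ can fall below $1/k$); the
pooled form cannot. In small strata the free-marginal statistic is the
stable choice, which is why stratified analyses report it.

Text reports round kappas to two decimals, half away from zero
(`round_half_up`), so e.g. $P_o = 0.930$ at k = 3 gives
$\kappa_{free} = 0.895 \to 0.90$; machine output keeps full precision.

Confidence intervals are percentile bootstrap over patients (default 2000
replicates, seeded), since the item is the sampling unit; for the
free-marginal kappa, which is an affine map of the mean per-item
agreement, the bootstrap reduces to resampling the per-item agreement
components and is vectorized. An analytic normal interval based on the
per-item agreement variance is available as an option. Replicates on
which the fixed-marginal kappa is undefined (degenerate marginals) are
skipped and counted. A coverage simulation (two raters, N = 249, true
$\kappa_{free} = 0.6$, 500 simulations) in the test suite checks that the
nominal 95% interval covers at close to nominal rate.

Patients missing either evaluation of a comparison are dropped pairwise
for that comparison only — no imputation anywhere — and the effective N
is reported alongside the number dropped.

## The comparison pipeline

`comparison_specs()` enumerates the standard evaluator pairings A–K
(initial vs initial, initial vs each reference, the local vs external
reference, the three panelist pairs, the two discharge investigators,
and the local reference against the unanimous diagnosis). The "unanimous"
method K is not itself a pair, so as a comparison we pair it with the
discharge consensus, the evaluation it most directly extends.
`numbered_comparison_map()` ships the mapping between the fifteen
numbered comparisons and letters x cohorts as data, so it can be
corrected without touching code. `run_comparison()` filters by cohort,
hospital, or infection site (multi-site patients match any of their
sites), builds the rating matrix, and returns the agreement statistics;
an empty stratum yields a flagged row rather than an error.

`reclassification_table()` cross-tabulates an initial against a later
category and labels the six off-diagonal transitions by their change in
apparent risk on the SIRS < indeterminate < sepsis ordering: moves toward
sepsis are risk increases (delayed antibiotics if the initial call were
acted on), moves toward SIRS are decreases (excess antibiotics).

`indeterminate_vote_fraction()` reports, per patient, the fraction of
evaluation methods calling the case indeterminate. The exact composition
of the pooled evaluations is not pinned down by the design we model, so
it is an argument; the default pools the five method-level evaluations
(attending, investigator initial, discharge consensus, panel consensus,
unanimous).

## Group tests

The stratified contrasts use four classical tests, all two-tailed:
pooled-variance two-proportion z (no continuity correction, so $z^2$
equals the uncorrected Pearson chi-square), the N−1 chi-square
(Pearson scaled by $(N-1)/N$, preferred at small expected counts),
the pooled-variance t-test, and the two-sample Kolmogorov–Smirnov test.
`parameter_screen()` applies the t-test to continuous and the z-test to
binary parameters, on available cases per parameter, and sorts by
p-value. No multiple-testing correction is applied by default — the
screen is descriptive, ranking candidate discriminators rather than
testing a family of hypotheses — but Benjamini–Hochberg adjustment is one
argument away.

## Discriminant models

`preset_model()` carries four published logistic scoring equations over
line-data covariates: sepsis-vs-indeterminate (SeptiScore, WBC extremes,
MAP.Max), SIRS-vs-indeterminate (log2 procalcitonin and SeptiScore), and
two antibiotic-treatment discriminators for SIRS patients. Procalcitonin
enters as log2 after flooring at 0.05 ng/mL — a detection-limit
convention that keeps the log defined; the floor is part of the symbolic
transform so serialized models round-trip bitwise. Scoring never imputes:
a record missing a model covariate is flagged and scored `NA`.

`fit_logistic()` wraps a binomial GLM with separation detection
(separation means the MLE does not exist, so coefficients are withheld
and the fit flagged). `roc_auc()` computes the AUC in its Mann–Whitney
rank form with half-credit for ties and a stratified bootstrap CI — the
bootstrap because the model-fitting route to these AUCs does not commit
to a closed-form variance. Whether an AUC is apparent (resubstitution) or
cross-validated matters; `roc_auc` itself is agnostic, and the
cross-validated number is what `recursive_feature_elimination()` traces
while dropping the least-important feature (smallest |Wald z| for the
logistic base, smallest mean Gini decrease for the random forest;
permutation importance is available) at each set size.

## The synthetic cohort generator

The generator exists so every downstream stage has a ground truth. It
emulates a 249-patient, seven-hospital ICU cohort:

* **latent class** drawn with prevalence 106/249 SIRS, 74/249
  indeterminate, 69/249 sepsis (the exact fractions, so they sum to
  one). Indeterminate is a real third class with its own covariate
  structure, not merely rater noise, because the analyses treat
  indeterminates as a group.
* **rater calls** drawn per role from 3x4 class-conditional confusion
  matrices, conditionally independent given the class. Default
  accuracies (attending 0.79; investigator initial 0.82; discharge
  reviewers and adjudicator 0.83; panelists 0.82) were chosen once so
  that all pairwise free-marginal kappas land in the 0.5–0.8 band with
  the attending's admission call noisiest and the local-vs-external
  reference comparison highest — the qualitative ordering the analysis
  is meant to detect. Two optional dependence knobs exist, both off by
  default: a shared per-patient difficulty effect that pushes every
  rater toward "possible", and `rpd_follows_discharge`, under which a
  panelist adopts the investigators' consensus with the given
  probability (the panel did see that consensus, so their agreement is
  an upper bound rather than an independent replication).
* **covariates** drawn class-conditionally from truncated normals within
  physiologic bands (procalcitonin log-normally, floored at 0.05 ng/mL),
  independent within class — the real correlation structure is unknown,
  so independence is the documented, configurable default. Locations
  follow the reported directionality (indeterminate and septic patients
  older, sicker, longer-staying, higher PCT and SeptiScore).
* **inclusion filter**: records are redrawn until they meet at least two
  systemic-inflammation criteria *as emitted*, i.e. after missingness
  masking, so the published invariant holds on the table an analyst
  sees. This conditioning slightly shifts the emitted distribution of
  the four criterion variables (temperature, heart rate, respiration,
  white count); recovery tests therefore check configured means on
  covariates outside the filter.
* **antibiotics**: septic patients are always treated; indeterminate
  patients get a +2.25 logit offset (treated fraction near 0.9); for
  SIRS patients a weak logistic model on MAP.Min, HR.Max, Temp.Max and
  N.SIRS was calibrated once to a treated fraction near 0.57 with
  treated/untreated separability of AUC about 0.7 — deliberately weak,
  because the scientific point the machinery must reproduce is that
  this decision is *hard* to discriminate.
* **missingness** is explicit `NA` at configured per-covariate rates
  (blood-gas and lactate panels most often absent), never imputed.

One arithmetic subtlety is worth recording: raters uniform over the
*four calls* are not at chance on the mapped category scale, because two
calls collapse to sepsis — the mapped marginal is (1/4, 1/4, 1/2) and
two independent such raters have expected $P_o = 0.375$, hence
$\kappa_{free} = 0.0625$ exactly, not 0. Chance level on the category
scale is instead `chance_rater_confusion()` (rows uniform over mapped
categories), under which pairwise kappas vanish; the test suite asserts
|κ| < 0.05 at n = 5000 under that configuration.

What the generator does **not** emulate: time-resolved vitals (only the
min/max summaries), within-class covariate correlation, site-specific
practice differences beyond enrolment weights, and free-text physician
comments. Passing tests on synthetic cohorts therefore demonstrate that
the statistical machinery is correct and well-calibrated under the
stated generative assumptions — not that any particular real cohort
satisfies those assumptions.

## Problem sizes and numerical choices

The test suite runs its Monte-Carlo checks at sizes chosen to keep the
whole suite around a minute while leaving comfortable statistical
margins: marginal/confusion recovery and null-kappa checks at n =
5000–6000 patients, coefficient recovery on ~5000 SIRS records, CI
coverage with 500 simulations x 1000 bootstrap replicates, and feature
elimination over 20 seeded runs at n = 2000. Exhaustive oracles
(enumerated rating matrices, the 64 panel triples) are preferred to
sampling wherever enumeration is feasible. Kappa denominators are
guarded: chance agreement within 1e-12 of 1 is reported as a flagged
undefined result rather than a quotient. Decimal rounding uses an
epsilon guard so that values like 0.895 stored in binary round up as
intended.

## A worked example

```{r}
cohort <- generate_cohort(cohort_config(n_patients = 249, seed = 42))
report <- run_all(cohort, comparison_specs(c("A", "C", "F")))
report[, c("comparison_id", "N", "p_o", "kappa_free", "kappa_fixed")]

rec <- reclassification_table(cohort, "attending_initial", "rpd_consensus")
rec
```

## Known limitations

* Fixed-marginal kappas on counts-only matrices always use the pooled
  (Fleiss) form; Cohen's form needs the raw two-rater calls.
* The multirater panel statistics pool the three panelists into one
  rating matrix by default; the averaged-pairwise alternative is
  available through the individual panelist comparisons (G, H, I).
* The generator's covariate independence within class understates the
  redundancy between, e.g., APACHE and its input vitals; screens on
  synthetic data will rank correlated families slightly differently than
  on real data.
* Between-group significance of stratified *agreement statistics*
  (as opposed to patient covariates) depends on how pseudo-replicates
  are formed across comparisons; the package reports the statistics and
  leaves such pooling explicit to the analyst.
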