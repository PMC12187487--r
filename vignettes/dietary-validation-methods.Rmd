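---
title: "Validating weighed food records against recovery biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating weighed food records against recovery biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietvalidr)
```

## The problem

Self-reported dietary assessment — here a 7-day weighed food record (WFR),
completed twice about a month apart — is the workhorse of nutritional
epidemiology, but it misreports: people forget items, estimate portions
poorly, and systematically under-report energy. Two complementary questions
decide whether such a tool is usable:

* **Validity** — do reported intakes agree with objective reference measures?
  Recovery biomarkers provide those references: a known, stable fraction of
  ingested protein nitrogen and potassium is excreted in a complete 24-hour
  urine, serum folate rises with folate intake, and in a weight-stable adult
  total energy expenditure (TEE) must equal energy intake.
* **Reproducibility** — do two administrations of the record rank people the
  same way?

`dietvalidr` implements this full analysis: the biomarker recovery
equations, the energy-metabolism chain (indirect calorimetry, activity
scoring, misreporting screening), the agreement-statistics toolkit, and an
orchestrating pipeline. Because participant-level study data of this kind
are rarely shareable, the package ships a synthetic-cohort generator that
emulates the statistical structure the analysis assumes, so every stage is
testable end to end against known ground truth.

## Biomarker recovery model

For a complete 24-hour urine collection:

* Total urinary nitrogen is derived from urea,
  $N\,[\mathrm{g/24h}] = 0.028\,[\mathrm{g/mmol}] \times \mathrm{urea}\,[\mathrm{mmol/24h}]$
  (the molar mass of the two nitrogen atoms in one urea molecule).
* Protein intake is estimated as
  $\hat P = 6.25 \times N / r_N$ with the standard nitrogen-to-protein
  factor 6.25 and recovery fraction $r_N = 0.81$ (the fraction of ingested
  nitrogen excreted within 24 h).
* Potassium intake is $\hat K = K_{\mathrm{urine}} / r_K$ with
  $r_K = 0.80$.
* Collection completeness is judged against an expected creatinine
  excretion of 21 mg/kg body weight for men and 17.5 mg/kg for women;
  the optional completeness correction rescales an analyte by
  expected/observed creatinine. The correction formula itself is a design
  choice — the completeness factor is conventionally named but its algebra
  is not standardised — and multiplicative rescaling is the standard
  normalisation; both corrected and uncorrected estimates are always
  emitted. Collections with a duration outside 24 ± 4 h are flagged, never
  rescaled.
* Urine volume is weight/density with a default density of 1.020 g/mL
  (configurable; reference texts quote 1.015–1.025 for healthy adults).

## Energy metabolism chain

Resting energy expenditure comes from ventilated-hood indirect calorimetry
via the Weir equation,
$\mathrm{EE}\,[\mathrm{kcal/min}] = 3.941\,\mathrm{VO_2} + 1.106\,\mathrm{VCO_2}$,
averaged over the (typically two) measurement periods, scaled to 24 h, minus
the protein correction $2.17\,[\mathrm{kcal/g}] \times N$. The constant set
is a named, swappable registry (`weir_constants()`): the protein-corrected
classical set is the default, and a simplified no-nitrogen set is provided
for sessions without urine data; every report records which set was used.

Physical activity level (PAL) is scored from the IPAQ short form: MET-hours
are summed over vigorous (8.0), moderate (4.0) and walking (3.3) activity —
the IPAQ scoring convention — plus sitting (1.3), with all remaining hours
assigned a sleep/lying MET of 0.95; PAL is total MET-hours divided by 24.
The source questionnaire does not fix the sitting and sleep/lying MET
values, so they are package defaults, configurable in `met_table()`. PAL
values above 2.5 (strictly) are excluded as implausible for a non-athletic
cohort. TEE is REE × PAL.

Misreporting is screened with Goldberg-type cut-offs on the ratio of
reported energy intake (the 7-day mean) to measured REE: under-reporter
below 1.05, over-reporter above 2.28, acceptable otherwise. Both bounds are
strict for the extreme classes, so the boundary values themselves count as
acceptable. Under-reporters are retained by default (the analysis compares
reported values with biomarkers; screening is descriptive), with a
sensitivity switch to drop them. Weight stability between visits is checked
at a strict 2.5% relative change.

## Agreement statistics

* **Spearman correlation** on midranks, exact p for n ≤ 9 without ties,
  asymptotic otherwise, with interpretation bands: below 0.20 poor, 0.20 to
  just under 0.50 acceptable, 0.50 and above strong. The published banding
  convention leaves the interval [0.49, 0.50) unassigned; the package
  resolves it to "acceptable", i.e. strong means ρ ≥ 0.50 exactly. Bands
  apply to the signed coefficient; the absolute value is also reported.
* **Regression R²** from OLS, reported unadjusted (in the R² sense);
  covariate adjustment (age, sex) appends terms to the model. A constant
  outcome yields R² = 0 by convention; rank-deficient designs are rejected.
* **Bland-Altman**: mean difference, sample SD (n − 1), limits of agreement
  at ±1.96 SD, with per-pair coordinates exported for plotting.
* **Wilcoxon signed-rank**, two-sided: zeros dropped by default (Pratt
  available); exact null distribution for up to 12 informative pairs
  (tabulated for untied ranks, enumerated by convolution when absolute
  differences tie), normal approximation with tie correction beyond, without
  continuity correction.
* **Paired t** with n − 1 df; identical vectors give t = 0, p = 1, while a
  constant nonzero difference is rejected as degenerate.
* **ICC**: single-measure, two-way model from the ANOVA mean squares;
  absolute agreement (ICC(A,1)) by default since a reproducible record
  should agree in level, not only ranking; consistency (ICC(C,1)) is
  selectable, and the model used is recorded in the output.
* **Normality gate**: Shapiro-Wilk at α = 0.05, retried on the log scale
  for positive data; nonparametric variables are summarised as median and
  IQR downstream.
* **Percent bias**: 100 × (reported − biomarker)/denominator, with the
  denominator selectable (biomarker by default).

No multiplicity adjustment is applied anywhere; the pipeline reports raw
p-values by design.

## The synthetic cohort

`sim_config()` + `simulate_cohort()` generate a full study: participants
(age 35–70, BMI 22–32 by construction, ~80% women, weight-stable between
visits), two 7-day record rounds, a 24-h urine on the last day of round 1,
fasting serum folate, two calorimetry measurements, and IPAQ minutes.

The intake model is lognormal throughout, parameterised by arithmetic mean
and CV (dietary intakes are positive and right-skewed; group-level tests on
such variables typically reject normality, which is why the analysis
defaults to nonparametric summaries):

* habitual intake $H_i$ per nutrient: between-person CV 0.25;
* daily intake $H_i \times$ day factor: within-person CV 0.30;
* reported intake = daily intake × per-participant bias factor
  (mean 0.92, SD 0.15), shared across days and rounds — the systematic
  component Goldberg screening is designed to catch. The bias mean was
  calibrated so the default cohort shows roughly the 13%
  under-reporter fraction typical of weighed-record studies in motivated
  volunteers. There is no additional day-level reporting error: day-to-day
  variation is carried entirely by the within-person CV.

Three structural choices deserve emphasis:

* **Energy balance.** Habitual energy intake is not an independent draw: it
  is REE × PAL × a small lognormal deviation (CV 0.10), because a
  weight-stable cohort is in energy balance. REE itself comes from a
  Mifflin-St Jeor-type function of weight, height, age and sex — used only
  to make the synthetic gas exchange realistic; the analysis never sees it.
  Gas exchange is synthesised by inverting the Weir equation at a
  respiratory quotient of 0.85, and IPAQ minutes are solved so that IPAQ
  scoring reproduces the drawn PAL exactly.
* **Plant-food propensity.** Fruit, vegetables, folate, potassium,
  vitamin C and fibre share a latent factor (50% of between-person
  log-variance), because the fruit-and-vegetable validity comparisons are
  only meaningful if plant-rich diets raise all of these together.
* **Biomarker time window.** The 24-h urinary biomarkers are based on the
  mean true intake over the final 3 record days, not the collection day
  alone: body-pool turnover smooths excretion over the preceding days. This
  is also what makes the weekly-average exposure window outperform the
  last-day window against the biomarker, the directional property the
  pipeline is expected to show. Setting `biomarker_window_days = 1` makes
  the urine reflect the collection day only.

Assay noise is lognormal with analyte-specific CVs (serum folate 6.05%,
urea 3%, potassium 1.2%, creatinine 4% — laboratory-quoted magnitudes), and
collection completeness has its own CV (8%). Serum folate is log-linear in
total folate intake (slope 0.8, anchored at 330 µg/d ↔ 8.75 ng/mL); the
dose-response form is an assumption of the generator, not of the analysis,
which treats serum folate purely as a correlate. Supplement users (70%) add
fixed daily folate (200 µg), calcium (400 mg) and vitamin D (10 µg); days go
unreported independently with probability 0.023 (≈6.84 of 7 days completed),
and at least one day per round is always retained. True-intake means are
typical Nordic-adult values (e.g. vegetables 241 g/d, fibre 19.1 g/d,
potassium 4267 mg/d, protein 82 g/d).

The `truth` table (habitual intakes, bias factors, latent REE/PAL,
biomarker bases) is written to a separate file so the analysis can be run
blinded; analysis functions never read it.

With `zero_noise = TRUE` every random component except the between-person
spread is switched off, and the recovery chain inverts exactly: biomarker
protein and potassium equal the latent truths to machine precision, ρ = 1
and percent bias 0 end to end. This round-trip limit is the backbone of the
test suite.

**What the generator does not emulate:** food-item-level reporting (only
nutrient totals), nutrient-specific reporting bias (one factor scales all
nutrients, so the generator cannot simultaneously reproduce, say, mild
protein over-reporting alongside large potassium under-reporting, a pattern
real food-composition gaps produce), correlated test-reference errors,
seasonal drift between rounds, or incomplete urine collections beyond a
completeness multiplier. Passing tests therefore demonstrate that the
*analysis machinery* is correct and well calibrated — not that any
particular field instrument is valid.

## Numerical and design notes

* Lognormal draws are parameterised so the *arithmetic* mean equals the
  requested mean for any CV; a zero CV degenerates to the exact mean rather
  than an `exp(log(·))` round trip, keeping the zero-noise limit exact.
* All CVs accept 0 (noise off); recovery fractions live in (0, 1].
* Determinism: one seed drives the whole dataset; identical config + seed
  reproduce every table bitwise.
* Problem sizes in the test suite were chosen to make each statistical
  check sharp but quick: Monte-Carlo bias recovery at n = 2000 (1%
  tolerance), limits-of-agreement coverage at n = 10 000, the large-sample
  validity oracle at n = 50 000 against a n = 500 pipeline run (compared on
  the Fisher-z scale within the 95% band of an n = 500 estimate), and the
  weekly-vs-last-day directional property over 20 replicates of n = 120.
* The exact Wilcoxon path is limited to 12 informative pairs; beyond that
  the normal approximation's error is far below any decision threshold the
  pipeline uses.
* Spearman p-values switch from exact to asymptotic at n = 9 (the usual
  `cor.test` convention); validity analyses at realistic n always use the
  asymptotic form.

## Worked example

```{r example}
cfg <- sim_config(n_participants = 71, seed = 2026)
study <- simulate_cohort(cfg)
validity <- run_validity(study)
tidy(validity)[, c("pair", "window", "n", "rho", "band", "r2_crude")]
glance(validity)

repro <- run_reproducibility(study)
tidy(repro)[, c("variable", "median_r1", "median_r2", "rho", "band", "icc")]
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(validity$bland_altman$protein_vs_urinary_protein)
autoplot(repro)
```

## Known limitations

* The Weir constant registry ships the classical protein-corrected set; the
  alternative gas-exchange constant sets in the literature differ in the
  third decimal and users can register their own, but no set is labelled
  with an author's name unless its values are verifiable.
* The Goldberg screen here uses measured REE as the denominator; predicted
  BMR equations are deliberately not a primary path (a measured REE is
  available whenever the chain runs), though `goldberg_classify()` accepts
  any positive denominator.
* Reported p-values are unadjusted; if many variable pairs are examined,
  control of the family-wise error is the user's responsibility.
* The ICC assumes exactly two rounds; k > 2 administrations are out of
  scope.
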