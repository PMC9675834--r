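---
title: "Mediation of race differences in telomere length through pollutant mixtures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mediation of race differences in telomere length through pollutant mixtures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popmediate)
```

## The scientific question

Non-Hispanic Black Americans tend to have *longer* leukocyte telomere
length (LTL) than non-Hispanic White Americans, despite carrying more risk
factors for short telomeres. One environmental explanation: serum burdens
of persistent organic pollutants (POPs) — PCBs, dioxins, furans — are both
racially patterned (through residential and occupational segregation) and
positively associated with LTL. `popmediate` implements the full analytic
chain needed to ask how much of the Black/White difference in log LTL is
transmitted through 15 correlated serum POPs in an NHANES-like cohort:
censored-data imputation, survey-weighted single-mediator mediation,
multivariate mixture mediation, summary-score mediation, and sensitivity
analysis — together with a synthetic-cohort generator whose ground truth
makes every stage testable without restricted survey data.

## The mediation model

For participant $i$, let $A_i$ be the binary group indicator (1 = Black
respondent analogue), $Y_i$ log LTL, $M_{ij}$ the log concentration of
chemical $j$ (lipid-standardised), and $Z_i$ the adjustment covariates
(standardized age and age$^2$, sex, 5-level education, log cotinine, log
total lipids, white-cell count, five differential percentages, survey
cycle). Three weighted linear models define the single-mediator
decomposition:

* total effect: $Y_i = \mu_0 + \mu_a A_i + Z_i^T\mu_z + \epsilon_i$
* mediator model: $M_{ij} = \alpha_{0j} + \alpha_{aj} A_i + Z_i^T\alpha_{zj} + \epsilon_{ij}$
* outcome model: $Y_i = \beta_{0j} + \beta_{aj} A_i + \beta_{mj} M_{ij} + Z_i^T\beta_{zj} + \epsilon_{ij}$

Substituting the second into the third gives the exact algebraic identity
$\mu_a = \beta_{aj} + \alpha_{aj}\beta_{mj}$ for least-squares fits
sharing weights and covariates: $\beta_{aj}$ is the direct effect,
$\alpha_{aj}\beta_{mj}$ the indirect effect (IE), and
$100\,\alpha_{aj}\beta_{mj}/\mu_a$ the percent mediated. The package
asserts this identity to $10^{-8}$ on every completed dataset; pooled
estimates may differ only through Rubin-rule averaging. Sobel's
first-order delta-method standard error
$\sqrt{\hat\alpha^2\mathrm{Var}(\hat\beta_m) + \hat\beta_m^2\mathrm{Var}(\hat\alpha)}$
tests each IE (a second-order term is available behind a flag), with
Benjamini–Hochberg correction applied jointly across the 15 mediators.

The multivariate extension replaces the scalar mediator with the vector
$M_i$: a multivariate mediator model yields $\hat\alpha_a$
(equation-by-equation weighted least squares, identical to stacked
single-response fits), an outcome model $Y|M,A,Z$ yields $\hat\beta_m$,
and the global indirect effect is $\hat\alpha_a^T\hat\beta_m$, with
$\hat\beta_a + \hat\alpha_a^T\hat\beta_m$ the total effect. Because the
15 exposures are highly collinear (within-PCB correlations up to ~0.95),
the unpenalized outcome model suffers variance inflation; a ridge penalty
$\lambda\sum_j \beta_{mj}^2$ on the mediator coefficients only — never on
$A$ (that would bias the direct effect) or $Z$ — tames it. Inference for
both uses the nonparametric bootstrap (percentile intervals from order
statistics; sign-based p-values with the +1 continuity correction),
because no analytic ridge inference is agreed upon once $\lambda$ is
cross-validated.

## Survey design

The cohort carries NHANES-style design columns (stratum, PSU, weight).
All single-mediator and summary-score fits are weighted least squares
with Taylor-linearized (sandwich) covariance: estimating-equation scores
$w_ie_ix_i$ are totalled within PSUs, centred within strata, combined
with the $n_h/(n_h-1)$ stratum factor, and sandwiched between
$(X^TWX)^{-1}$ factors. A stratum with a single PSU is a hard error —
silently centring such strata hides design mis-specification. Wald tests
use the standard normal reference by default, with a design-df $t$
reference (PSUs − strata) available; the linearized SEs are validated in
the test suite against a delete-one-PSU jackknife (within 15%) and
against heteroskedasticity-robust sandwich variances when every
observation is its own PSU.

The multivariate OLS/ridge estimators use the survey weights in point
estimation but *not* strata/PSUs in inference, mirroring the practical
limitation that no standard software fits multivariate regression fully
adjusted for the complex design; an optional cluster bootstrap
(resampling PSUs within strata) is provided but off by default.

## Below-LOD imputation

Each chemical's concentration is left-censored at its assay-specific
limit of detection (LOD), with 13–37% non-detects per chemical. Chemicals
with more than 50% below the LOD in either survey cycle are excluded
(`chemical_filter`; exactly 50% is retained). The remainder are multiply
imputed per batch by sequential censored-likelihood regression
(`impute_below_lod`): chemicals are ordered from least to most censored
(ranked in the reference batch), and each chemical's Tobit-type model —
Gaussian density for observed values, Gaussian CDF below the censor point
for flagged values, maximised via the accelerated-failure-time machinery
of `survival` — conditions on log LTL, group, education, age, sex, log
cotinine, blood-composition variables, log lipids, and the previously
imputed log chemicals. Imputations are *draws* from the fitted truncated
normal (never conditional means; multiple imputation must propagate
uncertainty), truncated above at log LOD.

Because each pass redraws values, raw imputed-cell means fluctuate by
Monte Carlo noise; stability is therefore judged on the *fitted* expected
truncated means, with default tolerance 0.02 log units, at least two and
at most four passes. Downstream estimates are combined by Rubin's rules
(between/within variance with Barnard–Rubin degrees of freedom) — the
standard choice, adopted here as the combining rule. An automated
tail-quantile diagnostic (`imputation_diagnostics`) replaces the visual
quality review of the motivating analysis: a chemical is flagged when its
pooled imputed mean falls more than 2 tail-SDs below the tail mean
implied by an intercept-only censored fit, the signature of
systematically too-low draws.

Whether the original imputation models used survey weights is unstated;
the default here is unweighted imputation models.

## Summary scores

Three linear combinations $S_i = \sum_j w_j M_{ij}$ collapse the mixture
into a single mediator that the survey-weighted single-mediator framework
can handle in full:

* **PCA** — first eigenvector of the correlation matrix of the log
  concentrations, computed once on the stacked imputation-completed data,
  sign-oriented so the weight sum is positive. Correlation-scale PCA is
  used because the chemicals live on different concentration scales and
  the uniformly positive correlation block yields an all-positive first
  component.
* **PDM** — the unit-norm direction maximising the mediated effect
  $|\alpha_w\beta_w|$ of the score. Both coefficients have closed forms
  in $w$ after weighted residualization on $(A, Z)$, so the objective
  $|(w^Ta)(w^Tb)|/(w^TCw)$ is optimized by BFGS from 20 random starts
  plus the PCA start; the objective is scale-invariant, so optimization
  is unconstrained and the result normalized. Deterministic under a
  seed.
* **TEQ** — toxic-equivalency weights (potency relative to
  2,3,7,8-TCDD) applied to *natural-scale* concentrations, then
  log-transformed for modelling (potency weighting is defined on
  concentrations; mediators are modelled on the log scale). Chemicals
  without a TEF are excluded. The shipped default table reproduces the
  motivating construction as printed — including TEF 0.030 for PCB 118,
  where the WHO 2005 re-evaluation lists 0.00003 — and a `who2005` table
  ships alongside; the choice only moves the score by a near-constant
  factor for these data. Zero scores are offset by half the smallest
  positive score before logging, with a warning. The displayed weighted
  *sum* is used (a normalizing average would change the score only by a
  positive constant, and the indirect effect is invariant to positive
  rescaling of the weights: $\alpha_w$ scales by $c$ and $\beta_w$ by
  $1/c$).

Subclass sensitivity restricts the PCA score to each chemical class (all
PCBs, non-ortho PCBs, non-dioxin-like PCBs, dioxins, furans) to show
which classes carry the effect.

## E-value

The indirect effect on log LTL converts to an approximate risk ratio by
the standard continuous-outcome rule $RR = \exp(0.91\,\beta/s_Y)$ with
$s_Y$ the analytic-sample SD of log LTL, and the E-value
$RR + \sqrt{RR(RR-1)}$ gives the minimum confounder strength (risk-ratio
scale, both sides) needed to explain the association away; ratios below
one are inverted first. The CI-bound E-value uses the interval endpoint
closer to the null and equals 1 when the interval crosses it. Which
estimate the motivating analysis converted is ambiguous; the default
here is the indirect effect itself, with the mediator–outcome association
variant available by calling `evalue` directly.

## The synthetic cohort

`generate_cohort` draws group membership (Black:White mix 321:930 by
default), covariates, exposures, outcome, censoring, and design:

* **Exposures** — multivariate log-normal per group. The default
  correlation comes from two correlated latent factors (PCB block;
  dioxin/furan block; factor correlation 0.6), giving within-PCB
  correlations ≈ 0.56–0.92, within-dioxin/furan ≈ 0.36–0.61, and
  cross-class ≈ 0.27–0.48 — matching the published ranges (0.51–0.98,
  0.33–0.80, 0.25–0.72) as closely as a two-factor structure allows.
  Group shifts $\alpha_a$ default to 0.1–0.55 log units, largest for the
  PCBs with the largest published group differences.
* **Outcome** — linear in group, mediators, and covariates with Gaussian
  noise (SD 0.20 on the log-LTL scale). Default $\beta_a = 0.033$ and
  $\alpha_a^T\beta_m \approx 0.019$ give a true total effect ≈ 0.052,
  patterned on the published total effect 0.054 with ~35% mediated.
* **Censoring** — LODs are placed at the published per-chemical
  below-LOD quantiles (16.9% for PCB 153 up to 36.9% for the most
  censored furan), per batch, because percent-below-LOD is reported
  rather than LOD values.
* **Design** — participants are dealt into 14 strata × 2 PSUs
  (balanced, so every stratum realizes both PSUs), with log-normal
  weights scaled to a nominal population; an informative-design knob
  couples weights to the outcome residual for robustness studies, off by
  default.
* **Covariates** are generated independently of exposures by default
  (confounding strength is a knob, default 0), so the mediation
  identification assumptions hold by construction and exact
  parameter-recovery tests are meaningful. The joint
  covariate–exposure distribution of the real survey is unknown; this
  independence is a modelling choice, not a data-derived fact. The five
  differential percentages are drawn Dirichlet-style and perturbed by a
  bounded shared deviation so they sum to 100 ± 2 without being exactly
  affinely constrained (which would alias the intercept).

What passing tests on this generator do *not* show: robustness to
exposure–covariate confounding, non-Gaussian exposure tails, informative
censoring (LOD correlated with unmodelled factors), or the oversampling
structure of the real survey — none of which the generator emulates by
default.

## Numerical and design choices

* Single-mediator recovery is exact only when mediators are
  conditionally independent given the group; with correlated mediators
  the single-mediator estimand deliberately differs from the structural
  $\alpha_j\beta_j$ (that difference is the point of the multivariate
  methods). Recovery tests therefore use a diagonal-covariance
  configuration; the ridge recovery test uses the correlated default,
  where the signal lies along the dominant principal direction and
  cross-validated shrinkage leaves it nearly unbiased.
* Ridge `lambda` is re-selected inside each bootstrap replicate by
  default (honest inference); the pipeline driver uses the documented
  fixed-`lambda` fast mode (selected once per imputed dataset) and the
  bootstrap is distributed across imputations (replicates pooled for the
  percentile interval) to keep the full pipeline inside interactive
  runtimes. B defaults to 1000 in the API; the drivers use 200 and the
  calibration tests 100–200 replicates, sizes chosen to keep the
  complete suite within a few minutes on one CPU while leaving binomial
  noise well inside the asserted tolerances.
* Problem sizes used by the validation suite: parameter recovery at
  n = 5000 over 50 replicates; Sobel size at n = 1000 over 500
  replicates; bootstrap coverage at n = 1000, B = 200, 100 replicates;
  the variance-inflation comparison at n = 500 over 50 cohorts with
  equicorrelation 0.95.
* Degenerate inputs are errors, not warnings: all-censored chemicals,
  rank-deficient designs (aliased columns are named), single-PSU strata,
  zero total effects in percent mediated, non-positive-definite exposure
  covariance.
* All randomness flows from named substreams of one master seed
  (simulation, imputation, bootstrap, cross-validation, PDM restarts),
  so partial reruns are reproducible; reruns with identical
  configuration are byte-identical.

## Known limitations

The imputation's sequential schedule (two-plus passes) is a pragmatic
choice; the motivating analysis says "iterative" without a schedule. The
percentile bootstrap can undercover slightly at moderate n. PDM is a
non-convex optimization: multi-start BFGS finds the global optimum
reliably at these dimensions (15 mediators) but carries no guarantee.
The E-value conversion treats log LTL as approximately normal. None of
the multivariate estimators provides design-based variance — the same
limitation the motivating analysis reports — so their intervals describe
the sample, not the survey population.
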