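# popmediate

Mediation analysis of Black/White differences in leukocyte telomere
length (LTL) through correlated persistent organic pollutant (POP)
exposures, in the style of the NHANES 1999–2002 analyses.

Black Americans tend to have *longer* LTL — a biomarker of cellular
aging, measured as a log T/S ratio — than White Americans, despite
carrying more risk factors for short telomeres. Serum POPs (PCBs,
dioxins, furans) are both racially patterned and positively associated
with LTL, making them a candidate environmental explanation.
`popmediate` implements the full analytic chain for quantifying how much
of the group difference is transmitted through 15 correlated serum
chemicals:

* **Single-mediator mediation** — survey-weighted (weights, strata,
  PSUs; Taylor-linearized variance) product-of-coefficients
  decomposition `mu_a = beta_aj + alpha_aj * beta_mj`, Sobel tests with
  Benjamini–Hochberg correction, percent mediated.
* **Censored-data imputation** — chemicals with >50% of values below
  the limit of detection in either survey cycle are excluded; the rest
  are multiply imputed per batch by sequential censored-likelihood
  (Tobit) regression, least-censored first, with Rubin's rules for
  pooling and an automated tail-quality diagnostic.
* **Multivariate mixture mediation** — unpenalized and ridge-penalized
  joint outcome models (`alpha_a' beta_m` global indirect effect) with
  bootstrap percentile inference; the ridge penalty targets variance
  inflation from the collinear exposure block.
* **Summary-score mediators** — first principal component (PCA), first
  principal direction of mediation (PDM), and the WHO toxic-equivalency
  (TEQ) score, each run through the survey-weighted single-mediator
  framework; subclass PCA sensitivity analyses.
* **Sensitivity analyses** — group-by-mediator interaction checks and
  the mediation E-value for unmeasured confounding.
* **A synthetic NHANES-like cohort generator** with known ground-truth
  effects (group exposure shifts, mediator effects, censoring targets,
  stratified two-PSU weighted design), so every stage is validated
  end-to-end without restricted survey data.

The methods vignette (`vignettes/pop-mediation-methods.Rmd`) documents
the models, assumptions, numerical choices, and limitations.

## Worked example

The numbered drivers under `analysis/` run the study end to end on the
default synthetic cohort (n = 1251, the analytic sample size of the
motivating study; 5 imputations; 200 bootstrap replicates):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_impute_below_lod.R
Rscript analysis/03_single_mediator.R
Rscript analysis/04_mixture_models.R
Rscript analysis/05_summary_scores.R
Rscript analysis/06_sensitivity.R
```

`analysis/03_single_mediator.R` prints (abridged):

```
== single-mediator mediation (pooled over 5 imputations) ==
total effect of group on log LTL: 0.0651 (SE 0.0145)

  model    ide    de pct_mediated    p_bh
  PCB74 0.0148 0.050         22.7 4.5e-04
 PCB118 0.0163 0.049         25.0 2.9e-05
 PCB153 0.0178 0.047         27.2 9.9e-05
 PCB187 0.0194 0.046         29.7 9.9e-05
    D03 0.0012 0.064          1.9 3.0e-01
    F03 0.0075 0.058         11.5 6.2e-03
...
decomposition check (max |mu_a - (de + ie)| on one dataset): 1.15e-15
```

Reading the rows: for the PCB 153 analogue, of the total group effect on
log LTL (0.065 on this synthetic draw), 0.0178 flows through that
chemical's exposure difference (27% mediated; BH-adjusted Sobel
p ≈ 1e-4), and the direct plus indirect effects reproduce the total to
machine precision — an exact identity of the nested weighted fits. The
mixture-level drivers then print, for the same cohort:

```
Unpenalized Linear Regression  IE 0.0120  DE 0.0532  %med 18.3  CI (-0.0021, 0.0255)  p 0.104
Ridge Regression               IE 0.0148  DE 0.0503  %med 22.7  CI (0.0066, 0.0234)  p 0.008

true global indirect effect: 0.01925
```

showing the variance-inflation story the methods are built around: with
15 mediators correlated up to ~0.9, the unpenalized interval is wide
enough to cross zero while the ridge interval, at similar point
estimate, excludes it. `analysis/06_sensitivity.R` closes with the
E-value:

```
E-value: 1.37 (CI-bound 1.28)
```

— an unmeasured confounder would need risk-ratio associations of ~1.4
with both the exposure score and LTL to explain the indirect effect
away.

All step computations live in the package (`R/`), so the same functions
are callable directly:

```r
library(popmediate)
sim <- generate_cohort(sim_config(n = 2000, seed = 7))
des <- survey_design(sim$cohort)
tab <- single_mediator_analysis(list(sim$cohort), des, pop_chemicals()$chemical)
mix <- mixture_mediation(sim$cohort, pop_chemicals()$chemical, method = "ridge", lambda = 10)
```

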