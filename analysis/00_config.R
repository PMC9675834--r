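# Shared settings for the analysis drivers. Every script regenerates the
# cohort deterministically from this config, so the steps can be run
# independently or in sequence.
library(popmediate)

MASTER_SEED <- 20220101L
N_COHORT <- 1251L          # analytic sample size of the motivating study
M_IMPUTATIONS <- 5L
B_BOOTSTRAP <- 200L
RESULTS_DIR <- "results"

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

study_sim <- function() sim_config(n = N_COHORT, seed = MASTER_SEED)

study_cohort <- function() generate_cohort(study_sim())

study_imputation <- function(sim = study_cohort()) {
  suppressWarnings(impute_below_lod(
    sim$panel,
    data.frame(Y = sim$cohort$Y, group = sim$cohort$group,
               sim$cohort[, setdiff(pop_covariate_cols(), "cycle")]),
    m = M_IMPUTATIONS, seed = MASTER_SEED + 1L))
}
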