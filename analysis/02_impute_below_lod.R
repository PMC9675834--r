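#!/usr/bin/env Rscript
# Sequential censored-likelihood multiple imputation of the below-LOD
# concentrations, per assay batch, ordered from least to most censored.
# Reports the imputation order, convergence, and the tail-quality
# diagnostic that automates the visual review which excluded two chemicals
# in the motivating analysis.
source("analysis/00_config.R")

sim <- study_cohort()
retained <- chemical_filter(sim$panel)
cat("chemicals retained by the <=50% below-LOD rule:", length(retained), "\n")

iset <- study_imputation(sim)
cat("imputations:", iset$m, " converged:", all(iset$converged), "\n")
cat("imputation order (ascending censoring in batch 1):\n  ",
    paste(iset$imputation_order, collapse = " -> "), "\n\n")

diag <- imputation_diagnostics(iset, sim$panel)
utils::write.csv(diag, file.path(RESULTS_DIR, "imputation_diagnostics.csv"),
                 row.names = FALSE)
cat("tail-quality diagnostic (flagged chemicals would be excluded):\n")
cat("  flagged:", sum(diag$flagged), "of", nrow(diag),
    "chemical-batch cells\n")

# fidelity of the imputations against the pre-censoring truth
err <- vapply(colnames(sim$panel$true_log), function(ch) {
  cells <- sim$panel$below_lod[, ch]
  if (!any(cells)) return(0)
  mean(vapply(iset$panels, function(p) {
    mean(p[cells, ch]) - mean(sim$panel$true_log[cells, ch])
  }, numeric(1)))
}, numeric(1))
cat("mean imputed-minus-true log concentration in censored cells:\n")
print(round(err, 3))
write_imputed_set(iset, file.path(RESULTS_DIR, "imputed"))
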