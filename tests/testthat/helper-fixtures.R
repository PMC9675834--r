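# Shared simulation fixtures. Generation is cheap; each test builds what it
# needs from these configs so nothing binary ships with the package.

# a lean adjustment set used where fit speed matters more than realism
lean_covs <- c("age_std", "age_std_sq", "sex_female")

# parameter-recovery conditions: mediators conditionally independent given
# the group, effects patterned on the published single-mediator magnitudes,
# no censoring (so the single-mediator estimand equals alpha_j * beta_j)
recovery_config <- function(n = 5000, seed = 1) {
  sim_config(n = n, chemical_corr = diag(15),
             lod_quantiles = rep(0, 15), seed = seed)
}

# complete null: no direct effect, no group-mediator shifts, no mediator
# effect on the outcome
null_config <- function(n = 1000, seed = 1) {
  sim_config(n = n, mediator_group_shifts = rep(0, 15),
             mediator_effects = rep(0, 15), direct_effect = 0,
             lod_quantiles = rep(0, 15), seed = seed)
}

# highly collinear mediators (equicorrelation 0.95) for the
# variance-inflation comparison
collinear_config <- function(n = 500, seed = 1) {
  cc <- matrix(0.95, 15, 15); diag(cc) <- 1
  sim_config(n = n, chemical_corr = cc, lod_quantiles = rep(0, 15),
             seed = seed)
}

imputation_covariates <- function(cohort) {
  data.frame(Y = cohort$Y, group = cohort$group,
             cohort[, setdiff(pop_covariate_cols(), "cycle")])
}

# tiny hand-built censoring panel: flags set to exact per-batch proportions
toy_panel <- function(props, n_per_batch = 40, seed = 99) {
  set.seed(seed)
  chems <- rownames(props)
  n <- 2 * n_per_batch
  batch <- rep(1:2, each = n_per_batch)
  logm <- matrix(rnorm(n * length(chems), 3, 1), n,
                 dimnames = list(NULL, chems))
  below <- matrix(FALSE, n, length(chems), dimnames = list(NULL, chems))
  lod <- matrix(NA_real_, length(chems), 2,
                dimnames = list(chems, c("1", "2")))
  for (b in 1:2) {
    rows <- which(batch == b)
    for (ch in chems) {
      k <- round(props[ch, b] * n_per_batch)
      ord <- rows[order(logm[rows, ch])]
      if (k > 0) below[ord[seq_len(k)], ch] <- TRUE
      lod[ch, b] <- if (k > 0) exp(logm[ord[k], ch] + 1e-6) else
        exp(min(logm[rows, ch]) - 1)
    }
  }
  conc <- exp(logm)
  conc[below] <- NA_real_
  lod_panel(conc, below, lod, batch, true_log = logm)
}
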