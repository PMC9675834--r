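chems <- pop_chemicals()$chemical

test_that("multivariate mediator fit equals stacked single-response fits", {
  sim <- generate_cohort(sim_config(n = 400, seed = 31))
  d <- sim$cohort
  mv <- fit_multivariate_mediator_model(d, chems)
  for (j in c("PCB74", "D05", "F08")) {
    single <- fit_wls(model.matrix(reformulate(c("group", pop_covariate_cols())), d),
                      d[[j]], d$weight)
    expect_equal(mv$alpha_a[[j]], single$coefficients[["group"]],
                 tolerance = 1e-10)
  }
  expect_lt(max(abs(mv$alpha_a - sim$config$mediator_group_shifts)), 0.6)
})

test_that("zero-shift configurations give a near-zero alpha vector", {
  sim <- generate_cohort(sim_config(n = 5000,
                                    mediator_group_shifts = rep(0, 15),
                                    lod_quantiles = rep(0, 15), seed = 32))
  mv <- fit_multivariate_mediator_model(sim$cohort, chems)
  expect_lt(max(abs(mv$alpha_a)), 0.12)
})

test_that("ridge at lambda = 0 equals the unpenalized fit and limits behave", {
  sim <- generate_cohort(sim_config(n = 400, seed = 33))
  d <- sim$cohort
  f0 <- fit_joint_outcome_model(d, chems, lambda = 0)
  ols <- fit_wls(model.matrix(reformulate(c("group", pop_covariate_cols(), chems)), d),
                 d$Y, d$weight)
  expect_equal(f0$beta_a, ols$coefficients[["group"]], tolerance = 1e-8)
  expect_equal(unname(f0$beta_m), unname(ols$coefficients[chems]),
               tolerance = 1e-8)

  finf <- fit_joint_outcome_model(d, chems, lambda = 1e12)
  expect_lt(max(abs(finf$beta_m)), 1e-8)
  tot <- fit_wls(model.matrix(reformulate(c("group", pop_covariate_cols())), d),
                 d$Y, d$weight)
  expect_equal(finf$beta_a, tot$coefficients[["group"]], tolerance = 1e-6)

  expect_error(fit_joint_outcome_model(d, chems, lambda = -1), "non-negative")
})

test_that("ridge solution matches the data-augmentation oracle on a tiny fixture", {
  set.seed(34)
  d <- data.frame(group = c(0, 0, 0, 1, 1, 1),
                  z = rnorm(6), m1 = rnorm(6), m2 = rnorm(6),
                  Y = rnorm(6), weight = runif(6, 0.5, 2))
  for (lam in c(0.3, 2, 25)) {
    f <- fit_joint_outcome_model(d, c("m1", "m2"), covariates = "z",
                                 lambda = lam)
    orc <- oracle_ridge_augmented(d, c("m1", "m2"), "z", d$weight, lam)
    expect_equal(unname(f$beta_m), unname(orc), tolerance = 1e-8)
  }
})

test_that("ridge indirect effect is continuous in lambda at zero", {
  sim <- generate_cohort(sim_config(n = 500, seed = 35))
  d <- sim$cohort
  ie0 <- mixture_mediation(d, chems, method = "ols")$ie
  ie_eps <- mixture_mediation(d, chems, method = "ridge", lambda = 1e-10)$ie
  expect_lt(abs(ie0 - ie_eps), 1e-6)
})

test_that("cross-validation selects large penalties for pure noise and small for signal", {
  lams_noise <- vapply(1:5, function(s) {
    sim <- generate_cohort(sim_config(n = 400, mediator_effects = rep(0, 15),
                                      direct_effect = 0, seed = 5000 + s))
    d <- sim$cohort
    d$Y <- rnorm(nrow(d)) # outcome unrelated to everything
    log10(as.numeric(select_ridge_lambda(d, chems, cv_seed = s)))
  }, numeric(1))
  expect_gt(median(lams_noise), 2) # upper half of the 10^-2..10^6 grid

  sim <- generate_cohort(sim_config(n = 4000, chemical_corr = diag(15),
                                    mediator_effects = c(0.1, 0.1, rep(0, 13)),
                                    lod_quantiles = rep(0, 15), seed = 36))
  lam <- as.numeric(select_ridge_lambda(sim$cohort, chems, cv_seed = 1))
  fr <- fit_joint_outcome_model(sim$cohort, chems, lambda = lam)
  f0 <- fit_joint_outcome_model(sim$cohort, chems, lambda = 0)
  expect_lt(max(abs(fr$beta_m[1:2] / f0$beta_m[1:2] - 1)), 0.05)

  l1 <- select_ridge_lambda(sim$cohort, chems, cv_seed = 9)
  l2 <- select_ridge_lambda(sim$cohort, chems, cv_seed = 9)
  expect_identical(as.numeric(l1), as.numeric(l2))
})

test_that("the global indirect effect is the inner product with exact decomposition", {
  expect_equal(global_indirect(c(0.5, 0.5), c(0.2, -0.2)), 0)
  expect_equal(global_indirect(rep(0.3, 4), rep(0, 4)), 0)
  expect_error(global_indirect(1:3, 1:2), "length")

  sim <- generate_cohort(sim_config(n = 600, seed = 37))
  mm <- mixture_mediation(sim$cohort, chems, method = "ols")
  tot <- fit_total_effect(sim$cohort, survey_design(sim$cohort))
  expect_equal(mm$beta_a + mm$ie, tot$coefficients[["group"]],
               tolerance = 1e-8)
})

test_that("bootstrap collapses to a point on a zero-noise outcome", {
  set.seed(38)
  n <- 120
  z <- rnorm(n); g <- rep(0:1, each = n / 2)
  d <- data.frame(group = g, z = z,
                  m1 = 1 + 0.5 * g + rnorm(n),
                  m2 = 2 - 0.3 * g + rnorm(n),
                  weight = 1)
  # Y an exact linear function with zero residual noise and no mediator
  # contribution: every resampled outcome fit recovers beta_m = 0 exactly,
  # so every replicate's indirect effect is exactly zero
  d$Y <- 0.3 * g + 0.1 * z
  bt <- bootstrap_mediation(d, c("m1", "m2"), covariates = "z",
                            method = "ols", B = 60, seed = 1)
  expect_lt(diff(bt$ci), 1e-10)
  expect_equal(bt$estimate, 0, tolerance = 1e-10)
  expect_error(bootstrap_mediation(d, c("m1", "m2"), covariates = "z",
                                   B = 10), "at least 50")
})

test_that("bootstrap p-values and CIs are order statistics with continuity correction", {
  sim <- generate_cohort(sim_config(n = 600, seed = 39))
  bt <- bootstrap_mediation(sim$cohort, chems, method = "ols", B = 80,
                            seed = 2)
  expect_equal(bt$ci[1], sort(bt$replicates)[ceiling(0.025 * bt$B)])
  k_le <- sum(bt$replicates <= 0); k_ge <- sum(bt$replicates >= 0)
  expect_equal(bt$p, min(1, 2 * min((1 + k_le), (1 + k_ge)) / (bt$B + 1)))
  bt2 <- bootstrap_mediation(sim$cohort, chems, method = "ols", B = 80,
                             seed = 2)
  expect_identical(bt$replicates, bt2$replicates)
})
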