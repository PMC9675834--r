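test_that("chemical filter excludes on >threshold censoring in any batch", {
  props <- rbind(A = c(0.60, 0.10), B = c(0.50, 0.50), C = c(0.10, 0.20))
  panel <- toy_panel(props)
  kept <- chemical_filter(panel)
  expect_false("A" %in% kept)      # 60% in one batch is enough to exclude
  expect_true("B" %in% kept)       # exactly 50% in both batches is retained
  expect_true("C" %in% kept)
  expect_equal(dim(attr(kept, "proportions")), c(3L, 2L))
  expect_error(chemical_filter(panel, threshold = 0), "threshold")
  expect_error(chemical_filter(panel, threshold = 1.5), "threshold")
})

test_that("imputation order ranks ascending censoring with stable ties", {
  props <- rbind(c1 = c(0.30, 0.10), c2 = c(0.10, 0.30), c3 = c(0.20, 0.20))
  panel <- toy_panel(props)
  expect_identical(rank_by_censoring(panel, 1), c("c2", "c3", "c1"))
  expect_identical(rank_by_censoring(panel, 2), c("c1", "c3", "c2"))
  tie <- toy_panel(rbind(x = c(0.25, 0.1), y = c(0.25, 0.1)))
  expect_identical(rank_by_censoring(tie, 1), c("x", "y"))
  expect_error(rank_by_censoring(panel, 9), "not present")
  # published-analogue ordering: PCB153 (16.9%) precedes PCB74 (30.5%)
  sim <- generate_cohort(sim_config(n = 2000, seed = 2))
  ord <- rank_by_censoring(sim$panel)
  expect_lt(which(ord == "PCB153"), which(ord == "PCB74"))
})

test_that("censored MLE reduces to least squares without censoring", {
  set.seed(3)
  n <- 200
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- 1 + 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(n, 0, 0.7)
  cf <- fit_censored_regression(y, X, rep(FALSE, n))
  ols <- unname(coef(lm(y ~ X)))
  expect_equal(unname(cf$coefficients), ols, tolerance = 1e-8)
})

test_that("censored MLE matches a direct likelihood optimiser and recovers truth", {
  set.seed(4)
  n <- 600
  X <- cbind(x = rnorm(n))
  y <- 0.5 + 0.8 * X[, 1] + rnorm(n)
  cp <- rep(quantile(y, 0.3), n)
  cens <- y < cp
  cf <- fit_censored_regression(y, X, cens, cp)
  or <- oracle_censored_mle(y, X, cens, cp)
  expect_equal(unname(cf$coefficients), unname(or$coefficients),
               tolerance = 1e-4)
  expect_equal(cf$sd, or$sd, tolerance = 1e-3)

  # intercept-only Monte-Carlo recovery: mean 0, sd 1, 30% censored
  est <- t(vapply(1:12, function(s) {
    set.seed(100 + s)
    z <- rnorm(2000)
    cp <- rep(qnorm(0.3), 2000)
    cens <- z < cp
    cf <- fit_censored_regression(z, matrix(numeric(0), 2000, 0), cens, cp)
    c(cf$coefficients[1], cf$sd)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1])), 0.05)
  expect_lt(abs(mean(est[, 2]) - 1), 0.05)
})

test_that("censored MLE rejects degenerate inputs", {
  set.seed(5)
  X <- cbind(a = rnorm(20), b = 0)
  X[, 2] <- 2 * X[, 1]
  expect_error(fit_censored_regression(rnorm(20), X, rep(FALSE, 20)),
               "rank deficient")
  expect_error(fit_censored_regression(rnorm(20), X[, 1, drop = FALSE],
                                       rep(TRUE, 20), rep(0, 20)),
               "all observations censored")
})

test_that("imputation preserves observed cells and censoring bounds", {
  sim <- generate_cohort(sim_config(n = 500, seed = 11))
  iset <- suppressWarnings(
    impute_below_lod(sim$panel, imputation_covariates(sim$cohort),
                     m = 3, seed = 21))
  obs_log <- log(sim$panel$concentrations)
  lod_log <- log(sim$panel$lod)
  for (p in iset$panels) {
    expect_identical(p[!sim$panel$below_lod],
                     obs_log[!sim$panel$below_lod])
    for (ch in colnames(p)) {
      i <- which(sim$panel$below_lod[, ch])
      if (length(i))
        expect_true(all(p[i, ch] <=
                          lod_log[ch, as.character(sim$panel$batch[i])] + 1e-12))
    }
  }
  # imputations differ from each other in the censored cells
  cens <- which(sim$panel$below_lod)
  expect_false(identical(iset$panels[[1]][cens], iset$panels[[2]][cens]))
})

test_that("panels without censoring impute to identical copies", {
  sim <- generate_cohort(sim_config(n = 200, lod_quantiles = rep(0, 15),
                                    seed = 12))
  iset <- impute_below_lod(sim$panel, imputation_covariates(sim$cohort),
                           m = 4, seed = 1)
  expect_length(iset$panels, 4)
  expect_identical(iset$panels[[1]], iset$panels[[4]])
  expect_identical(iset$panels[[1]], sim$panel$true_log)
})

test_that("imputation recovers the generating moments of a censored bivariate panel", {
  # two correlated log-normal chemicals, ~25% censoring each
  cc <- diag(15); cc[1, 2] <- cc[2, 1] <- 0.6
  qs <- rep(0, 15); qs[1:2] <- 0.25
  sim <- generate_cohort(sim_config(n = 2000, chemical_corr = cc,
                                    lod_quantiles = qs, seed = 13))
  iset <- suppressWarnings(
    impute_below_lod(sim$panel, imputation_covariates(sim$cohort),
                     m = 3, seed = 31))
  truth <- sim$panel$true_log
  pooled_mean <- rowMeans(vapply(iset$panels,
                                 function(p) colMeans(p[, 1:2]), numeric(2)))
  expect_lt(max(abs(pooled_mean - colMeans(truth[, 1:2]))), 0.05)
  pooled_cor <- mean(vapply(iset$panels, function(p) cor(p[, 1], p[, 2]),
                            numeric(1)))
  expect_lt(abs(pooled_cor - cor(truth[, 1], truth[, 2])), 0.05)
})

test_that("the tail diagnostic flags systematically low imputations only", {
  sim <- generate_cohort(sim_config(n = 600, seed = 14))
  iset <- suppressWarnings(
    impute_below_lod(sim$panel, imputation_covariates(sim$cohort),
                     m = 2, seed = 41))
  d <- imputation_diagnostics(iset, sim$panel)
  expect_true(all(!d$flagged))
  bad <- iset
  i <- which(sim$panel$below_lod[, "PCB153"])
  bad$panels <- lapply(bad$panels, function(p) {
    p[i, "PCB153"] <- p[i, "PCB153"] - 4
    p
  })
  db <- imputation_diagnostics(bad, sim$panel)
  expect_true(all(db$flagged[db$chemical == "PCB153"]))
  expect_true(all(!db$flagged[db$chemical != "PCB153"]))
})

test_that("Rubin pooling matches hand-computed combining rules", {
  p <- pool_rubin(c(1.0, 1.2), c(0.04, 0.04))
  expect_equal(p$estimate, 1.1)
  expect_equal(p$variance, 0.04 + 1.5 * 0.02)
  p1 <- pool_rubin(0.5, 0.09)
  expect_equal(p1$variance, 0.09)
  pid <- pool_rubin(rep(2, 10), rep(0.01, 10))
  expect_equal(pid$se, sqrt(0.01))
  expect_equal(pid$df, Inf)
  pbr <- pool_rubin(c(1, 1.3, 0.9), c(0.02, 0.03, 0.025), df_com = 50)
  expect_lt(pbr$df, 50)
  expect_error(pool_rubin(1:3, 1:2), "differ in length")
})

test_that("light censoring leaves downstream mediation essentially unchanged", {
  sim <- generate_cohort(sim_config(n = 1500, lod_quantiles = rep(0.01, 15),
                                    seed = 15))
  des <- survey_design(sim$cohort)
  complete <- sim$cohort
  complete[, colnames(sim$panel$true_log)] <- sim$panel$true_log
  ref <- single_mediator_analysis(list(complete), des, "PCB153")
  iset <- suppressWarnings(
    impute_below_lod(sim$panel, imputation_covariates(sim$cohort),
                     m = 3, seed = 51))
  imp <- single_mediator_analysis(completed_cohorts(sim$cohort, iset),
                                  des, "PCB153")
  expect_lt(abs(imp$ide - ref$ide), 0.005)
})
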