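test_that("weighted least squares solves the weighted normal equations", {
  X <- cbind(1, x = c(0.5, 1, 2, 3, 4.5))
  y <- 2 * X[, 2]
  f <- fit_wls(X, y)
  expect_equal(unname(f$coefficients), c(0, 2), tolerance = 1e-12)
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-12)

  set.seed(1)
  w <- runif(5, 0.2, 3)
  y2 <- y + rnorm(5)
  f2 <- fit_wls(X, y2, w)
  expect_equal(unname(f2$coefficients), unname(oracle_wls(X, y2, w)),
               tolerance = 1e-10)

  # duplicating a row equals doubling its weight
  Xd <- rbind(X, X[3, ]); yd <- c(y2, y2[3])
  wd <- c(w, w[3]); w2 <- w; w2[3] <- 2 * w[3]
  expect_equal(fit_wls(Xd, yd, wd)$coefficients,
               fit_wls(X, y2, w2)$coefficients, tolerance = 1e-10)

  # unit weights reproduce ordinary least squares
  set.seed(2)
  Xn <- cbind(1, a = rnorm(50), b = rnorm(50))
  yn <- rnorm(50)
  expect_equal(unname(fit_wls(Xn, yn)$coefficients),
               unname(coef(lm(yn ~ Xn[, -1]))), tolerance = 1e-10)

  Xr <- cbind(1, u = 1:10, v = 2 * (1:10))
  expect_error(fit_wls(Xr, rnorm(10)), "aliased.*v")
})

test_that("linearized variance matches a robust sandwich when PSUs are singletons", {
  skip_if_not_installed("sandwich")
  set.seed(3)
  n <- 400
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n) * (1 + 0.5 * abs(x))
  d <- data.frame(y = y, x = x, stratum = 1, psu = seq_len(n), weight = 1)
  des <- survey_design(d)
  f <- taylor_variance(fit_wls(cbind(1, x = x), y), des)
  lmfit <- lm(y ~ x)
  vhc <- sandwich::vcovHC(lmfit, type = "HC0")
  expect_lt(max(abs(diag(f$vcov) / diag(vhc) - 1)), 0.10)
})

test_that("duplicated PSUs contribute zero between-PSU variance", {
  set.seed(4)
  n <- 60
  x <- rnorm(n); y <- 1 + x + rnorm(n)
  # stratum of two identical PSUs: differences cancel exactly
  d <- data.frame(stratum = rep(1:10, each = 6),
                  psu = rep(rep(1:2, each = 3), 10))
  X <- cbind(1, x = rep(x[1:30], each = 2)[1:60])
  yy <- rep(y[1:30], each = 2)[1:60]
  # construct exact duplicate PSUs: copy psu 1 rows into psu 2
  for (h in 1:10) {
    r1 <- which(d$stratum == h & d$psu == 1)
    r2 <- which(d$stratum == h & d$psu == 2)
    X[r2, ] <- X[r1, ]
    yy[r2] <- yy[r1]
  }
  d$weight <- 1
  des <- survey_design(d)
  f <- taylor_variance(fit_wls(X, yy), des)
  expect_equal(max(abs(f$vcov)), 0, tolerance = 1e-20)
})

test_that("linearized SEs agree with a delete-one-PSU jackknife on 30x2 designs", {
  set.seed(5)
  n <- 600
  d <- data.frame(stratum = rep(1:30, each = 20),
                  psu = rep(rep(1:2, each = 10), 30))
  x <- rnorm(n)
  cluster_effect <- rnorm(60, 0, 0.3)[(d$stratum - 1) * 2 + d$psu]
  y <- 1 + 0.4 * x + cluster_effect + rnorm(n)
  d$weight <- runif(n, 0.5, 2)
  des <- survey_design(d)
  X <- cbind(1, x = x)
  f <- taylor_variance(fit_wls(X, y, d$weight), des)
  se_lin <- sqrt(diag(f$vcov))[["x"]]
  se_jk <- oracle_jackknife_se(X, y, d$weight, d$stratum, d$psu, "x")
  expect_lt(abs(se_lin / se_jk - 1), 0.15)
})

test_that("design variance is invariant to rescaling the weights", {
  sim <- generate_cohort(sim_config(n = 400, seed = 6))
  d <- sim$cohort
  f1 <- fit_total_effect(d, survey_design(d), lean_covs)
  d2 <- d; d2$weight <- d$weight * 7.3
  f2 <- fit_total_effect(d2, survey_design(d2), lean_covs)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$vcov, f2$vcov, tolerance = 1e-8)
})

test_that("single-PSU strata are a hard error", {
  d <- data.frame(stratum = c(1, 1, 2), psu = c(1, 2, 1), weight = 1)
  expect_error(survey_design(d), "single PSU")
  expect_error(survey_design(data.frame(stratum = 1:2, psu = c(1, 1),
                                        weight = c(1, -1))),
               "strictly positive")
})

test_that("Wald tests use the normal reference and guard degenerate SEs", {
  f <- list(coefficients = c(a = 0, b = 1.96, z = 1),
            vcov = diag(c(1, 1, 0))^2)
  dimnames(f$vcov) <- list(c("a", "b", "z"), c("a", "b", "z"))
  class(f) <- "wls_fit"
  expect_equal(wald_test(f, "a")$p, 1)
  expect_equal(wald_test(f, "b")$p, 0.05, tolerance = 1e-3)
  expect_error(wald_test(f, "z"), "zero or undefined")
  tt <- wald_test(f, "b", df = 10)
  expect_gt(tt$p, 0.05)
})

test_that("design-based intervals achieve near-nominal coverage under an ignorable design", {
  truth <- generate_cohort(recovery_config(n = 100, seed = 1))$truth$true_total
  # 14 strata x 2 PSUs -> 14 design df; the CI uses the design-df t reference
  tq <- qt(0.975, df = 14)
  hits <- vapply(1:200, function(s) {
    sim <- generate_cohort(recovery_config(n = 1000, seed = 500 + s))
    f <- fit_total_effect(sim$cohort, survey_design(sim$cohort), lean_covs)
    w <- wald_test(f, "group", df = 14)
    abs(w$estimate - truth) <= tq * w$se
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})
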