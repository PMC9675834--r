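test_that("PCA weights are the leading correlation eigenvector, unit norm, sign-oriented", {
  set.seed(41)
  z <- rnorm(300)
  two <- cbind(a = 2 + 3 * z, b = -1 + 0.5 * z) # correlation exactly 1
  w2 <- pca_weights(two)
  expect_equal(unname(w2$weights), c(1, 1) / sqrt(2), tolerance = 1e-10)

  m <- generate_cohort(sim_config(n = 1000, seed = 41))$panel$true_log
  w <- pca_weights(m[, 1:4])
  expect_equal(sum(w$weights^2), 1, tolerance = 1e-12)
  expect_gt(sum(w$weights), 0)
  pi_w <- oracle_power_iteration(cor(m[, 1:4]))
  expect_equal(unname(w$weights), pi_w, tolerance = 1e-6)

  bad <- m[, 1:3]; bad[, 2] <- 7
  expect_error(pca_weights(bad), "zero-variance")
  expect_error(pca_weights(m, subset = c("PCB74", "nope")), "not in panel")
})

test_that("PDM weights maximise the mediated-effect objective", {
  sim <- generate_cohort(sim_config(n = 1500, seed = 42))
  d <- sim$cohort
  des <- survey_design(d)
  chems <- pop_chemicals()$chemical
  w <- pdm_weights(d, chems, n_starts = 8, seed = 1)
  expect_equal(sum(w$weights^2), 1, tolerance = 1e-10)

  # definitional dominance: the optimum beats the PCA direction under the
  # same survey-weighted score fits the optimizer targets
  obj <- function(v) {
    dd <- d; dd$.s <- drop(as.matrix(d[, chems]) %*% v)
    af <- fit_mediator_model(dd, des, ".s")
    bf <- fit_outcome_model(dd, des, ".s")
    abs(af$coefficients[["group"]] * bf$coefficients[[".s"]])
  }
  wp <- pca_weights(as.matrix(d[, chems]))
  expect_gte(obj(as.numeric(w$weights)) + 1e-10, obj(as.numeric(wp$weights)))
  expect_equal(obj(as.numeric(w$weights)), attr(w, "objective"),
               tolerance = 1e-6)

  expect_equal(unname(pdm_weights(d, "PCB74")$weights), 1)

  w2 <- pdm_weights(d, chems, n_starts = 8, seed = 1)
  expect_identical(w$weights, w2$weights)
})

test_that("PDM concentrates on the only mediating chemical", {
  shifts <- c(0.8, rep(0, 14))
  effects <- c(0.05, rep(0, 14))
  sim <- generate_cohort(sim_config(n = 5000, chemical_corr = diag(15),
                                    mediator_group_shifts = shifts,
                                    mediator_effects = effects,
                                    lod_quantiles = rep(0, 15), seed = 43))
  w <- pdm_weights(sim$cohort, pop_chemicals()$chemical, n_starts = 10,
                   seed = 2)
  expect_gt(abs(w$weights[["PCB74"]]), 0.9)
})

test_that("TEQ scores are potency-weighted sums over TEF-bearing chemicals", {
  chems <- pop_chemicals()$chemical
  unit <- matrix(1, 2, 15, dimnames = list(NULL, chems))
  s <- teq_score(unit)
  expect_equal(as.numeric(s), c(0.6803, 0.6803))
  expect_equal(as.numeric(teq_score(2 * unit)), 2 * as.numeric(s))

  # excluded chemicals do not contribute
  unit2 <- unit; unit2[, "PCB153"] <- 1e6
  expect_equal(as.numeric(teq_score(unit2)), as.numeric(s))

  expect_error(teq_score(unit, data.frame(chemical = "PCB118", tef = -1)),
               "negative TEF")
  zero <- matrix(0, 3, 15, dimnames = list(NULL, chems))
  zero[1, ] <- 1
  dz <- as.data.frame(log(pmax(zero, 1e-300)))
  expect_warning(log_with_offset(as.numeric(teq_score(zero))), "offset")

  who <- tef_table("who2005")
  expect_equal(who$tef[who$chemical == "PCB118"], 3e-5)
  expect_equal(tef_table()$tef[tef_table()$chemical == "PCB118"], 0.03)
})

test_that("indicator weights reduce score mediation to the single-mediator result", {
  sim <- generate_cohort(sim_config(n = 700, seed = 44))
  des <- survey_design(sim$cohort)
  wobj <- popmediate:::score_weights(setNames(1, "PCB118"), "pca")
  sm <- score_mediation(list(sim$cohort), des, wobj)
  single <- single_mediator_analysis(list(sim$cohort), des, "PCB118")
  expect_equal(sm$ide, single$ide, tolerance = 1e-10)
  expect_equal(sm$de, single$de, tolerance = 1e-10)
  expect_equal(sm$p, single$p, tolerance = 1e-10)
})

test_that("score mediation is invariant to positive rescaling of the weights", {
  sim <- generate_cohort(sim_config(n = 700, seed = 45))
  des <- survey_design(sim$cohort)
  chems <- pop_chemicals()$chemical
  w1 <- pca_weights(as.matrix(sim$cohort[, chems]))
  w5 <- w1; w5$weights <- 5 * w1$weights; class(w5) <- "score_weights"
  # bypass the unit-norm constructor to test the invariance directly
  sm1 <- score_mediation(list(sim$cohort), des, w1)
  sm5 <- score_mediation(list(sim$cohort), des, w5)
  expect_equal(sm1$ide, sm5$ide, tolerance = 1e-8)
  expect_equal(sm1$p, sm5$p, tolerance = 1e-6)
  # decomposition identity holds for the score model too
  tot <- fit_total_effect(sim$cohort, des)
  expect_equal(sm1$ide + sm1$de, tot$coefficients[["group"]],
               tolerance = 1e-8)
})

test_that("subclass PCA mediation isolates the classes carrying the signal", {
  sub <- pop_subclasses()
  expect_length(sub$non_ortho, 2)
  expect_length(sub$pcb, 9)

  # signal only in the PCB class
  shifts <- ifelse(pop_chemicals()$class == "pcb", 0.6, 0)
  effects <- ifelse(pop_chemicals()$class == "pcb", 0.006, 0)
  sim <- generate_cohort(sim_config(n = 3000, mediator_group_shifts = shifts,
                                    mediator_effects = effects,
                                    lod_quantiles = rep(0, 15), seed = 46))
  des <- survey_design(sim$cohort)
  tab <- subclass_pca_mediation(list(sim$cohort), des)
  expect_equal(nrow(tab), 5)
  expect_lt(tab$p[tab$model == "PCA: pcb"], 0.05)
  expect_gt(tab$p[tab$model == "PCA: dioxin"], 0.05)
  wts <- attr(tab, "weights")
  expect_equal(abs(unname(wts$non_ortho$weights)), rep(1 / sqrt(2), 2),
               tolerance = 1e-6)

  one <- subclass_pca_mediation(list(sim$cohort), des,
                                class_map = list(only = "PCB153"))
  single <- single_mediator_analysis(list(sim$cohort), des, "PCB153")
  expect_equal(one$ide, single$ide, tolerance = 1e-10)
  expect_error(subclass_pca_mediation(list(sim$cohort), des,
                                      class_map = list(x = character(0))),
               "empty subclass")
})
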