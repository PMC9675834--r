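#' Total-effect model Y|A,Z
#'
#' Survey-weighted regression of log LTL on the group indicator and the
#' adjustment covariates; the group coefficient is the total effect
#' `mu_a` with its design-based standard error.
#'
#' @param data cohort data frame (columns `Y`, `group`, covariates, design).
#' @param design a [survey_design()] spec, or `NULL` for an unweighted fit.
#' @param covariates adjustment covariate column names.
#' @return A `wls_fit` labelled `"Y|A,Z"`.
#' @export
fit_total_effect <- function(data, design = NULL,
                             covariates = pop_covariate_cols()) {
  form <- stats::reformulate(c("group", covariates), response = "Y")
  fit_survey_lm(form, data, design, model_label = "Y|A,Z")
}

#' Mediator model M_j|A,Z
#'
#' Survey-weighted regression of one log-scale mediator on group and
#' covariates; the group coefficient is `alpha_aj`, the group difference in
#' that exposure.
#'
#' @inheritParams fit_total_effect
#' @param mediator mediator column name.
#' @return A `wls_fit` labelled `"M|A,Z"`.
#' @export
fit_mediator_model <- function(data, design = NULL, mediator,
                               covariates = pop_covariate_cols()) {
  if (length(unique(data$group)) < 2)
    stop("group indicator is constant: no exposure contrast to estimate")
  form <- stats::reformulate(c("group", covariates), response = mediator)
  fit_survey_lm(form, data, design, model_label = paste0(mediator, "|A,Z"))
}

#' Outcome model Y|M_j,A,Z
#'
#' Survey-weighted regression of log LTL on group, one mediator, and
#' covariates; the group coefficient is the direct effect `beta_aj` and the
#' mediator coefficient is `beta_mj`.
#'
#' @inheritParams fit_mediator_model
#' @return A `wls_fit` labelled `"Y|M,A,Z"`.
#' @export
fit_outcome_model <- function(data, design = NULL, mediator,
                              covariates = pop_covariate_cols()) {
  form <- stats::reformulate(c("group", mediator, covariates), response = "Y")
  fit_survey_lm(form, data, design, model_label = paste0("Y|", mediator, ",A,Z"))
}

#' Product-of-coefficients indirect effect with Sobel inference
#'
#' `IE = alpha_a * beta_m` from an M|A,Z fit and a Y|M,A,Z fit on the same
#' data and design. The first-order Sobel (delta-method) standard error is
#' `sqrt(alpha^2 Var(beta_m) + beta_m^2 Var(alpha))`; the second-order term
#' `Var(alpha) Var(beta_m)` can be added via `second_order = TRUE`.
#'
#' @param alpha_fit the mediator-model fit.
#' @param beta_fit the outcome-model fit.
#' @param mediator mediator name (coefficient in `beta_fit`).
#' @param second_order include the second-order variance term.
#' @return List with `ie`, `se`, `statistic`, `p`, `ci` (95% Wald),
#'   `alpha`, `beta_m`, `direct` (`beta_a` from the outcome model), and
#'   their variances.
#' @export
indirect_effect <- function(alpha_fit, beta_fit, mediator,
                            second_order = FALSE) {
  a <- alpha_fit$coefficients["group"]
  va <- diag(alpha_fit$vcov)["group"]
  b <- beta_fit$coefficients[mediator]
  vb <- diag(beta_fit$vcov)[mediator]
  if (any(!is.finite(c(va, vb)))) stop("missing coefficient variances")
  ie <- unname(a * b)
  v <- unname(a^2 * vb + b^2 * va + if (second_order) va * vb else 0)
  se <- sqrt(v)
  z <- if (ie == 0 && se == 0) 0 else ie / se
  p <- 2 * stats::pnorm(-abs(z))
  list(ie = ie, se = se, statistic = z, p = p,
       ci = ie + c(-1, 1) * stats::qnorm(0.975) * se,
       alpha = unname(a), var_alpha = unname(va),
       beta_m = unname(b), var_beta_m = unname(vb),
       direct = unname(beta_fit$coefficients["group"]),
       var_direct = unname(diag(beta_fit$vcov)["group"]))
}

#' Percent of the total effect that is mediated
#'
#' `100 * ie / total`. Values outside [0, 100] are legitimate (inconsistent
#' mediation, where direct and indirect effects oppose) and are flagged via
#' the `"inconsistent"` attribute rather than truncated.
#'
#' @param ie indirect effect.
#' @param total total effect; must be non-zero.
#' @return Percent mediated.
#' @export
percent_mediated <- function(ie, total) {
  if (any(total == 0)) stop("total effect is zero: percent mediated undefined")
  pm <- 100 * ie / total
  attr(pm, "inconsistent") <- pm < 0 | pm > 100
  pm
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]) with
#' input validation; adjusted p-values are monotone and never smaller than
#' the raw ones.
#'
#' @param pvalues raw p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Group-by-mediator interaction sensitivity check
#'
#' Refits the outcome model with an `A x M_j` product term and reports the
#' Wald test of the interaction coefficient. A clearly non-null interaction
#' signals that the no-interaction mean structure assumed by the
#' product-of-coefficients decomposition is suspect for that mediator.
#'
#' @inheritParams fit_outcome_model
#' @return List with `coefficient`, `se`, `statistic`, `p`.
#' @export
interaction_sensitivity <- function(data, design = NULL, mediator,
                                    covariates = pop_covariate_cols()) {
  term <- paste0("group:", mediator)
  form <- stats::reformulate(c("group", mediator, term, covariates),
                             response = "Y")
  fit <- fit_survey_lm(form, data, design,
                       model_label = paste0("Y|", mediator, ",A,AxM,Z"))
  wt <- wald_test(fit, term)
  list(coefficient = wt$estimate, se = wt$se, statistic = wt$statistic,
       p = wt$p)
}

#' Completed cohort datasets from an imputation set
#'
#' Returns one cohort data frame per imputation with the mediator columns
#' replaced by the imputed log-scale panel; with `iset = NULL` the cohort is
#' returned as a single complete dataset.
#'
#' @param cohort cohort data frame.
#' @param iset an [impute_below_lod()] result, or `NULL`.
#' @return List of data frames.
#' @export
completed_cohorts <- function(cohort, iset = NULL) {
  if (is.null(iset)) return(list(cohort))
  stopifnot(inherits(iset, "imputed_set"))
  lapply(iset$panels, function(p) {
    out <- cohort
    out[, colnames(p)] <- p
    out
  })
}

#' Single-mediator mediation analysis across imputations
#'
#' For each mediator, fits the survey-weighted M|A,Z and Y|M,A,Z models on
#' every completed dataset, forms the Sobel indirect effect per dataset, and
#' pools across imputations by Rubin's rules (the total-effect model does
#' not involve the mediators and is fitted once). Percent mediated is
#' computed from the pooled point estimates; Benjamini-Hochberg adjustment
#' is applied jointly across the supplied mediators.
#'
#' @param datasets list of completed cohort data frames (see
#'   [completed_cohorts()]).
#' @param design a [survey_design()] built from the cohort (design columns
#'   are identical across imputations), or `NULL`.
#' @param mediators mediator column names.
#' @param covariates adjustment covariates.
#' @return Data frame with one row per mediator: `model`, `ide`, `ide_se`,
#'   `de`, `total`, `pct_mediated`, `ci_lower`, `ci_upper`, `p`, `p_bh`.
#'   The shared pooled total effect and its SE are attached as attributes
#'   `"total_effect"` and `"total_se"`.
#' @export
single_mediator_analysis <- function(datasets, design = NULL,
                                     mediators,
                                     covariates = pop_covariate_cols()) {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  m <- length(datasets)
  tot_fit <- fit_total_effect(datasets[[1]], design, covariates)
  tot <- wald_test(tot_fit, "group")

  rows <- lapply(mediators, function(j) {
    per <- lapply(datasets, function(d) {
      af <- fit_mediator_model(d, design, j, covariates)
      bf <- fit_outcome_model(d, design, j, covariates)
      indirect_effect(af, bf, j)
    })
    ie_pool <- pool_rubin(vapply(per, `[[`, numeric(1), "ie"),
                          vapply(per, function(x) x$se^2, numeric(1)))
    de_pool <- pool_rubin(vapply(per, `[[`, numeric(1), "direct"),
                          vapply(per, `[[`, numeric(1), "var_direct"))
    q <- if (is.finite(ie_pool$df)) stats::qt(0.975, ie_pool$df) else stats::qnorm(0.975)
    z <- ie_pool$estimate / ie_pool$se
    p <- if (is.finite(ie_pool$df)) 2 * stats::pt(-abs(z), ie_pool$df) else 2 * stats::pnorm(-abs(z))
    data.frame(model = j, ide = ie_pool$estimate, ide_se = ie_pool$se,
               de = de_pool$estimate,
               total = tot$estimate,
               pct_mediated = as.numeric(percent_mediated(ie_pool$estimate,
                                                          tot$estimate)),
               ci_lower = ie_pool$estimate - q * ie_pool$se,
               ci_upper = ie_pool$estimate + q * ie_pool$se,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p)
  attr(out, "total_effect") <- tot$estimate
  attr(out, "total_se") <- tot$se
  out
}

#' Exact decomposition check for nested weighted fits
#'
#' On a single completed dataset, the total-effect group coefficient equals
#' the direct effect plus the product-of-coefficients indirect effect —
#' an algebraic identity of nested weighted least-squares fits sharing
#' weights and covariates. Returns the worst absolute violation across
#' mediators, which should be at numerical noise level.
#'
#' @inheritParams single_mediator_analysis
#' @param data one completed cohort data frame.
#' @return Maximum absolute `mu_a - (beta_aj + alpha_aj * beta_mj)`.
#' @export
check_decomposition <- function(data, design = NULL, mediators,
                                covariates = pop_covariate_cols()) {
  mu <- fit_total_effect(data, design, covariates)$coefficients["group"]
  errs <- vapply(mediators, function(j) {
    af <- fit_mediator_model(data, design, j, covariates)
    bf <- fit_outcome_model(data, design, j, covariates)
    abs(mu - (bf$coefficients["group"] +
                af$coefficients["group"] * bf$coefficients[j]))
  }, numeric(1))
  max(errs)
}
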