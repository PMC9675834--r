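#' Which estimators honor the complex survey design?
#'
#' The single-mediator and summary-score estimators run through the
#' survey-weighted single-mediator framework (weights, strata, PSUs); the
#' multivariate OLS and ridge estimators use the survey weights in point
#' estimation only, with bootstrap inference that ignores strata/PSUs.
#'
#' @return Named logical vector over the estimator roster.
#' @export
estimator_design_aware <- function() {
  c(single = TRUE, ols = FALSE, ridge = FALSE,
    pca = TRUE, pdm = TRUE, teq = TRUE, `subclass-pca` = TRUE)
}

#' Pipeline configuration
#'
#' @param input `"simulate"` or `"csv"`.
#' @param sim a [sim_config()] (simulate mode).
#' @param cohort_csv path to a cohort table (csv mode; complete log-scale
#'   exposure columns, covariates, and design columns as documented in
#'   [validate_cohort()]).
#' @param estimators subset of `c("single", "ols", "ridge", "pca", "pdm",
#'   "teq", "subclass-pca")`.
#' @param m number of imputations.
#' @param B bootstrap replicates for the multivariate estimators.
#' @param cv_folds ridge cross-validation folds.
#' @param seed master seed; named substreams (imputation, bootstrap,
#'   cross-validation, PDM restarts) are derived from it.
#' @param out_dir output directory for the result tables and manifest.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = c("simulate", "csv"), sim = sim_config(),
                            cohort_csv = NULL,
                            estimators = c("single", "ols", "ridge", "pca",
                                           "pdm", "teq", "subclass-pca"),
                            m = 10, B = 1000, cv_folds = 5, seed = 1L,
                            out_dir = NULL) {
  input <- match.arg(input)
  known <- names(estimator_design_aware())
  bad <- setdiff(estimators, known)
  if (length(bad)) stop("unknown estimator(s): ", paste(bad, collapse = ", "))
  if (input == "csv" && is.null(cohort_csv)) stop("csv mode needs cohort_csv")
  structure(list(input = input, sim = sim, cohort_csv = cohort_csv,
                 estimators = estimators, m = m, B = B, cv_folds = cv_folds,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate a user-supplied cohort table
#'
#' Checks for the outcome, group, covariate and exposure columns the
#' estimators need; unknown columns are ignored with a warning. Returns the
#' cohort with `educ` and `cycle` coerced to factors.
#'
#' @param cohort data frame.
#' @param mediators expected exposure column names.
#' @return The validated cohort.
#' @export
validate_cohort <- function(cohort, mediators = pop_chemicals()$chemical) {
  need <- c("Y", "group", pop_covariate_cols(), mediators)
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("cohort lacks required column(s): ", paste(missing, collapse = ", "))
  known <- c("participant_id", need, "stratum", "psu", "weight")
  extra <- setdiff(names(cohort), known)
  if (length(extra))
    warning("ignoring unknown cohort column(s): ", paste(extra, collapse = ", "))
  cohort$educ <- factor(cohort$educ)
  cohort$cycle <- factor(cohort$cycle)
  if (!all(cohort$group %in% 0:1)) stop("group must be binary 0/1")
  cohort
}

seed_stream <- function(seed, stream) {
  offsets <- c(simulate = 0L, imputation = 1000L, bootstrap = 2000L,
               cv = 3000L, pdm = 4000L)
  (seed + offsets[[stream]]) %% .Machine$integer.max
}

#' Run the full mediation pipeline
#'
#' simulate (or load) -> censoring filter -> sequential censored-likelihood
#' multiple imputation -> single-mediator, multivariate (OLS/ridge with
#' bootstrap), and summary-score (PCA/PDM/TEQ) mediation -> subclass PCA and
#' interaction/E-value sensitivity -> report tables. When `out_dir` is set,
#' writes `mediation_results.csv` (per-model indirect/direct effects,
#' percent mediated, CI, p, with BH columns for single-mediator rows and a
#' design-aware flag per row), `score_weights.csv` (chemical x method),
#' `subclass_results.csv`, and `manifest.json` (seeds, sizes, estimator
#' design flags, and the effect truth when simulating).
#'
#' @param config a [pipeline_config()].
#' @return List with `results` (main table), `weights` (weight table),
#'   `subclass`, `sensitivity` (interaction + E-value for the PCA score),
#'   `truth` (simulate mode), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  est <- config$estimators
  aware <- estimator_design_aware()

  if (config$input == "simulate") {
    simcfg <- config$sim
    simcfg$seed <- as.integer(seed_stream(config$seed, "simulate") +
                                simcfg$seed)
    sim <- generate_cohort(simcfg)
    cohort <- sim$cohort
    panel <- sim$panel
    truth <- sim$truth
  } else {
    cohort <- validate_cohort(utils::read.csv(config$cohort_csv))
    panel <- NULL
    truth <- NULL
  }

  has_design <- all(c("stratum", "psu", "weight") %in% names(cohort))
  design <- if (has_design) survey_design(cohort) else NULL
  if (!has_design) {
    refuse <- intersect(est, names(aware)[aware])
    if (length(refuse)) {
      warning("no survey design columns: refusing design-aware estimator(s) ",
              paste(refuse, collapse = ", "),
              "; multivariate estimators proceed without design-based inference")
      est <- setdiff(est, refuse)
    }
    if (!length(est)) stop("no runnable estimators without design columns")
  }

  if (!is.null(panel) && any(panel$below_lod)) {
    retained <- chemical_filter(panel)
    keep <- colnames(panel$concentrations) %in% retained
    panel <- lod_panel(panel$concentrations[, retained, drop = FALSE],
                       panel$below_lod[, retained, drop = FALSE],
                       panel$lod[retained, , drop = FALSE], panel$batch,
                       true_log = panel$true_log[, retained, drop = FALSE])
    cov_cols <- setdiff(pop_covariate_cols(), "cycle")
    imp_covs <- data.frame(Y = cohort$Y, group = cohort$group,
                           cohort[, cov_cols])
    iset <- impute_below_lod(panel, imp_covs, m = config$m,
                             seed = seed_stream(config$seed, "imputation"))
    mediators <- retained
  } else {
    mediators <- intersect(pop_chemicals()$chemical, names(cohort))
    iset <- NULL
  }
  datasets <- completed_cohorts(cohort, iset)
  stacked_logm <- do.call(rbind, lapply(datasets, function(d) {
    as.matrix(d[, mediators, drop = FALSE])
  }))

  results <- list()
  weights_tab <- data.frame(chemical = mediators)
  sensitivity <- list()
  subclass <- NULL

  if ("single" %in% est) {
    results$single <- single_mediator_analysis(datasets, design, mediators)
  }

  for (method in intersect(c("ols", "ridge"), est)) {
    per <- lapply(seq_along(datasets), function(l) {
      lam <- if (method == "ridge") {
        as.numeric(select_ridge_lambda(datasets[[l]], mediators,
                                       cv_folds = config$cv_folds,
                                       cv_seed = seed_stream(config$seed, "cv") + l))
      } else 0
      boot <- bootstrap_mediation(datasets[[l]], mediators, method = method,
                                  lambda = lam,
                                  B = max(50, ceiling(config$B / length(datasets))),
                                  seed = seed_stream(config$seed, "bootstrap") + l)
      boot
    })
    reps <- unlist(lapply(per, `[[`, "replicates"))
    bb <- length(reps)
    ie <- mean(vapply(per, `[[`, numeric(1), "estimate"))
    de <- mean(vapply(per, `[[`, numeric(1), "beta_a"))
    ci <- unname(stats::quantile(reps, c(0.025, 0.975), type = 1))
    p <- min(1, 2 * min((1 + sum(reps <= 0)) / (bb + 1),
                        (1 + sum(reps >= 0)) / (bb + 1)))
    results[[method]] <- data.frame(
      model = if (method == "ols") "Unpenalized Linear Regression" else "Ridge Regression",
      ide = ie, ide_se = stats::sd(reps), de = de, total = ie + de,
      pct_mediated = 100 * ie / (ie + de),
      ci_lower = ci[1], ci_upper = ci[2], p = p, p_bh = NA_real_,
      stringsAsFactors = FALSE)
  }

  score_objs <- list()
  if ("pca" %in% est) score_objs$pca <- pca_weights(stacked_logm)
  if ("pdm" %in% est) {
    score_objs$pdm <- pdm_weights(datasets[[1]], mediators,
                                  seed = seed_stream(config$seed, "pdm"))
  }
  if ("teq" %in% est) {
    s <- teq_score(exp(stacked_logm))
    score_objs$teq <- attr(s, "weights")
  }
  for (nm in names(score_objs)) {
    lab <- c(pca = "PCA: All Toxicants", pdm = "PDM", teq = "TEQ")[[nm]]
    results[[nm]] <- score_mediation(datasets, design, score_objs[[nm]],
                                     label = lab)
    wcol <- stats::setNames(rep(NA_real_, length(mediators)), mediators)
    wcol[score_objs[[nm]]$chemicals] <- score_objs[[nm]]$weights
    weights_tab[[nm]] <- unname(wcol)
  }

  if ("pca" %in% est) {
    scored <- lapply(datasets, append_score, wobj = score_objs$pca)
    ints <- vapply(scored, function(d) {
      interaction_sensitivity(d, design, ".score")$p
    }, numeric(1))
    sensitivity$pca_interaction_p_median <- stats::median(ints)
    row <- results$pca
    sd_y <- stats::sd(cohort$Y)
    ev <- mediation_evalue(row$ide, c(row$ci_lower, row$ci_upper), sd_y)
    sensitivity$evalue <- ev
  }

  if ("subclass-pca" %in% est) {
    subclass <- subclass_pca_mediation(datasets, design)
  }

  tab <- do.call(rbind, unname(results))
  rownames(tab) <- NULL
  flags <- vapply(names(results), function(nm) unname(aware[[nm]]), logical(1))
  tab$design_aware <- rep(flags, vapply(results, nrow, integer(1)))

  manifest <- list(
    seed = config$seed,
    m = if (is.null(iset)) 1L else iset$m,
    B = config$B,
    n = nrow(cohort),
    estimators = est,
    design_aware = as.list(aware[intersect(names(aware), est)]),
    mediators = mediators,
    total_effect = attr(results$single, "total_effect"),
    package_version = as.character(utils::packageVersion("popmediate"))
  )
  if (!is.null(truth)) {
    manifest$effect_truth <- list(
      true_direct = truth$true_direct,
      true_global_indirect = truth$true_global_indirect,
      true_total = truth$true_total)
  }

  out <- list(results = tab, weights = weights_tab, subclass = subclass,
              sensitivity = sensitivity, truth = truth, manifest = manifest,
              datasets = datasets, design = design, mediators = mediators)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(config$out_dir, "mediation_results.csv"),
                     row.names = FALSE)
    utils::write.csv(weights_tab,
                     file.path(config$out_dir, "score_weights.csv"),
                     row.names = FALSE)
    if (!is.null(subclass))
      utils::write.csv(subclass,
                       file.path(config$out_dir, "subclass_results.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
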