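#' Default covariate columns used for adjustment in all mediation models
#'
#' Standardized age (linear and quadratic), sex, educational attainment
#' (5 levels), log serum cotinine, log total lipids, white blood cell count,
#' the five differential percentages, and survey cycle (batch).
#'
#' @return Character vector of cohort column names.
#' @export
pop_covariate_cols <- function() {
  c("age_std", "age_std_sq", "sex_female", "educ", "log_cotinine",
    "log_lipids", "wbc", "pct_lymph", "pct_neut", "pct_eos",
    "pct_baso", "pct_mono", "cycle")
}

default_chemical_profile <- function() {
  ch <- pop_chemicals()
  # two correlated latent factors: one for the PCB block, one for
  # dioxins/furans; factor correlation 0.6 gives cross-block correlations
  # in the 0.25-0.5 range while keeping within-PCB correlations high
  load_pcb <- c(0.80, 0.92, 0.78, 0.95, 0.96, 0.76, 0.90, 0.88, 0.85)
  load_df  <- c(0.70, 0.75, 0.65, 0.80, 0.72, 0.60)
  loadings <- cbind(
    f1 = c(load_pcb, rep(0, 6)),
    f2 = c(rep(0, 9), load_df)
  )
  phi <- matrix(c(1, 0.6, 0.6, 1), 2)
  corr <- loadings %*% phi %*% t(loadings)
  diag(corr) <- 1
  dimnames(corr) <- list(ch$chemical, ch$chemical)
  list(
    names = ch$chemical,
    log_means = c(2.6, 3.0, 3.4, 3.6, 3.9, 3.5, 3.0, 3.6, 2.8,
                  4.0, 4.6, 5.8, 2.2, 2.0, 2.6),
    log_sds = c(rep(0.8, 9), rep(0.7, 6)),
    corr = corr,
    group_shifts = c(0.45, 0.50, 0.40, 0.50, 0.50, 0.20, 0.40, 0.25, 0.55,
                     0.10, 0.20, 0.20, 0.25, 0.20, 0.15),
    mediator_effects = c(0.004, 0.005, 0.003, 0.006, 0.006, 0.001,
                         0.004, 0.004, 0.007, rep(0.001, 6)),
    lod_quantiles = ch$below_lod
  )
}

#' Configuration for the synthetic NHANES-like cohort generator
#'
#' Assembles and validates all knobs of the data-generating process: exposure
#' means/covariance by group, outcome coefficients, censoring targets,
#' covariate distributions, and the stratified two-PSU survey design. The
#' defaults emulate the published study conditions: 15 log-normal chemicals
#' with within-PCB correlations roughly 0.5-0.95, cross-class correlations
#' roughly 0.25-0.5, per-chemical below-LOD fractions between 13% and 37%,
#' a Black:White mix of 321:930, and a total race effect on log LTL near
#' 0.054 of which roughly 0.021 flows through the chemicals.
#'
#' @param n number of participants.
#' @param p_group probability of membership in the exposure group
#'   (`group = 1`, the Black-respondent analogue).
#' @param chemical_names character vector of mediator names.
#' @param chemical_log_means baseline (group 0) log-scale means.
#' @param chemical_log_sds log-scale standard deviations.
#' @param chemical_corr positive-definite correlation matrix of the
#'   log-scale exposures.
#' @param mediator_group_shifts additive group shifts of the log exposures
#'   (the structural `alpha_a` vector).
#' @param direct_effect direct effect of group on log LTL (`beta_a`).
#' @param mediator_effects outcome coefficients of the log exposures
#'   (`beta_m`).
#' @param outcome_intercept,outcome_sigma intercept and residual SD of the
#'   log-LTL model.
#' @param covariate_effects named list of outcome coefficients for the
#'   numeric covariates plus `educ` (length-5 per-level effects) and
#'   `cycle2` (batch-2 offset).
#' @param interaction_effects optional named vector of group-by-mediator
#'   interaction coefficients (default none), used for interaction
#'   sensitivity power studies.
#' @param confounding strength of a shared age effect on all log exposures
#'   (0 = covariates independent of exposures, the default, under which the
#'   mediation identification assumptions hold by construction).
#' @param lod_quantiles per-chemical target censoring proportions; either a
#'   vector (same in each batch) or a matrix with one column per batch.
#'   LODs are placed at these quantiles of the realized per-batch
#'   distributions, since the source tables report percent-below-LOD rather
#'   than LOD values.
#' @param p_batch2 probability of assay batch (survey cycle) 2.
#' @param n_strata,psus_per_stratum survey design shape (balanced
#'   assignment; at least 2 PSUs per stratum is required for variance
#'   estimation).
#' @param weight_sdlog log-normal spread of the survey weights.
#' @param population nominal population total the weights are scaled to.
#' @param informative_design strength of dependence between weights and the
#'   outcome residual (0 = ignorable design, the default).
#' @param seed integer seed; the full cohort is bit-reproducible given the
#'   config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 1251,
                       p_group = 321 / 1251,
                       chemical_names = NULL,
                       chemical_log_means = NULL,
                       chemical_log_sds = NULL,
                       chemical_corr = NULL,
                       mediator_group_shifts = NULL,
                       direct_effect = 0.033,
                       mediator_effects = NULL,
                       outcome_intercept = 0.01,
                       outcome_sigma = 0.20,
                       covariate_effects = NULL,
                       interaction_effects = NULL,
                       confounding = 0,
                       lod_quantiles = NULL,
                       p_batch2 = 750 / 1251,
                       n_strata = 14,
                       psus_per_stratum = 2,
                       weight_sdlog = 0.5,
                       population = 2.2e8,
                       informative_design = 0,
                       seed = 1L) {
  prof <- default_chemical_profile()
  if (is.null(chemical_names)) chemical_names <- prof$names
  j <- length(chemical_names)
  if (is.null(chemical_log_means)) {
    chemical_log_means <- if (j == length(prof$log_means)) prof$log_means else rep(3, j)
  }
  if (is.null(chemical_log_sds)) {
    chemical_log_sds <- if (j == length(prof$log_sds)) prof$log_sds else rep(0.8, j)
  }
  if (is.null(chemical_corr)) {
    chemical_corr <- if (j == nrow(prof$corr)) prof$corr else diag(j)
  }
  if (is.null(mediator_group_shifts)) {
    mediator_group_shifts <- if (j == length(prof$group_shifts)) prof$group_shifts else rep(0, j)
  }
  if (is.null(mediator_effects)) {
    mediator_effects <- if (j == length(prof$mediator_effects)) prof$mediator_effects else rep(0, j)
  }
  if (is.null(lod_quantiles)) {
    lod_quantiles <- if (j == length(prof$lod_quantiles)) prof$lod_quantiles else rep(0, j)
  }
  if (is.vector(lod_quantiles)) {
    lod_quantiles <- cbind(batch1 = lod_quantiles, batch2 = lod_quantiles)
  }
  if (is.null(covariate_effects)) {
    covariate_effects <- list(
      age_std = -0.030, age_std_sq = 0.010, sex_female = 0.010,
      log_cotinine = -0.002, log_lipids = 0.020, wbc = -0.002,
      pct_lymph = 0, pct_neut = 0, pct_eos = 0, pct_baso = 0, pct_mono = 0,
      educ = c(0, 0.005, 0.010, 0.010, 0.015), cycle2 = -0.010
    )
  }
  cfg <- list(
    n = as.integer(n), p_group = p_group, chemical_names = chemical_names,
    chemical_log_means = chemical_log_means, chemical_log_sds = chemical_log_sds,
    chemical_corr = chemical_corr,
    mediator_group_shifts = mediator_group_shifts,
    direct_effect = direct_effect, mediator_effects = mediator_effects,
    outcome_intercept = outcome_intercept, outcome_sigma = outcome_sigma,
    covariate_effects = covariate_effects,
    interaction_effects = interaction_effects,
    confounding = confounding, lod_quantiles = lod_quantiles,
    p_batch2 = p_batch2, n_strata = as.integer(n_strata),
    psus_per_stratum = as.integer(psus_per_stratum),
    weight_sdlog = weight_sdlog, population = population,
    informative_design = informative_design, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  j <- length(cfg$chemical_names)
  if (cfg$p_group <= 0 || cfg$p_group >= 1) stop("p_group must lie in (0, 1)")
  if (cfg$psus_per_stratum < 2)
    stop("psus_per_stratum must be >= 2: with a single PSU per stratum, ",
         "between-PSU variance estimation is impossible")
  if (cfg$n < cfg$n_strata * cfg$psus_per_stratum)
    stop("n too small to realize every PSU in every stratum")
  for (nm in c("chemical_log_means", "chemical_log_sds",
               "mediator_group_shifts", "mediator_effects")) {
    if (length(cfg[[nm]]) != j) stop(nm, " must have length ", j)
  }
  cc <- cfg$chemical_corr
  if (!isTRUE(all.equal(cc, t(cc), tolerance = 1e-10)))
    stop("chemical_corr must be symmetric")
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("chemical_corr is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")")
  if (nrow(cfg$lod_quantiles) != j)
    stop("lod_quantiles must have one row per chemical")
  if (any(cfg$lod_quantiles < 0) || any(cfg$lod_quantiles >= 1))
    stop("lod_quantiles must lie in [0, 1)")
  invisible(cfg)
}

rmvnorm_chol <- function(n, mu, sigma) {
  p <- length(mu)
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% chol(sigma), 2, mu, `+`)
}

# split a bounded total deviation across the five differential percentages
# so they sum to 100 within +/- 2 without being affinely constrained
cell_percentages <- function(n) {
  means <- c(29.78, 58.43, 2.92, 0.67, 8.25)
  k <- 25 # dirichlet concentration: SDs of a few percentage points
  g <- matrix(stats::rgamma(n * 5, shape = rep(means / sum(means) * k, each = n)), n, 5)
  p <- 100 * g / rowSums(g)
  total_dev <- stats::runif(n, -1.8, 1.8)
  share <- matrix(stats::rgamma(n * 5, shape = 1), n, 5)
  share <- share / rowSums(share)
  p <- p + total_dev * share
  colnames(p) <- c("pct_lymph", "pct_neut", "pct_eos", "pct_baso", "pct_mono")
  p
}

#' Generate a synthetic NHANES-like cohort with known mediation structure
#'
#' Draws group membership, covariates, log-scale exposures (multivariate
#' normal per group), a log-LTL outcome from the linear structural model, a
#' stratified two-PSU-per-stratum weighted design, and a censoring panel in
#' which each chemical's limit of detection is placed at its configured
#' per-batch quantile. The pre-censoring exposure truth is retained in the
#' panel so imputation can be validated against it.
#'
#' @param config a [sim_config()].
#' @return A list of class `pop_cohort_sim` with elements `cohort` (data
#'   frame; one row per participant with outcome `Y`, `group`, covariates,
#'   log-scale exposure columns, `stratum`, `psu`, `weight`), `panel` (a
#'   [lod_panel()] holding natural-scale concentrations, censoring flags and
#'   LODs), and `truth` (an `effect_truth` list with the structural direct,
#'   per-mediator indirect, global indirect and total effects).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n
  j <- length(config$chemical_names)

  group <- stats::rbinom(n, 1, config$p_group)

  age <- pmin(pmax(stats::rnorm(n, 50.8, 19.3), 20), 90)
  age_std <- (age - 50) / 20
  covars <- data.frame(
    age_std = age_std,
    age_std_sq = age_std^2,
    sex_female = stats::rbinom(n, 1, 0.537),
    educ = factor(sample(1:5, n, replace = TRUE,
                         prob = c(81, 215, 324, 338, 293) / 1251),
                  levels = 1:5),
    log_cotinine = stats::rnorm(n, -0.55, 3.80),
    log_lipids = stats::rnorm(n, 6.48, 0.22),
    wbc = pmax(stats::rnorm(n, 7.18, 2.15), 2)
  )
  covars <- cbind(covars, as.data.frame(cell_percentages(n)))
  covars$cycle <- factor(1 + stats::rbinom(n, 1, config$p_batch2), levels = 1:2)

  sigma <- diag(config$chemical_log_sds) %*% config$chemical_corr %*%
    diag(config$chemical_log_sds)
  log_m <- rmvnorm_chol(n, rep(0, j), sigma)
  log_m <- log_m +
    outer(rep(1, n), config$chemical_log_means) +
    outer(group, config$mediator_group_shifts) +
    config$confounding * outer(age_std, rep(1, j))
  colnames(log_m) <- config$chemical_names

  ce <- config$covariate_effects
  lin_z <- config$outcome_intercept +
    ce$age_std * covars$age_std + ce$age_std_sq * covars$age_std_sq +
    ce$sex_female * covars$sex_female +
    ce$log_cotinine * covars$log_cotinine +
    ce$log_lipids * covars$log_lipids + ce$wbc * covars$wbc +
    ce$pct_lymph * covars$pct_lymph + ce$pct_neut * covars$pct_neut +
    ce$pct_eos * covars$pct_eos + ce$pct_baso * covars$pct_baso +
    ce$pct_mono * covars$pct_mono +
    ce$educ[as.integer(covars$educ)] +
    ce$cycle2 * (covars$cycle == "2")
  eps <- stats::rnorm(n, 0, config$outcome_sigma)
  y <- lin_z + config$direct_effect * group +
    drop(log_m %*% config$mediator_effects) + eps
  if (!is.null(config$interaction_effects)) {
    ie <- config$interaction_effects
    for (nm in names(ie)) y <- y + ie[[nm]] * group * log_m[, nm]
  }

  # balanced stratified design: shuffle, then deal participants into
  # strata and PSUs so every stratum realizes all its PSUs
  ord <- sample.int(n)
  stratum <- integer(n)
  stratum[ord] <- rep_len(seq_len(config$n_strata), n)
  psu <- integer(n)
  for (h in seq_len(config$n_strata)) {
    idx <- which(stratum == h)
    psu[idx[sample.int(length(idx))]] <- rep_len(seq_len(config$psus_per_stratum),
                                                 length(idx))
  }
  w <- stats::rlnorm(n, 0, config$weight_sdlog)
  if (config$informative_design != 0) {
    w <- w * exp(config$informative_design * scale(eps)[, 1])
  }
  w <- w * config$population / sum(w)

  cohort <- data.frame(participant_id = seq_len(n), group = group, Y = y,
                       covars, log_m, check.names = FALSE)
  cohort$stratum <- stratum
  cohort$psu <- psu
  cohort$weight <- w

  batch <- as.integer(covars$cycle)
  lod_log <- matrix(NA_real_, j, 2,
                    dimnames = list(config$chemical_names, c("1", "2")))
  below <- matrix(FALSE, n, j, dimnames = list(NULL, config$chemical_names))
  for (b in 1:2) {
    rows <- which(batch == b)
    for (k in seq_len(j)) {
      q <- config$lod_quantiles[k, b]
      if (q > 0) {
        lod_log[k, b] <- stats::quantile(log_m[rows, k], probs = q,
                                         names = FALSE, type = 7)
        below[rows, k] <- log_m[rows, k] < lod_log[k, b]
      } else {
        lod_log[k, b] <- NA_real_ # chemical fully observed in this batch
      }
    }
  }
  conc <- exp(log_m)
  conc[below] <- NA_real_
  panel <- lod_panel(concentrations = conc, below_lod = below,
                     lod = exp(lod_log), batch = batch,
                     true_log = log_m)

  per_mediator <- config$mediator_group_shifts * config$mediator_effects
  names(per_mediator) <- config$chemical_names
  truth <- structure(list(
    true_direct = config$direct_effect,
    true_indirect_per_mediator = per_mediator,
    true_global_indirect = sum(per_mediator),
    true_total = config$direct_effect + sum(per_mediator),
    true_percent_mediated =
      100 * sum(per_mediator) / (config$direct_effect + sum(per_mediator))
  ), class = "effect_truth")

  structure(list(cohort = cohort, panel = panel, truth = truth,
                 config = config),
            class = "pop_cohort_sim")
}

#' Pairwise correlations of log-scale exposures
#'
#' Computes the correlation matrix of the log concentrations, either from a
#' panel's pre-censoring truth or from any completed (imputed) matrix, and
#' reports the within- and cross-class off-diagonal ranges used to check the
#' generator against the published correlation structure.
#'
#' @param x a [lod_panel()] carrying a complete `true_log` matrix, or a
#'   numeric matrix of log concentrations.
#' @return The correlation matrix, with attribute `"ranges"` summarising
#'   min/max off-diagonals by chemical-class pair when the column names match
#'   the standard roster. Constant columns are flagged with a warning and
#'   their correlations set to `NA`.
#' @export
empirical_correlations <- function(x) {
  m <- if (inherits(x, "lod_panel")) {
    if (is.null(x$true_log)) stop("panel has no complete log matrix; supply an imputed matrix")
    x$true_log
  } else as.matrix(x)
  sds <- apply(m, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(stats::cor(m))
  if (any(const)) {
    warning("constant column(s): ", paste(colnames(m)[const], collapse = ", "),
            "; correlations undefined (NA)")
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
    diag(r)[!const] <- 1
  }
  ch <- pop_chemicals()
  if (all(colnames(m) %in% ch$chemical)) {
    cls <- ch$class[match(colnames(m), ch$chemical)]
    cls[cls %in% c("dioxin", "furan")] <- "df"
    pairs <- list(pcb_pcb = c("pcb", "pcb"), df_df = c("df", "df"),
                  pcb_df = c("pcb", "df"))
    ranges <- lapply(pairs, function(p) {
      vals <- r[cls == p[1], cls == p[2], drop = FALSE]
      if (p[1] == p[2]) vals <- vals[lower.tri(vals)]
      if (!length(vals) || all(is.na(vals))) return(c(NA_real_, NA_real_))
      range(vals, na.rm = TRUE)
    })
    attr(r, "ranges") <- ranges
  }
  r
}

#' Write a simulated cohort to plain-text files
#'
#' Writes the cohort table as CSV, the effect truth as a flat `key: value`
#' file, and the LOD metadata (chemical, batch, LOD, percent below) as CSV.
#'
#' @param sim a `pop_cohort_sim` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "pop_cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cohort = file.path(dir, "cohort.csv"),
    truth = file.path(dir, "effect_truth.yaml"),
    lod = file.path(dir, "lod_metadata.csv")
  )
  utils::write.csv(sim$cohort, paths[["cohort"]], row.names = FALSE)
  tr <- sim$truth
  flat <- c(
    list(true_direct = tr$true_direct,
         true_global_indirect = tr$true_global_indirect,
         true_total = tr$true_total,
         true_percent_mediated = tr$true_percent_mediated),
    as.list(stats::setNames(tr$true_indirect_per_mediator,
                            paste0("true_indirect_",
                                   names(tr$true_indirect_per_mediator))))
  )
  yaml::write_yaml(flat, paths[["truth"]])
  utils::write.csv(lod_metadata(sim$panel), paths[["lod"]], row.names = FALSE)
  invisible(paths)
}

#' Read a generator configuration from a YAML file
#'
#' Scalar and vector fields are passed straight to [sim_config()];
#' `chemical_corr` may be given as a flattened row-major matrix.
#'
#' @param path YAML file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$chemical_corr) && !is.matrix(raw$chemical_corr)) {
    jj <- sqrt(length(unlist(raw$chemical_corr)))
    raw$chemical_corr <- matrix(unlist(raw$chemical_corr), jj, jj, byrow = TRUE)
  }
  if (!is.null(raw$lod_quantiles) && is.list(raw$lod_quantiles)) {
    raw$lod_quantiles <- do.call(cbind, raw$lod_quantiles)
  }
  do.call(sim_config, raw)
}
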