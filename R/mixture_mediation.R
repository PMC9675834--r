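#' Multivariate mediator model M|A,Z
#'
#' Equation-by-equation weighted least squares for all mediators jointly
#' (with identical predictors this equals the multivariate-regression MLE
#' per response, and stacking single-response fits exactly). Returns the
#' group-coefficient vector `alpha_a`.
#'
#' @param data cohort data frame.
#' @param mediators mediator column names.
#' @param covariates adjustment covariates.
#' @param weights observation weights (defaults to the cohort `weight`
#'   column if present, else unit weights). Survey weights enter point
#'   estimation only; the multivariate methods do not use strata/PSU
#'   information for inference.
#' @return List with `alpha_a` (named vector), `coefficients` (predictors x
#'   mediators matrix), and `residuals`.
#' @export
fit_multivariate_mediator_model <- function(data, mediators,
                                            covariates = pop_covariate_cols(),
                                            weights = NULL) {
  w <- mixture_weights(data, weights)
  form <- stats::reformulate(c("group", covariates))
  X <- stats::model.matrix(form, data)
  qx <- qr(X * sqrt(w))
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient mediator-model design; aliased: ",
         paste(aliased, collapse = ", "))
  }
  M <- as.matrix(data[, mediators, drop = FALSE])
  xtwx_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  B <- xtwx_inv %*% crossprod(X, w * M)
  rownames(B) <- colnames(X)
  list(alpha_a = stats::setNames(B["group", ], mediators),
       coefficients = B, residuals = M - X %*% B)
}

mixture_weights <- function(data, weights) {
  if (!is.null(weights)) return(weights)
  if (!is.null(data$weight)) data$weight else rep(1, nrow(data))
}

#' Joint outcome model Y|M,A,Z, optionally ridge-penalized
#'
#' Minimises the weighted residual sum of squares plus
#' `lambda * sum(beta_penalized^2)`, where only the mediator coefficients
#' are penalized (penalizing the group indicator would bias the direct
#' effect, and the penalty exists to tame variance inflation from the
#' collinear exposures, not to shrink covariate adjustment). Mediator
#' columns are standardized internally with weighted means/SDs and the
#' weights are normalized to sum to n, so `lambda` is on a per-observation
#' scale; coefficients are returned on the original scale. `lambda = 0`
#' reproduces the unpenalized weighted least-squares fit.
#'
#' @inheritParams fit_multivariate_mediator_model
#' @param lambda ridge penalty, `>= 0`.
#' @return List with `beta_a`, `beta_m` (named, original scale),
#'   `coefficients` (full vector), and `lambda`.
#' @export
fit_joint_outcome_model <- function(data, mediators,
                                    covariates = pop_covariate_cols(),
                                    weights = NULL, lambda = 0) {
  if (lambda < 0) stop("lambda must be non-negative")
  w <- mixture_weights(data, weights)
  w <- w * length(w) / sum(w)
  form <- stats::reformulate(c("group", covariates))
  Xz <- stats::model.matrix(form, data)
  M <- as.matrix(data[, mediators, drop = FALSE])
  mu <- colSums(w * M) / sum(w)
  sd_w <- sqrt(colSums(w * sweep(M, 2, mu)^2) / sum(w))
  if (any(sd_w <= 0)) stop("zero-variance mediator column")
  Ms <- sweep(sweep(M, 2, mu), 2, sd_w, `/`)
  X <- cbind(Xz, Ms)
  y <- data$Y
  pen <- c(rep(0, ncol(Xz)), rep(1, ncol(Ms)))
  A <- crossprod(X * sqrt(w)) + lambda * diag(pen)
  b <- drop(solve(A, crossprod(X, w * y)))
  names(b) <- colnames(X)
  beta_m <- b[mediators] / sd_w
  coef_orig <- b
  coef_orig[mediators] <- beta_m
  coef_orig["(Intercept)"] <- coef_orig["(Intercept)"] - sum(beta_m * mu)
  list(beta_a = unname(b["group"]), beta_m = stats::setNames(beta_m, mediators),
       coefficients = coef_orig, lambda = lambda)
}

#' Cross-validated ridge penalty selection
#'
#' Grid-search k-fold cross-validation minimising weighted squared
#' prediction error of the joint outcome model; deterministic under
#' `cv_seed`. Folds are drawn stratified by group so every fold contains
#' both groups (a fold missing a group is re-drawn with a warning).
#'
#' @inheritParams fit_joint_outcome_model
#' @param grid candidate lambda values.
#' @param cv_folds number of folds (>= 2).
#' @param cv_seed seed for fold assignment.
#' @return Selected lambda, with attribute `"cv_error"` (named vector of
#'   mean weighted prediction errors over the grid).
#' @export
select_ridge_lambda <- function(data, mediators,
                                covariates = pop_covariate_cols(),
                                weights = NULL,
                                grid = 10^seq(-2, 6, length.out = 33),
                                cv_folds = 5, cv_seed = 1L) {
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  n <- nrow(data)
  w <- mixture_weights(data, weights)
  set.seed(cv_seed)
  folds <- make_group_folds(data$group, cv_folds)
  err <- rep(0, length(grid))
  for (k in seq_len(cv_folds)) {
    test <- folds == k
    fits <- lapply(grid, function(l) {
      fit_joint_outcome_model(data[!test, , drop = FALSE], mediators,
                              covariates, w[!test], lambda = l)
    })
    form <- stats::reformulate(c("group", covariates))
    Xt <- stats::model.matrix(form, data[test, , drop = FALSE])
    Mt <- as.matrix(data[test, mediators, drop = FALSE])
    for (i in seq_along(grid)) {
      cf <- fits[[i]]$coefficients
      pred <- drop(Xt %*% cf[colnames(Xt)] + Mt %*% cf[mediators])
      err[i] <- err[i] + sum(w[test] * (data$Y[test] - pred)^2)
    }
  }
  err <- err / sum(w)
  best <- grid[which.min(err)]
  attr(best, "cv_error") <- stats::setNames(err, signif(grid, 4))
  best
}

make_group_folds <- function(group, k) {
  n <- length(group)
  for (try in 1:25) {
    folds <- integer(n)
    for (g in unique(group)) {
      idx <- which(group == g)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(group[folds == f])) == length(unique(group))
    }, logical(1)))
    if (ok) return(folds)
    warning("cross-validation fold missing a group; re-drawing folds")
  }
  stop("could not build folds containing both groups")
}

#' Global indirect effect of the mediator mixture
#'
#' Inner product `alpha_a' beta_m`; with `beta_a` supplied the accompanying
#' percent mediated `100 * IE / (beta_a + IE)` is attached.
#'
#' @param alpha_a group-coefficient vector from the mediator model.
#' @param beta_m mediator-coefficient vector from the outcome model.
#' @param beta_a optional direct effect.
#' @return The global indirect effect (attribute `"pct_mediated"` when
#'   `beta_a` is given).
#' @export
global_indirect <- function(alpha_a, beta_m, beta_a = NULL) {
  if (length(alpha_a) != length(beta_m))
    stop("alpha_a and beta_m differ in length")
  ie <- sum(alpha_a * beta_m)
  if (!is.null(beta_a))
    attr(ie, "pct_mediated") <- 100 * ie / (beta_a + ie)
  ie
}

#' One-shot multivariate mediation point estimate
#'
#' Fits the multivariate mediator model and the (un)penalized joint outcome
#' model and returns the global indirect effect decomposition.
#'
#' @inheritParams fit_joint_outcome_model
#' @param method `"ols"` (unpenalized) or `"ridge"`.
#' @param lambda ridge penalty; `NULL` selects by cross-validation via
#'   [select_ridge_lambda()].
#' @param cv_folds,cv_seed passed to [select_ridge_lambda()].
#' @return List with `ie`, `beta_a` (direct), `total`, `pct_mediated`,
#'   `alpha_a`, `beta_m`, `lambda`.
#' @export
mixture_mediation <- function(data, mediators,
                              covariates = pop_covariate_cols(),
                              weights = NULL, method = c("ols", "ridge"),
                              lambda = NULL, cv_folds = 5, cv_seed = 1L) {
  method <- match.arg(method)
  w <- mixture_weights(data, weights)
  if (method == "ols") {
    lambda <- 0
  } else if (is.null(lambda)) {
    lambda <- select_ridge_lambda(data, mediators, covariates, w,
                                  cv_folds = cv_folds, cv_seed = cv_seed)
  }
  af <- fit_multivariate_mediator_model(data, mediators, covariates, w)
  bf <- fit_joint_outcome_model(data, mediators, covariates, w,
                                lambda = as.numeric(lambda))
  ie <- global_indirect(af$alpha_a, bf$beta_m, bf$beta_a)
  list(ie = as.numeric(ie), beta_a = bf$beta_a,
       total = bf$beta_a + as.numeric(ie),
       pct_mediated = attr(ie, "pct_mediated"),
       alpha_a = af$alpha_a, beta_m = bf$beta_m,
       lambda = as.numeric(lambda))
}

#' Bootstrap inference for the global indirect effect
#'
#' Resamples participants with replacement, recomputes the global indirect
#' effect `alpha_a' beta_m` per replicate, and returns the percentile 95%
#' confidence interval (order statistics of the replicates) and a two-sided
#' sign-based p-value with the +1 continuity correction,
#' `p = 2 min{(1 + #(t <= 0))/(B + 1), (1 + #(t >= 0))/(B + 1)}`. For the
#' ridge estimator the penalty is re-selected by cross-validation inside
#' each replicate by default (`lambda = NULL`); passing a fixed `lambda` is
#' the documented fast mode. An optional cluster bootstrap (resampling PSUs
#' within strata) is available when a design is supplied.
#'
#' @inheritParams mixture_mediation
#' @param B number of bootstrap replicates (>= 50).
#' @param seed RNG seed.
#' @param cluster resample whole PSUs within strata instead of participants
#'   (requires `design`).
#' @param design a [survey_design()] spec; used only by the cluster mode.
#' @return Object of class `bootstrap_distribution`: list with `estimate`
#'   (full-data point estimate), `replicates`, `B` (successful replicates),
#'   `ci`, `p`, `seed`, `n_failed`.
#' @export
bootstrap_mediation <- function(data, mediators,
                                covariates = pop_covariate_cols(),
                                weights = NULL, method = c("ols", "ridge"),
                                lambda = NULL, B = 1000, seed = 1L,
                                cv_folds = 5, cluster = FALSE,
                                design = NULL) {
  method <- match.arg(method)
  if (B < 50) stop("B must be at least 50")
  if (cluster && is.null(design)) stop("cluster bootstrap requires a design")
  w <- mixture_weights(data, weights)
  point <- mixture_mediation(data, mediators, covariates, w, method,
                             lambda = lambda, cv_seed = seed)
  set.seed(seed)
  n <- nrow(data)
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- if (cluster) {
      unlist(lapply(unique(design$stratum), function(h) {
        rows <- which(design$stratum == h)
        psus <- unique(design$psu[rows])
        take <- sample(psus, length(psus), replace = TRUE)
        unlist(lapply(take, function(cl) rows[design$psu[rows] == cl]))
      }), use.names = FALSE)
    } else {
      sample.int(n, n, replace = TRUE)
    }
    reps[b] <- tryCatch(
      mixture_mediation(data[idx, , drop = FALSE], mediators, covariates,
                        w[idx], method, lambda = lambda,
                        cv_seed = seed + b)$ie,
      error = function(e) NA_real_)
  }
  failed <- sum(is.na(reps))
  if (failed > 0.05 * B)
    stop(failed, " of ", B, " bootstrap replicates failed")
  reps <- reps[!is.na(reps)]
  bb <- length(reps)
  ci <- unname(stats::quantile(reps, c(0.025, 0.975), type = 1))
  p <- min(1, 2 * min((1 + sum(reps <= 0)) / (bb + 1),
                      (1 + sum(reps >= 0)) / (bb + 1)))
  structure(list(estimate = point$ie, beta_a = point$beta_a,
                 pct_mediated = point$pct_mediated,
                 replicates = reps, B = bb, ci = ci, p = p, seed = seed,
                 n_failed = failed, method = method,
                 lambda = point$lambda),
            class = "bootstrap_distribution")
}
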