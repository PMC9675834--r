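#' Summary-score weight object
#'
#' @param weights named numeric weights over chemicals.
#' @param method `"pca"`, `"pdm"`, or `"teq"`.
#' @return Object of class `score_weights`.
#' @keywords internal
score_weights <- function(weights, method) {
  stopifnot(method %in% c("pca", "pdm", "teq"))
  if (method %in% c("pca", "pdm")) {
    nrm <- sqrt(sum(weights^2))
    if (abs(nrm - 1) > 1e-8) weights <- weights / nrm
  } else if (any(weights < 0)) stop("TEQ weights must be non-negative")
  structure(list(weights = weights, method = method,
                 chemicals = names(weights)),
            class = "score_weights")
}

orient_sign <- function(w) if (sum(w) < 0) -w else w

#' First-principal-component score weights
#'
#' First eigenvector of the correlation matrix of the standardized log
#' concentrations restricted to `subset` (correlation-scale PCA: the
#' chemicals live on different concentration scales, and the uniformly
#' positive correlations of the exposure block give an all-positive first
#' component). The sign is oriented so the weight sum is positive; weights
#' have unit Euclidean norm.
#'
#' @param log_m matrix of complete log-scale concentrations (for multiply
#'   imputed data, stack the completed panels).
#' @param subset chemical names to restrict to (default all columns).
#' @return A `score_weights` object with attribute `"var_explained"`.
#' @export
pca_weights <- function(log_m, subset = NULL) {
  log_m <- as.matrix(log_m)
  if (!is.null(subset)) {
    missing <- setdiff(subset, colnames(log_m))
    if (length(missing)) stop("chemicals not in panel: ",
                              paste(missing, collapse = ", "))
    log_m <- log_m[, subset, drop = FALSE]
  }
  if (ncol(log_m) < 2) stop("need at least 2 chemicals for PCA")
  sds <- apply(log_m, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance chemical: ",
                          paste(colnames(log_m)[sds == 0], collapse = ", "))
  ev <- eigen(stats::cor(log_m), symmetric = TRUE)
  w <- orient_sign(stats::setNames(ev$vectors[, 1], colnames(log_m)))
  out <- score_weights(w, "pca")
  attr(out, "var_explained") <- ev$values[1] / sum(ev$values)
  out
}

#' First principal direction of mediation
#'
#' The unit-norm linear combination `S = w'M` maximising the magnitude of
#' the mediated effect `|alpha_w * beta_w|` of the resulting score, where
#' `alpha_w` is the group coefficient of the S|A,Z model and `beta_w` the
#' score coefficient of the Y|S,A,Z model. Both coefficients have closed
#' forms in `w` (via weighted residualization of Y and M on the
#' group-plus-covariate design), so the objective
#' `|(w'a)(w'b)| / (w'Cw)` is optimized directly on the sphere by
#' quasi-Newton iteration from multiple random starts plus the PCA start
#' (the objective is scale-invariant, so the optimization is
#' unconstrained). Deterministic under `seed`; sign oriented as in
#' [pca_weights()].
#'
#' @param data completed cohort data frame.
#' @param mediators mediator columns.
#' @param covariates adjustment covariates.
#' @param weights observation weights (cohort `weight` column by default).
#' @param n_starts number of random restarts (the PCA start is always
#'   included).
#' @param seed RNG seed for the restarts.
#' @return A `score_weights` object with attribute `"objective"` (the
#'   achieved `|alpha_w beta_w|`).
#' @export
pdm_weights <- function(data, mediators, covariates = pop_covariate_cols(),
                        weights = NULL, n_starts = 20, seed = 1L) {
  w_obs <- mixture_weights(data, weights)
  if (length(mediators) == 1) {
    return(score_weights(stats::setNames(1, mediators), "pdm"))
  }
  form <- stats::reformulate(c("group", covariates))
  X <- stats::model.matrix(form, data)
  M <- as.matrix(data[, mediators, drop = FALSE])
  y <- data$Y
  xtwx_inv <- chol2inv(chol(crossprod(X * sqrt(w_obs))))
  hat <- function(v) X %*% (xtwx_inv %*% crossprod(X, w_obs * v))
  Mr <- M - apply(M, 2, hat)
  yr <- y - drop(hat(y))
  a <- fit_multivariate_mediator_model(data, mediators, covariates,
                                       w_obs)$alpha_a
  b <- drop(crossprod(Mr, w_obs * yr))
  C <- crossprod(Mr * sqrt(w_obs))
  C <- C + diag(1e-8 * mean(diag(C)), ncol(C))
  objective <- function(v) {
    q <- drop(v %*% C %*% v)
    if (q <= 0) return(Inf)
    -abs(sum(v * a) * sum(v * b)) / q
  }
  set.seed(seed)
  starts <- c(list(as.numeric(pca_weights(M)$weights)),
              lapply(seq_len(n_starts), function(i) stats::rnorm(length(mediators))))
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(stats::optim(s, objective, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("principal-direction optimization failed from all starts")
  w <- best$par / sqrt(sum(best$par^2))
  w <- orient_sign(stats::setNames(w, mediators))
  out <- score_weights(w, "pdm")
  attr(out, "objective") <- -best$value
  out
}

#' Toxic equivalency (TEQ) score
#'
#' Potency-weighted sum `sum_j TEF_j * concentration_ij` over the chemicals
#' that carry a toxic equivalency factor, computed on the natural
#' concentration scale (potency weighting is defined on concentrations);
#' chemicals without a TEF are excluded. The score is log-transformed
#' before use as a mediator — see [score_mediation()].
#'
#' @param conc_natural matrix of natural-scale concentrations.
#' @param tef TEF table (data frame `chemical`, `tef`), default
#'   [tef_table()].
#' @return Numeric per-participant score, with attribute `"weights"` (a
#'   `score_weights` object over the TEF-bearing chemicals present).
#' @export
teq_score <- function(conc_natural, tef = tef_table()) {
  conc_natural <- as.matrix(conc_natural)
  if (any(tef$tef < 0)) stop("negative TEF")
  use <- tef[tef$chemical %in% colnames(conc_natural), , drop = FALSE]
  if (!nrow(use)) stop("no TEF-bearing chemicals in panel")
  s <- drop(conc_natural[, use$chemical, drop = FALSE] %*% use$tef)
  attr(s, "weights") <- score_weights(stats::setNames(use$tef, use$chemical),
                                      "teq")
  s
}

log_with_offset <- function(s) {
  if (any(s < 0)) stop("negative score cannot be log-transformed")
  if (any(s == 0)) {
    pos <- s[s > 0]
    if (!length(pos)) stop("all scores zero: log-scale mediator undefined")
    off <- min(pos) / 2
    warning("zero score(s) offset by half the smallest positive score (",
            format(off), ") before log transform")
    s <- s + off
  }
  log(s)
}

append_score <- function(d, wobj) {
  if (wobj$method == "teq") {
    s <- teq_score(exp(as.matrix(d[, wobj$chemicals, drop = FALSE])),
                   data.frame(chemical = wobj$chemicals,
                              tef = as.numeric(wobj$weights)))
    d$.score <- log_with_offset(as.numeric(s))
  } else {
    d$.score <- drop(as.matrix(d[, wobj$chemicals, drop = FALSE]) %*%
                       wobj$weights)
  }
  d
}

#' Run a summary exposure score through the single-mediator framework
#'
#' Forms the per-participant score from the supplied weights (log-scale
#' linear combination for PCA/PDM; potency-weighted natural-scale sum, then
#' log, for TEQ), substitutes it as the sole mediator, and returns the full
#' pooled survey-weighted mediation result. Because `alpha_w` scales by `c`
#' and `beta_w` by `1/c`, the indirect effect is invariant to positive
#' rescaling of the weights.
#'
#' @param datasets list of completed cohort data frames
#'   ([completed_cohorts()]).
#' @param design a [survey_design()] spec, or `NULL`.
#' @param weights_obj a `score_weights` object ([pca_weights()],
#'   [pdm_weights()], or the `"weights"` attribute of [teq_score()]).
#' @param covariates adjustment covariates.
#' @param label row label (defaults to the score method).
#' @return One-row data frame with the [single_mediator_analysis()] columns.
#' @export
score_mediation <- function(datasets, design = NULL, weights_obj,
                            covariates = pop_covariate_cols(),
                            label = NULL) {
  stopifnot(inherits(weights_obj, "score_weights"))
  scored <- lapply(datasets, append_score, wobj = weights_obj)
  out <- single_mediator_analysis(scored, design, mediators = ".score",
                                  covariates = covariates)
  out$model <- if (is.null(label)) toupper(weights_obj$method) else label
  out
}

#' Subclass PCA mediation sensitivity analysis
#'
#' Restricts the PCA summary score to each chemical subclass (all PCBs,
#' non-ortho PCBs, non-dioxin-like PCBs, dioxins, furans by default) and
#' runs each score through the single-mediator framework, showing which
#' classes carry the global indirect effect.
#'
#' @inheritParams score_mediation
#' @param class_map named list of chemical subsets (default
#'   [pop_subclasses()]).
#' @return Data frame with one row per subclass plus a `"weights"`
#'   attribute (list of per-subclass `score_weights`).
#' @export
subclass_pca_mediation <- function(datasets, design = NULL,
                                   class_map = pop_subclasses(),
                                   covariates = pop_covariate_cols()) {
  if (any(!lengths(class_map))) stop("empty subclass in class_map")
  stacked <- do.call(rbind, lapply(datasets, function(d) {
    as.matrix(d[, unique(unlist(class_map)), drop = FALSE])
  }))
  wts <- list()
  rows <- lapply(names(class_map), function(cl) {
    chems <- class_map[[cl]]
    if (length(chems) == 1) {
      wobj <- score_weights(stats::setNames(1, chems), "pca")
    } else {
      wobj <- pca_weights(stacked, subset = chems)
    }
    wts[[cl]] <<- wobj
    score_mediation(datasets, design, wobj, covariates,
                    label = paste0("PCA: ", cl))
  })
  out <- do.call(rbind, rows)
  out$p_bh <- NULL
  attr(out, "weights") <- wts
  out
}
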