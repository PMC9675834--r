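#' Survey design specification for a stratified cluster sample
#'
#' Validates the design columns of a cohort: strictly positive weights and
#' at least two primary sampling units (PSUs) per stratum. A stratum with a
#' single PSU is a hard error — between-PSU variance cannot be estimated and
#' silently centring such strata would hide design mis-specification;
#' collapse strata or handle certainty units upstream instead.
#'
#' @param data data frame holding the design columns.
#' @param stratum,psu,weights column names (defaults `"stratum"`, `"psu"`,
#'   `"weight"`).
#' @return An object of class `survey_design_spec` with vectors `stratum`,
#'   `psu`, `weights`.
#' @export
survey_design <- function(data, stratum = "stratum", psu = "psu",
                          weights = "weight") {
  s <- data[[stratum]]; p <- data[[psu]]; w <- data[[weights]]
  if (is.null(s) || is.null(p) || is.null(w))
    stop("design columns not found: need ", stratum, ", ", psu, ", ", weights)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("survey weights must be strictly positive and finite")
  npsu <- tapply(p, s, function(x) length(unique(x)))
  if (any(npsu < 2))
    stop("stratum ", paste(names(npsu)[npsu < 2], collapse = ", "),
         " has a single PSU; collapse strata or handle certainty units ",
         "before variance estimation")
  structure(list(stratum = s, psu = p, weights = w),
            class = "survey_design_spec")
}

#' Weighted least squares with model-based variance
#'
#' Minimises the weighted residual sum of squares. With unit weights this is
#' ordinary least squares; duplicating a row is equivalent to doubling its
#' weight. The returned covariance is the model-based
#' `sigma^2 (X'WX)^{-1}`; replace it with [taylor_variance()] for
#' design-based inference.
#'
#' @param X design matrix (including any intercept).
#' @param y response.
#' @param weights positive weights.
#' @param model_label optional label (e.g. `"Y|M,A,Z"`).
#' @return Object of class `wls_fit`: coefficients, vcov, residuals,
#'   fitted, sigma2, df_residual, and the inputs needed for linearization.
#' @export
fit_wls <- function(X, y, weights = rep(1, length(y)), model_label = "") {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(weights) == n)
  if (any(weights <= 0)) stop("weights must be strictly positive")
  qx <- qr(X * sqrt(weights))
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  xtwx_inv <- chol2inv(chol(crossprod(X * sqrt(weights))))
  beta <- drop(xtwx_inv %*% crossprod(X, weights * y))
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  df_res <- n - ncol(X)
  sigma2 <- sum(weights * resid^2) / df_res
  vcov <- sigma2 * xtwx_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, vcov = vcov, residuals = resid,
                 fitted = fitted, sigma2 = sigma2, n = n,
                 df_residual = df_res, X = X, weights = weights,
                 xtwx_inv = xtwx_inv, model_label = model_label,
                 variance_type = "model"),
            class = "wls_fit")
}

#' Taylor-linearized (sandwich) variance for a stratified cluster design
#'
#' Design-based covariance of weighted least-squares coefficients: the
#' estimating-equation scores `w_i e_i x_i` are totalled within PSUs,
#' centred within strata, and combined with the standard
#' `n_h / (n_h - 1)` stratum factor; the score covariance is sandwiched
#' between `(X'WX)^{-1}` factors. Invariant to rescaling all weights by a
#' positive constant.
#'
#' @param fit a [fit_wls()] result produced with the design weights.
#' @param design a [survey_design_spec][survey_design()].
#' @return The fit with its `vcov` replaced by the linearized covariance and
#'   `variance_type = "taylor"`.
#' @export
taylor_variance <- function(fit, design) {
  stopifnot(inherits(fit, "wls_fit"), inherits(design, "survey_design_spec"))
  if (length(design$stratum) != fit$n)
    stop("design and fit differ in length")
  scores <- fit$X * (design$weights * fit$residuals)
  p <- ncol(scores)
  vmid <- matrix(0, p, p)
  for (h in unique(design$stratum)) {
    rows <- which(design$stratum == h)
    psus <- unique(design$psu[rows])
    nh <- length(psus)
    if (nh < 2)
      stop("stratum ", h, " has a single PSU; collapse strata or handle ",
           "certainty units before variance estimation")
    z <- t(vapply(psus, function(cl) {
      colSums(scores[rows[design$psu[rows] == cl], , drop = FALSE])
    }, numeric(p)))
    zc <- sweep(z, 2, colMeans(z))
    vmid <- vmid + nh / (nh - 1) * crossprod(zc)
  }
  a <- fit$xtwx_inv
  v <- a %*% vmid %*% a
  v <- (v + t(v)) / 2
  dimnames(v) <- dimnames(fit$vcov)
  fit$vcov <- v
  fit$variance_type <- "taylor"
  fit
}

#' Wald test of a single coefficient
#'
#' `z = estimate / SE` with a two-sided p-value from the standard normal
#' reference (the package default; a design-df t reference is available via
#' `df`).
#'
#' @param fit a `wls_fit`.
#' @param coefficient coefficient name or index.
#' @param df degrees of freedom for a t reference; `Inf` (default) uses the
#'   normal.
#' @return List with `estimate`, `se`, `statistic`, `p`.
#' @export
wald_test <- function(fit, coefficient, df = Inf) {
  est <- fit$coefficients[coefficient]
  se <- sqrt(diag(fit$vcov))[coefficient]
  if (!is.finite(se) || se <= 0) stop("zero or undefined standard error for ",
                                      coefficient)
  z <- est / se
  p <- if (is.finite(df)) 2 * stats::pt(-abs(z), df) else 2 * stats::pnorm(-abs(z))
  list(estimate = unname(est), se = unname(se), statistic = unname(z),
       p = unname(p))
}

#' Survey-weighted linear model from a formula
#'
#' Convenience wrapper: builds the model matrix, fits weighted least squares
#' with the design weights, and (by default) replaces the model-based
#' covariance with the Taylor-linearized design-based covariance.
#'
#' @param formula model formula.
#' @param data data frame (must contain the design columns when
#'   `design` is a `survey_design_spec` built from it).
#' @param design a [survey_design_spec][survey_design()], or `NULL` for an
#'   unweighted, model-based fit.
#' @param variance `"taylor"` (default) or `"model"`.
#' @param model_label stored on the fit.
#' @return A `wls_fit`.
#' @export
fit_survey_lm <- function(formula, data, design = NULL,
                          variance = c("taylor", "model"),
                          model_label = deparse(formula)) {
  variance <- match.arg(variance)
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  w <- if (is.null(design)) rep(1, length(y)) else design$weights
  fit <- fit_wls(X, y, w, model_label = model_label)
  if (!is.null(design) && variance == "taylor") fit <- taylor_variance(fit, design)
  fit
}
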