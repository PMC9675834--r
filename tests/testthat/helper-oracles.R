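# Independent oracles used to cross-check the package's estimators.
# These deliberately take different computational routes than the
# implementation (brute-force solves, data augmentation, replication,
# direct likelihood optimisation, power iteration).

# weighted normal equations by brute-force matrix solve
oracle_wls <- function(X, y, w) {
  W <- diag(w)
  drop(solve(t(X) %*% W %*% X, t(X) %*% W %*% y))
}

# delete-one-PSU-pair jackknife SE for one coefficient of a weighted fit
oracle_jackknife_se <- function(X, y, w, stratum, psu, coefficient) {
  full <- fit_wls(X, y, w)$coefficients[coefficient]
  v <- 0
  for (h in unique(stratum)) {
    rows_h <- which(stratum == h)
    psus <- unique(psu[rows_h])
    nh <- length(psus)
    for (cl in psus) {
      wj <- w
      drop_rows <- rows_h[psu[rows_h] == cl]
      keep_rows <- setdiff(rows_h, drop_rows)
      wj[drop_rows] <- 0
      wj[keep_rows] <- wj[keep_rows] * nh / (nh - 1)
      use <- wj > 0
      th <- fit_wls(X[use, , drop = FALSE], y[use], wj[use])$coefficients[coefficient]
      v <- v + (nh - 1) / nh * (th - full)^2
    }
  }
  sqrt(v)
}

# censored-normal log-likelihood maximised directly with optim
oracle_censored_mle <- function(y, X, censored, censor_point) {
  Xi <- cbind(1, X)
  nll <- function(par) {
    beta <- par[seq_len(ncol(Xi))]
    s <- exp(par[length(par)])
    mu <- drop(Xi %*% beta)
    obs <- !censored
    -sum(stats::dnorm(y[obs], mu[obs], s, log = TRUE)) -
      sum(stats::pnorm(censor_point[censored], mu[censored], s, log.p = TRUE))
  }
  start <- c(stats::coef(stats::lm.fit(Xi, ifelse(censored, censor_point, y))),
             log(stats::sd(y)))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  list(coefficients = unname(opt$par[seq_len(ncol(Xi))]),
       sd = unname(exp(opt$par[length(opt$par)])))
}

# leading eigenvector by power iteration
oracle_power_iteration <- function(S, iter = 2000) {
  v <- rep(1, ncol(S)) / sqrt(ncol(S))
  for (i in seq_len(iter)) {
    v2 <- drop(S %*% v)
    v <- v2 / sqrt(sum(v2^2))
  }
  if (sum(v) < 0) v <- -v
  unname(v)
}

# ridge solution by sqrt(lambda) data augmentation + QR least squares,
# reproducing the estimator's weighted standardization of penalized columns
oracle_ridge_augmented <- function(data, mediators, covariates, w, lambda) {
  w <- w * length(w) / sum(w)
  Xz <- stats::model.matrix(stats::reformulate(c("group", covariates)), data)
  M <- as.matrix(data[, mediators, drop = FALSE])
  mu <- colSums(w * M) / sum(w)
  sd_w <- sqrt(colSums(w * sweep(M, 2, mu)^2) / sum(w))
  Ms <- sweep(sweep(M, 2, mu), 2, sd_w, `/`)
  X <- cbind(Xz, Ms)
  pen <- c(rep(0, ncol(Xz)), rep(1, ncol(Ms)))
  Xa <- rbind(X * sqrt(w), sqrt(lambda) * diag(pen)[pen == 1, , drop = FALSE])
  ya <- c(sqrt(w) * data$Y, rep(0, sum(pen)))
  b <- stats::coef(stats::lm.fit(Xa, ya))
  stats::setNames(b[colnames(X) %in% mediators] / sd_w, mediators)
}
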