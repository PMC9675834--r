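#' Convert a log-outcome effect to an approximate risk ratio
#'
#' Standard continuous-outcome conversion for E-value sensitivity analysis:
#' the standardized mean difference `d = beta / sd_y` maps to
#' `RR = exp(0.91 * d)`. A zero effect maps to `RR = 1`; negative effects
#' map below 1 and are inverted downstream before the E-value formula.
#'
#' @param beta effect in log-outcome units.
#' @param sd_y outcome standard deviation (> 0), e.g. of log LTL in the
#'   analytic sample.
#' @return Approximate risk ratio.
#' @export
effect_to_rr <- function(beta, sd_y) {
  if (any(sd_y <= 0)) stop("sd_y must be positive")
  exp(0.91 * beta / sd_y)
}

#' E-value for unmeasured confounding
#'
#' Minimum risk-ratio strength of association an unmeasured confounder must
#' have with both sides of an association to explain it away:
#' `E = RR + sqrt(RR * (RR - 1))` for `RR >= 1`; ratios below 1 are
#' inverted first, so `E(1/RR) = E(RR)`. `E = 1` iff `RR = 1`.
#'
#' @param rr risk ratio (> 0).
#' @return E-value (>= 1).
#' @export
evalue <- function(rr) {
  if (any(rr <= 0)) stop("risk ratio must be positive")
  rr <- ifelse(rr < 1, 1 / rr, rr)
  rr + sqrt(rr * (rr - 1))
}

#' Mediation E-value for an indirect effect and its confidence bound
#'
#' Converts the indirect-effect point estimate and the CI bound closer to
#' the null to the risk-ratio scale and returns both E-values. If the CI
#' crosses the null the bound E-value is 1 (no unmeasured confounding is
#' needed to move the interval to the null).
#'
#' @param ie indirect effect, log-outcome units.
#' @param ci length-2 confidence interval for the indirect effect.
#' @param sd_y outcome standard deviation.
#' @return List with `rr`, `evalue_point`, `evalue_ci`.
#' @export
mediation_evalue <- function(ie, ci, sd_y) {
  rr <- effect_to_rr(ie, sd_y)
  e_point <- evalue(rr)
  crosses <- min(ci) <= 0 && max(ci) >= 0
  bound <- if (crosses) 0 else ci[which.min(abs(ci))]
  e_ci <- if (crosses) 1 else evalue(effect_to_rr(bound, sd_y))
  list(rr = rr, evalue_point = e_point, evalue_ci = e_ci)
}
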