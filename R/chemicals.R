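#' Roster of the 15 analysed persistent organic pollutants
#'
#' The analytic chemical set used throughout the package: nine PCB congeners,
#' three dioxins, and three furans measured in serum (ng/g or pg/g lipid) in
#' the NHANES 1999-2000 and 2001-2002 cycles. `below_lod` carries the
#' published percent of observations below the limit of detection for each
#' chemical, which the synthetic-cohort generator uses as its default
#' censoring targets. Subclass indicators identify the non-ortho
#' (dioxin-like) and non-dioxin-like PCBs used in the subclass sensitivity
#' analyses.
#'
#' @return A data frame with columns `chemical`, `class`
#'   (`"pcb"`, `"dioxin"`, `"furan"`), `non_ortho`, `non_dioxin_like`,
#'   and `below_lod` (proportion below LOD).
#' @export
pop_chemicals <- function() {
  data.frame(
    chemical = c("PCB74", "PCB118", "PCB126", "PCB138", "PCB153",
                 "PCB169", "PCB170", "PCB180", "PCB187",
                 "D03", "D05", "D07", "F03", "F04", "F08"),
    class = c(rep("pcb", 9), rep("dioxin", 3), rep("furan", 3)),
    non_ortho = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
                  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    non_dioxin_like = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE,
                        TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    below_lod = c(0.305, 0.284, 0.217, 0.203, 0.169,
                  0.177, 0.264, 0.177, 0.321,
                  0.209, 0.133, 0.205, 0.369, 0.273, 0.253),
    stringsAsFactors = FALSE
  )
}

#' Chemical subclass map for subclass PCA sensitivity analyses
#'
#' @return Named list of character vectors, each a subset of
#'   [pop_chemicals()] chemicals: all PCBs, non-ortho PCBs, non-dioxin-like
#'   PCBs, dioxins, and furans.
#' @export
pop_subclasses <- function() {
  ch <- pop_chemicals()
  list(
    pcb             = ch$chemical[ch$class == "pcb"],
    non_ortho       = ch$chemical[ch$non_ortho],
    non_dioxin_like = ch$chemical[ch$non_dioxin_like],
    dioxin          = ch$chemical[ch$class == "dioxin"],
    furan           = ch$chemical[ch$class == "furan"]
  )
}

#' Toxic equivalency factor (TEF) table
#'
#' Potency weights relative to 2,3,7,8-TCDD for the dioxin-like chemicals in
#' the analytic set. Two tables ship with the package: `"default"` is the
#' table used by the motivating NHANES toxic-equivalency score (note that it
#' assigns PCB 118 a TEF of 0.030, where the WHO 2005 re-evaluation lists
#' 0.00003), and `"who2005"` carries the WHO 2005 values. Chemicals without
#' a TEF (the non-dioxin-like PCBs) are absent from the table and are
#' excluded from the TEQ score by construction.
#'
#' @param version `"default"` or `"who2005"`.
#' @return Data frame with columns `chemical` and `tef`.
#' @export
tef_table <- function(version = c("default", "who2005")) {
  version <- match.arg(version)
  path <- system.file("extdata", paste0("tef_", version, ".csv"),
                      package = "popmediate", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (any(tab$tef < 0)) stop("negative TEF in table: ", version)
  tab
}

#' Published reference values from the motivating NHANES mediation analysis
#'
#' Point estimates as printed in the motivating NHANES 1999-2002 analysis of
#' Black/White leukocyte telomere length differences mediated by POPs. These
#' are *reference constants* for arithmetic consistency checks (e.g. that
#' printed indirect plus direct effects reproduce the printed total effect)
#' and for patterning synthetic-cohort effect sizes; nothing in the package
#' recomputes them from data.
#'
#' @return A list with elements:
#' \describe{
#'   \item{total_effect}{printed total effect of race on log LTL, with CI and p.}
#'   \item{n_white, n_black}{analytic sample sizes by group.}
#'   \item{mediation_rows}{data frame of printed per-model indirect effect
#'     (IDE), direct effect (DE) and percent mediated for selected models.}
#'   \item{n_imputed_chemicals, n_quality_excluded}{17 chemicals passed the
#'     below-LOD filter and were imputed; 2 (PCB 156, PCB 99) were excluded
#'     after an imputation-quality review, leaving the analysed 15.}
#'   \item{evalue}{printed E-value for the PCA score mediation (point and
#'     CI-bound).}
#' }
#' @export
reference_estimates <- function() {
  list(
    total_effect = list(estimate = 0.054, ci = c(0.009, 0.099), p = 0.018),
    n_white = 930,
    n_black = 321,
    mediation_rows = data.frame(
      model = c("PCB118", "PCB153", "PCB187", "Unpenalized", "Ridge",
                "PCA", "TEQ", "PDM"),
      ide = c(0.015, 0.019, 0.024, 0.011, 0.013, 0.019, 0.016, 0.000),
      de = c(0.039, 0.035, 0.031, 0.040, 0.037, 0.035, 0.039, 0.054),
      pct_mediated = c(28.6, 34.5, 43.4, 20.9, 26.0, 34.8, 28.8, 0.6),
      stringsAsFactors = FALSE
    ),
    n_imputed_chemicals = 17L,
    quality_excluded = c("PCB156", "PCB99"),
    evalue = list(point = 1.35, ci_bound = 1.22)
  )
}

#' Total serum lipids from cholesterol and triglycerides
#'
#' The short enzymatic-summation formula for total serum lipids,
#' `2.27 * total cholesterol + triglycerides + 62.3` (all in mg/dL), used
#' because the survey files report cholesterol and triglycerides but no
#' single lipid concentration. Serum POP concentrations are expressed per
#' gram of lipid, so this denominator feeds both lipid adjustment and any
#' lipid-standardised concentrations.
#'
#' @param total_cholesterol,triglycerides positive, mg/dL.
#' @return Total lipids in mg/dL.
#' @export
derive_lipids <- function(total_cholesterol, triglycerides) {
  if (any(!is.finite(total_cholesterol)) || any(!is.finite(triglycerides)))
    stop("non-finite lipid inputs")
  if (any(total_cholesterol <= 0) || any(triglycerides <= 0))
    stop("cholesterol and triglycerides must be positive (mg/dL)")
  2.27 * total_cholesterol + triglycerides + 62.3
}
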