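#' Spike-recovery percentage
#'
#' Recovery of a protein standard spiked into a native sample:
#' `100 * Ps / (Cs + Pus)`, where `Ps` is the protein measured in the
#' spiked sample, `Pus` the protein measured in the unspiked sample and
#' `Cs` the spike concentration (all mg/mL). Perfect extraction gives
#' 100%.
#'
#' @param Ps Protein measured in the spiked sample (mg/mL).
#' @param Pus Protein measured in the unspiked sample (mg/mL).
#' @param Cs Spike concentration (mg/mL).
#' @return Recovery percentage.
#' @export
percent_recovery <- function(Ps, Pus, Cs) {
  if (any(c(Ps, Pus, Cs) < 0)) stopf("inputs must be non-negative")
  if (Cs + Pus == 0) stopf("Cs + Pus is zero; recovery undefined")
  100 * Ps / (Cs + Pus)
}

#' Kjeldahl nitrogen percentage
#'
#' `%N = 1.4008 * (Vs - Vb) * M / W`: titrant volume difference between
#' test portion and blank (mL), acid molarity (mol/L) and test-portion
#' mass (g). 1.4008 converts mmol of titrated ammonia per gram to percent
#' nitrogen by mass.
#'
#' @param Vs Titrant volume for the test portion (mL).
#' @param Vb Titrant volume for the blank (mL).
#' @param M Acid molarity (mol/L).
#' @param W Test-portion mass (g).
#' @return Nitrogen percentage by mass.
#' @export
percent_nitrogen <- function(Vs, Vb, M, W) {
  if (W <= 0) stopf("test-portion mass W must be positive")
  if (M <= 0) stopf("acid molarity M must be positive")
  if (Vs < Vb) warnf("Vs < Vb: blank exceeds test portion")
  1.4008 * (Vs - Vb) * M / W
}

#' Protein summary from Kjeldahl nitrogen values
#'
#' Converts percent nitrogen to percent protein with the dairy conversion
#' factor 6.38, for both the true-protein and the casein determinations,
#' and reports whey protein by difference: `whey = TP - CN`.
#'
#' @param pctN_true Percent nitrogen of the true-protein determination.
#' @param pctN_casein Percent nitrogen of the casein determination.
#' @param factor Nitrogen-to-protein conversion factor (default 6.38, the
#'   milk-protein convention).
#' @return A list with `true_protein`, `casein` and `whey` percentages.
#' @export
protein_summary <- function(pctN_true, pctN_casein, factor = 6.38) {
  if (pctN_true < 0 || pctN_casein < 0) stopf("inputs must be non-negative")
  tp <- factor * pctN_true
  cn <- factor * pctN_casein
  whey <- tp - cn
  if (whey < 0)
    warnf("whey protein by difference is negative (%.4g%%)", whey)
  list(true_protein = tp, casein = cn, whey = whey)
}
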