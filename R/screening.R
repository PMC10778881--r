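#' Component count explaining a target fraction of X variance
#'
#' The screening default: the smallest number of PLS components whose
#' cumulative X sum of squares reaches `threshold`, capped at `cap` and at
#' the rank bound.
#'
#' @param X Spectra matrix.
#' @param y Response used to direct the PLS components.
#' @param threshold Cumulative X-variance fraction to reach (default 0.95).
#' @param cap Hard upper bound on components (default 10).
#' @return Integer component count.
#' @export
choose_screening_ncomp <- function(X, y, threshold = 0.95, cap = 10L) {
  kmax <- min(cap, nrow(X) - 1L, ncol(X))
  d <- suppressWarnings(pls_decompose(X, y, kmax))
  hit <- which(d$x_var_explained >= threshold)
  if (length(hit)) min(hit[1], d$k) else d$k
}

# F-distribution Hotelling T2 control limit: k(n-1)/(n-k) * F_{k, n-k, conf}
t2_limit <- function(n, k, confidence) {
  if (confidence >= 1) return(Inf)
  k * (n - 1) / (n - k) * stats::qf(confidence, k, n - k)
}

# Q-residual control limit. "jm" is the Jackson-Mudholkar parametric limit
# computed from the eigenvalues of the residual covariance; "empirical" is
# the plain quantile of the observed Q values. For "jm" the eigenvalues are
# estimated from the rows in the central (1 - trim) mass of Q, so a
# moderate fraction of gross outliers cannot inflate the gate that is
# supposed to catch them.
q_limit <- function(residuals, q, confidence, method = c("jm", "empirical"),
                    trim = 0.1) {
  method <- match.arg(method)
  if (confidence >= 1) {
    return(if (method == "empirical") max(q) else Inf)
  }
  if (method == "empirical")
    return(as.numeric(stats::quantile(q, confidence, type = 7)))
  keep <- q <= stats::quantile(q, 1 - trim, type = 7)
  residuals <- residuals[keep, , drop = FALSE]
  n <- nrow(residuals)
  lam <- svd(residuals, nu = 0, nv = 0)$d^2 / (n - 1)
  lam <- lam[lam > max(lam[1], 0) * 1e-12]
  if (!length(lam) || lam[1] <= 0) return(0)
  th1 <- sum(lam); th2 <- sum(lam^2); th3 <- sum(lam^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 == 0) h0 <- 1e-4
  ca <- stats::qnorm(confidence)
  th1 * (ca * sqrt(2 * th2 * h0^2) / th1 +
           1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

#' Flag outlier spectra by combined Hotelling T2 and Q-residual gates
#'
#' Decomposes the full spectra matrix with PLS directed at one protein's
#' concentrations, computes per-spectrum [t2_scores()] and [q_scores()],
#' and flags spectra beyond the control limits at the stated confidence.
#' Under the default `"and"` rule a spectrum must exceed both limits -
#' extreme inside the model space and poorly reconstructed by it - to be
#' flagged; `"or"` flags on either.
#'
#' The T2 limit uses the F-distribution formula
#' `k(n-1)/(n-k) F_(k, n-k, conf)`. The Q limit defaults to the
#' Jackson-Mudholkar parametric limit with its eigenvalue scale estimated
#' on the central 90% of the Q distribution, so the gate is not inflated
#' by the very contamination it is meant to catch; the plain empirical
#' quantile is available via `q_method = "empirical"`.
#'
#' @param s A `spectra_set`.
#' @param conc A [concentration_table()] covering the set's samples, or a
#'   numeric response vector with one value per spectrum.
#' @param k Number of PLS components; `NULL` (default) uses
#'   [choose_screening_ncomp()] (>= 95% X variance, capped at 10).
#' @param confidence Confidence level of both gates (default 0.99).
#' @param rule `"and"` (default) or `"or"` combination of the two gates.
#' @param protein Which protein directs the PLS when `conc` is a table.
#' @param q_method `"jm"` (default) or `"empirical"` Q limit.
#' @return An `outlier_report`: a `data.frame` with columns `spectrum_id`,
#'   `t2`, `q`, `flagged`, plus attributes `t2_limit`, `q_limit`,
#'   `confidence`, `rule`, `k`.
#' @export
flag_outliers <- function(s, conc, k = NULL, confidence = 0.99,
                          rule = c("and", "or"),
                          protein = c("beta_lg", "alpha_la"),
                          q_method = c("jm", "empirical")) {
  rule <- match.arg(rule)
  q_method <- match.arg(q_method)
  validate_spectra_set(s)
  y <- if (inherits(conc, "concentration_table")) {
    protein <- match.arg(protein)
    join_concentrations(s, conc)[[protein]]
  } else as.numeric(conc)
  X <- s$absorbance
  n <- nrow(X)
  if (is.null(k)) k <- choose_screening_ncomp(X, y)
  d <- pls_decompose(X, y, k)
  t2 <- t2_scores(d)
  q <- q_scores(d)
  t2_lim <- t2_limit(n, d$k, confidence)
  q_lim <- q_limit(d$residuals, q, confidence, q_method)
  flagged <- if (rule == "and") (t2 > t2_lim) & (q > q_lim)
             else (t2 > t2_lim) | (q > q_lim)
  if (all(flagged)) warnf("all %d spectra flagged as outliers", n)
  rep <- data.frame(spectrum_id = s$spectrum_id, t2 = t2, q = q,
                    flagged = flagged, stringsAsFactors = FALSE)
  attr(rep, "t2_limit") <- t2_lim
  attr(rep, "q_limit") <- q_lim
  attr(rep, "confidence") <- confidence
  attr(rep, "rule") <- rule
  attr(rep, "k") <- d$k
  class(rep) <- c("outlier_report", "data.frame")
  rep
}

#' Drop flagged spectra from a set
#'
#' @param s A `spectra_set`.
#' @param report An `outlier_report` from [flag_outliers()].
#' @return The surviving `spectra_set`.
#' @export
remove_outliers <- function(s, report) {
  keep <- !report$flagged[match(s$spectrum_id, report$spectrum_id)]
  subset_spectra(s, keep)
}
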