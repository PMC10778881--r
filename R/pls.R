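#' NIPALS partial least squares decomposition
#'
#' Fits a univariate-response PLS model X = T P' + E, y = X b + f by the
#' NIPALS algorithm on the column-centered data. Loadings are normalized to
#' unit Euclidean norm (scores absorb the scale), so `crossprod(P)` has unit
#' diagonal and the score variances `s_j` are directly comparable across
#' components. Regression coefficients are kept for every truncation
#' 1..k (`b_path`), which makes component-count scans cheap.
#'
#' @param X Numeric matrix, n spectra x p wavenumbers.
#' @param y Numeric response vector of length n (one protein's
#'   concentrations, mg/mL).
#' @param k Number of latent components, `1 <= k <= min(n - 1, p)`.
#' @return An object of class `pls_decomposition` with fields `scores` (T,
#'   n x k), `loadings` (P, p x k, unit columns), `weights` (W),
#'   `residuals` (E = Xc - T P'), `score_sd` (s_j), `y_loadings` (q),
#'   `coefficients` (b for k components), `b_path` (p x k), `x_center`,
#'   `y_center`, `k`, and `x_var_explained` (cumulative fraction of centered
#'   X sum of squares captured by the first j components).
#' @export
pls_decompose <- function(X, y, k) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stopf("PLS needs at least 2 rows")
  if (length(y) != n) stopf("length(y) must equal nrow(X)")
  if (k < 1 || k > min(n - 1, p))
    stopf("k = %d outside the valid range 1..min(n - 1, p) = %d",
          k, min(n - 1, p))
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2, x_center)
  yc <- y - y_center
  total_ss <- sum(Xc^2)

  Tm <- matrix(0, n, k); P <- matrix(0, p, k); W <- matrix(0, p, k)
  q <- numeric(k)
  Xd <- Xc; yd <- yc
  k_used <- k
  for (j in seq_len(k)) {
    w <- crossprod(Xd, yd)[, 1]
    wn2 <- sqrt(sum(w^2))
    if (wn2 < 1e-12 * (1 + sqrt(total_ss))) { k_used <- j - 1L; break }
    w <- w / wn2
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-24) { k_used <- j - 1L; break }
    pvec <- crossprod(Xd, t)[, 1] / tt
    qj <- sum(yd * t) / tt
    # unit-norm loading convention: scale t by ||p||, divide p and q by it
    pn <- sqrt(sum(pvec^2))
    pvec <- pvec / pn
    t <- t * pn
    qj <- qj / pn
    Xd <- Xd - tcrossprod(t, pvec)
    yd <- yd - t[, 1] * qj
    Tm[, j] <- t; P[, j] <- pvec; W[, j] <- w; q[j] <- qj
  }
  if (k_used == 0L) stopf("X carries no covariance with y; no PLS component")
  if (k_used < k) {
    warnf("PLS deflation became degenerate after %d component(s); k reduced",
          k_used)
    Tm <- Tm[, seq_len(k_used), drop = FALSE]
    P <- P[, seq_len(k_used), drop = FALSE]
    W <- W[, seq_len(k_used), drop = FALSE]
    q <- q[seq_len(k_used)]
    k <- k_used
  }

  # b for every truncation: b_j = W_j (P_j' W_j)^{-1} q_j
  PW <- crossprod(P, W)
  b_path <- matrix(0, p, k)
  for (j in seq_len(k)) {
    sol <- solve(PW[seq_len(j), seq_len(j), drop = FALSE], q[seq_len(j)])
    b_path[, j] <- W[, seq_len(j), drop = FALSE] %*% sol
  }
  comp_ss <- colSums(Tm^2)
  structure(list(
    scores = Tm, loadings = P, weights = W,
    residuals = Xd, score_sd = apply(Tm, 2, stats::sd),
    y_loadings = q, coefficients = b_path[, k],
    b_path = b_path, x_center = x_center, y_center = y_center,
    k = k,
    x_var_explained = if (total_ss > 0) cumsum(comp_ss) / total_ss
                      else rep(NA_real_, k)),
    class = "pls_decomposition")
}

#' Predict from a PLS decomposition
#'
#' @param object A [pls_decompose()] fit.
#' @param newdata Matrix with the training wavenumber count.
#' @param ncomp Component counts to predict with; a vector returns one
#'   column per requested truncation.
#' @param ... Unused.
#' @return Numeric vector (single `ncomp`) or matrix (one column per
#'   `ncomp`).
#' @export
predict.pls_decomposition <- function(object, newdata, ncomp = object$k, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_center))
    stopf("newdata has %d columns; model was trained on %d",
          ncol(newdata), length(object$x_center))
  if (any(ncomp < 1 | ncomp > object$k))
    stopf("ncomp outside fitted range 1..%d", object$k)
  Xc <- sweep(newdata, 2, object$x_center)
  out <- Xc %*% object$b_path[, ncomp, drop = FALSE] + object$y_center
  if (length(ncomp) == 1L) as.numeric(out) else out
}

#' Hotelling T-squared statistics of a PLS decomposition
#'
#' For spectrum i, `T2_i = sum_j t_{ij}^2 / s_j^2`: the squared Mahalanobis
#' distance of its latent scores from the model center, standardized by the
#' per-component score standard deviations. Large values mark spectra that
#' are extreme inside the model space.
#'
#' @param d A `pls_decomposition`.
#' @return Non-negative numeric vector, one value per spectrum.
#' @export
t2_scores <- function(d) {
  stopifnot(inherits(d, "pls_decomposition"))
  rowSums(sweep(d$scores, 2, d$score_sd, "/")^2)
}

#' Q-residual statistics of a PLS decomposition
#'
#' For spectrum i, `Q_i = e_i' e_i`: the squared norm of its row of the
#' residual matrix E = X - T P'. Large values mark spectra the model space
#' does not describe.
#'
#' @param d A `pls_decomposition`.
#' @return Non-negative numeric vector, one value per spectrum.
#' @export
q_scores <- function(d) {
  stopifnot(inherits(d, "pls_decomposition"))
  rowSums(d$residuals^2)
}
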