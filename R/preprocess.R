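#' Row/column scaling of spectra
#'
#' `"normalize"` scales each spectrum (row) to unit Euclidean norm and is
#' stateless. `"mean_center"` subtracts per-wavenumber column means; the
#' means are learned from the calibration matrix and re-applied to any
#' validation matrix through `state`, so validation rows never contribute
#' statistics.
#'
#' @param X Spectra matrix.
#' @param method `"normalize"` or `"mean_center"`.
#' @param state Fitted state from a previous call (calibration column
#'   means); `NULL` fits a fresh state.
#' @return A list with the transformed matrix `X` and the fitted `state`.
#' @export
scale_spectra <- function(X, method = c("normalize", "mean_center"),
                          state = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (method == "normalize") {
    norms <- sqrt(rowSums(X^2))
    if (any(norms == 0))
      stopf("cannot normalize zero-norm spectrum (row %d)",
            which(norms == 0)[1])
    return(list(X = X / norms, state = NULL))
  }
  if (is.null(state)) state <- list(center = colMeans(X))
  if (length(state$center) != ncol(X))
    stopf("mean-center state has %d columns, X has %d",
          length(state$center), ncol(X))
  list(X = sweep(X, 2, state$center), state = state)
}

snv_rows <- function(X) {
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  if (any(sdv == 0))
    stopf("SNV undefined for constant spectrum (row %d)", which(sdv == 0)[1])
  (X - mu) / sdv
}

#' Scatter and baseline correction of spectra
#'
#' Row-operating corrections for multiplicative scatter and baseline drift:
#' \describe{
#'   \item{snv}{standard normal variate: each row to mean 0, sample SD 1.}
#'   \item{rnv}{robust normal variate: `(x - q_lo) / (q_hi - q_lo)` with
#'     percentiles `params$percentiles` (default 25/75, i.e. the IQR).}
#'   \item{lsnv}{local SNV: SNV applied within contiguous wavenumber
#'     windows of `params$window` points (default 151).}
#'   \item{msc}{multiplicative scatter correction: each row regressed on
#'     the calibration mean spectrum, corrected as `(x - b) / a`.}
#'   \item{emsc}{extended MSC: the regression additionally carries a
#'     polynomial (order `params$order`, default 2) in the wavenumber, and
#'     the fitted polynomial baseline is removed before the gain division.}
#'   \item{baseline}{polynomial detrend (order `params$order`, default 2):
#'     each row's least-squares polynomial in the wavenumber is subtracted.}
#' }
#' MSC/EMSC learn their reference spectrum from the calibration matrix;
#' the other methods are stateless.
#'
#' @param X Spectra matrix.
#' @param method One of `"snv"`, `"rnv"`, `"lsnv"`, `"msc"`, `"emsc"`,
#'   `"baseline"`.
#' @param params Method parameters, see above.
#' @param state Fitted state (MSC/EMSC reference) or `NULL` to fit.
#' @param wavenumbers Axis values; needed by `emsc`/`baseline`, otherwise
#'   the column index is used.
#' @return A list with the corrected matrix `X` and the fitted `state`.
#' @export
scatter_correct <- function(X,
                            method = c("snv", "rnv", "lsnv", "msc", "emsc",
                                       "baseline"),
                            params = list(), state = NULL,
                            wavenumbers = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  p <- ncol(X)
  z <- if (is.null(wavenumbers)) seq_len(p) else as.numeric(wavenumbers)
  z <- 2 * (z - min(z)) / max(diff(range(z)), 1) - 1

  if (method == "snv") return(list(X = snv_rows(X), state = NULL))

  if (method == "rnv") {
    pc <- params$percentiles %||% c(25, 75)
    lo <- apply(X, 1, stats::quantile, probs = min(pc) / 100, type = 7)
    hi <- apply(X, 1, stats::quantile, probs = max(pc) / 100, type = 7)
    if (any(hi - lo == 0))
      stopf("RNV undefined: zero interquantile range (row %d)",
            which(hi - lo == 0)[1])
    return(list(X = (X - lo) / (hi - lo), state = NULL))
  }

  if (method == "lsnv") {
    w <- params$window %||% 151L
    nseg <- max(1L, as.integer(round(p / w)))
    seg <- split(seq_len(p), ceiling(seq_len(p) / (p / nseg)))
    out <- X
    for (idx in seg) out[, idx] <- snv_rows(X[, idx, drop = FALSE])
    return(list(X = out, state = NULL))
  }

  if (method == "baseline") {
    ord <- params$order %||% 2L
    D <- cbind(1, stats::poly(z, ord))
    coefs <- X %*% D %*% solve(crossprod(D))
    return(list(X = X - tcrossprod(coefs, D), state = NULL))
  }

  # msc / emsc share the reference-spectrum state
  if (is.null(state)) state <- list(reference = colMeans(X))
  ref <- state$reference
  if (length(ref) != p)
    stopf("scatter-correction reference has %d points, X has %d",
          length(ref), p)
  if (stats::sd(ref) < 1e-10 * (1 + max(abs(ref))))
    stopf("%s reference spectrum has (near-)zero variance; %s",
          toupper(method),
          "the correction is undefined after mean-centering")
  if (method == "msc") {
    a <- (X %*% (ref - mean(ref))) / sum((ref - mean(ref))^2)
    b <- rowMeans(X) - a * mean(ref)
    if (any(a == 0)) stopf("MSC gain of zero (row %d)", which(a == 0)[1])
    return(list(X = (X - as.numeric(b)) / as.numeric(a), state = state))
  }
  # emsc
  ord <- params$order %||% 2L
  D <- cbind(1, stats::poly(z, ord), ref)
  coef <- t(solve(crossprod(D), crossprod(D, t(X))))  # n x (ord + 2)
  a <- coef[, ncol(coef)]
  if (any(a == 0)) stopf("EMSC gain of zero (row %d)", which(a == 0)[1])
  base <- tcrossprod(coef[, -ncol(coef), drop = FALSE],
                     D[, -ncol(D), drop = FALSE])
  list(X = (X - base) / a, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Savitzky-Golay filtering of spectra
#'
#' Row-wise local polynomial smoothing/differentiation. At
#' `deriv_order = 0` any polynomial of degree <= `poly_order` is reproduced
#' exactly at interior points; `deriv_order` 1 or 2 returns the derivative
#' per index step.
#'
#' @param X Spectra matrix.
#' @param filter_win Odd window length, `> poly_order` and
#'   `<= n_wavenumbers`.
#' @param poly_order Local polynomial degree.
#' @param deriv_order Derivative order, 0, 1 or 2 (<= `poly_order`).
#' @return Filtered matrix of the same shape.
#' @export
savgol <- function(X, filter_win, poly_order, deriv_order = 0L) {
  X <- as.matrix(X)
  if (filter_win %% 2 == 0) stopf("filter_win must be odd, got %d", filter_win)
  if (filter_win <= poly_order)
    stopf("filter_win (%d) must exceed poly_order (%d)",
          filter_win, poly_order)
  if (filter_win > ncol(X))
    stopf("filter_win (%d) exceeds the %d wavenumbers", filter_win, ncol(X))
  if (!deriv_order %in% 0:2) stopf("deriv_order must be 0, 1 or 2")
  if (deriv_order > poly_order)
    stopf("deriv_order (%d) exceeds poly_order (%d)", deriv_order, poly_order)
  t(apply(X, 1, signal::sgolayfilt, p = poly_order, n = filter_win,
          m = deriv_order, ts = 1))
}

#' Define an ordered preprocessing pipeline
#'
#' Stage order is fixed: (1) scaling, (2) scatter/baseline correction,
#' (3) Savitzky-Golay smoothing; any stage may be skipped. Fitting learns
#' stage state (column means, MSC reference) from the calibration matrix
#' only.
#'
#' @param scale Character vector of scaling steps applied in order, drawn
#'   from `"normalize"`, `"mean_center"`; `character(0)` or `"none"` skips.
#' @param scatter `"none"`, a method name accepted by [scatter_correct()],
#'   or a list `list(method =, params =)`.
#' @param savgol `"none"` or a list
#'   `list(filter_win =, poly_order =, deriv_order =)`.
#' @return A `pipeline_spec` object.
#' @export
pipeline_spec <- function(scale = character(0), scatter = "none",
                          savgol = "none") {
  if (identical(scale, "none")) scale <- character(0)
  if (is.character(scatter) && !identical(scatter, "none"))
    scatter <- list(method = scatter, params = list())
  spec <- structure(list(scale = scale, scatter = scatter, savgol = savgol),
                    class = "pipeline_spec")
  spec
}

#' @export
format.pipeline_spec <- function(x, ...) {
  parts <- character(0)
  if (length(x$scale))
    parts <- c(parts, vapply(x$scale, function(m)
      switch(m, mean_center = "MC", normalize = "normalize", m), ""))
  if (!identical(x$scatter, "none"))
    parts <- c(parts, toupper(x$scatter$method))
  if (!identical(x$savgol, "none"))
    parts <- c(parts, sprintf("SavGol(%d,%d,%d)", x$savgol$filter_win,
                              x$savgol$poly_order, x$savgol$deriv_order))
  if (!length(parts)) parts <- "raw"
  paste(parts, collapse = " + ")
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat("pipeline_spec:", format(x), "\n")
  invisible(x)
}

#' Fit a preprocessing pipeline on calibration spectra
#'
#' @param spec A [pipeline_spec()].
#' @param X Calibration spectra matrix.
#' @param wavenumbers Optional axis for wavenumber-aware stages.
#' @return A `fitted_pipeline` holding the spec, the learned per-stage
#'   state, and the transformed calibration matrix in `$X`.
#' @export
fit_pipeline <- function(spec, X, wavenumbers = NULL) {
  state <- list(scale = vector("list", length(spec$scale)), scatter = NULL)
  cur <- as.matrix(X)
  for (i in seq_along(spec$scale)) {
    r <- scale_spectra(cur, spec$scale[i], state = NULL)
    cur <- r$X; state$scale[[i]] <- r$state
  }
  if (!identical(spec$scatter, "none")) {
    r <- scatter_correct(cur, spec$scatter$method, spec$scatter$params,
                         state = NULL, wavenumbers = wavenumbers)
    cur <- r$X; state$scatter <- r$state
  }
  if (!identical(spec$savgol, "none"))
    cur <- savgol(cur, spec$savgol$filter_win, spec$savgol$poly_order,
                  spec$savgol$deriv_order %||% 0L)
  structure(list(spec = spec, state = state, wavenumbers = wavenumbers,
                 X = cur),
            class = "fitted_pipeline")
}

#' Apply a fitted pipeline to new spectra
#'
#' Uses only calibration-fitted state; the transform of a validation row
#' never depends on the other validation rows.
#'
#' @param fp A `fitted_pipeline` from [fit_pipeline()].
#' @param X New spectra matrix with the training wavenumber count.
#' @return Transformed matrix.
#' @export
apply_pipeline <- function(fp, X) {
  spec <- fp$spec
  cur <- as.matrix(X)
  for (i in seq_along(spec$scale))
    cur <- scale_spectra(cur, spec$scale[i], state = fp$state$scale[[i]])$X
  if (!identical(spec$scatter, "none"))
    cur <- scatter_correct(cur, spec$scatter$method, spec$scatter$params,
                           state = fp$state$scatter,
                           wavenumbers = fp$wavenumbers)$X
  if (!identical(spec$savgol, "none"))
    cur <- savgol(cur, spec$savgol$filter_win, spec$savgol$poly_order,
                  spec$savgol$deriv_order %||% 0L)
  cur
}

#' Enumerate every pipeline in a per-stage option grid
#'
#' The Cartesian product in the fixed stage order. A skip-scatter path is
#' always added, so the count is
#' `|scale options| * (|scatter options| + 1) * |savgol options|`.
#'
#' @param space A list with elements `scale` (list of character vectors),
#'   `scatter` (list of method names or `list(method =, params =)`), and
#'   `savgol` (list of `"none"` or SavGol parameter lists).
#' @return List of [pipeline_spec()] objects in deterministic order
#'   (scale outermost, savgol innermost).
#' @export
enumerate_pipelines <- function(space) {
  if (!length(space$scale) || !length(space$savgol))
    stopf("every stage grid must be non-empty")
  scatters <- c(list("none"), space$scatter)
  out <- list()
  for (sc in space$scale)
    for (ct in scatters)
      for (sg in space$savgol)
        out[[length(out) + 1L]] <- pipeline_spec(sc, ct, sg)
  out
}

#' Default preprocessing search grid
#'
#' 2 scaling options (normalize; mean-center then normalize) x
#' (6 scatter/baseline corrections + skip) x (10 Savitzky-Golay windows x
#' 3 polynomial orders + skip) = 434 candidate chains.
#'
#' @return A space list for [enumerate_pipelines()].
#' @export
default_pipeline_space <- function() {
  wins <- c(19L, 39L, 59L, 77L, 99L, 115L, 131L, 151L, 171L, 191L)
  sg <- list("none")
  for (w in wins)
    for (po in 1:3)
      sg[[length(sg) + 1L]] <- list(filter_win = w, poly_order = po,
                                    deriv_order = 0L)
  list(scale = list("normalize", c("mean_center", "normalize")),
       scatter = list("snv", "rnv", "lsnv", "msc", "emsc", "baseline"),
       savgol = sg)
}

#' Search for the best preprocessing pipeline
#'
#' For every candidate chain: fit on the calibration spectra, transform the
#' validation spectra with calibration state only, fit PLS per component
#' count for each protein, and score validation R-squared. A chain's score
#' is the per-component-count aggregate (`min` of the two proteins by
#' default, `mean` optionally) maximized over the component range; ties are
#' broken by the smaller component count, then by grid order. Chains that
#' fail on the data (e.g. an SNV zero-variance row) are recorded as failed
#' and the search continues.
#'
#' @param cal,val Lists with `X` (spectra matrix) and `Y` (two-column
#'   matrix, beta-lactoglobulin then alpha-lactalbumin).
#' @param space Option grid, default [default_pipeline_space()].
#' @param ncomp_range PLS component counts to scan (default 1..20).
#' @param wavenumbers Optional axis for wavenumber-aware stages.
#' @param aggregate `"min"` (conservative joint score) or `"mean"`.
#' @return A `search_result` list: `results` data.frame (pipeline label,
#'   r2_beta_lg, r2_alpha_la, ncomp, score, failed), `winner` (row index),
#'   `pipelines` (the spec list), `fitted_winner` (the winning
#'   `fitted_pipeline`).
#' @export
search_best_pipeline <- function(cal, val, space = default_pipeline_space(),
                                 ncomp_range = 1:20, wavenumbers = NULL,
                                 aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  if (nrow(cal$X) == nrow(val$X) && isTRUE(all.equal(cal$X, val$X)))
    warnf("calibration and validation matrices are identical")
  specs <- enumerate_pipelines(space)
  kmax <- min(max(ncomp_range), nrow(cal$X) - 1L)
  res <- data.frame(pipeline = vapply(specs, format, ""),
                    r2_beta_lg = NA_real_, r2_alpha_la = NA_real_,
                    ncomp = NA_integer_, score = NA_real_, failed = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(specs)) {
    r <- tryCatch({
      fp <- fit_pipeline(specs[[i]], cal$X, wavenumbers)
      Xv <- apply_pipeline(fp, val$X)
      r2 <- sapply(1:2, function(j) {
        d <- suppressWarnings(pls_decompose(fp$X, cal$Y[, j], kmax))
        ks <- ncomp_range[ncomp_range <= d$k]
        pred <- predict(d, Xv, ncomp = ks)
        apply(as.matrix(pred), 2, function(yh)
          evaluate_predictions(val$Y[, j], yh)$r2)
      })
      r2 <- as.matrix(r2)
      agg <- if (aggregate == "min") pmin(r2[, 1], r2[, 2])
             else rowMeans(r2)
      best <- which.max(agg)  # first max = smallest ncomp on ties
      list(r2b = r2[best, 1], r2a = r2[best, 2],
           ncomp = ncomp_range[ncomp_range <= kmax][best], score = agg[best])
    }, error = function(e) NULL)
    if (is.null(r)) { res$failed[i] <- TRUE; next }
    res$r2_beta_lg[i] <- r$r2b; res$r2_alpha_la[i] <- r$r2a
    res$ncomp[i] <- r$ncomp; res$score[i] <- r$score
  }
  ok <- which(!res$failed)
  if (!length(ok)) stopf("every candidate pipeline failed")
  ord <- ok[order(-res$score[ok], res$ncomp[ok], ok)]
  winner <- ord[1]
  structure(list(results = res, winner = winner, pipelines = specs,
                 fitted_winner = fit_pipeline(specs[[winner]], cal$X,
                                              wavenumbers)),
            class = "search_result")
}
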