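#' Prediction metrics: R-squared and RMSE
#'
#' `r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` and
#' `rmse = sqrt(mean((y - yhat)^2))`, in the units of `y` (mg/mL). On an
#' external validation set these are the RMSEP and R2P of the model. R2 is
#' reported as computed - a badly extrapolating model yields a large
#' negative value, never clipped.
#'
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#' @return A list with `r2` and `rmse`.
#' @export
evaluate_predictions <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat) || length(y) < 2)
    stopf("y and yhat must have equal length >= 2")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stopf("R-squared undefined: y has zero variance")
  list(r2 = 1 - sum((y - yhat)^2) / ss_tot,
       rmse = sqrt(mean((y - yhat)^2)))
}

#' Define a calibration model
#'
#' Supported families and parameters:
#' \describe{
#'   \item{pls}{`n_components` latent variables (NIPALS).}
#'   \item{svr}{epsilon-insensitive support vector regression
#'     (`C`, `epsilon`, `kernel` in linear/rbf/poly, `gamma`, `degree`);
#'     inputs are standardized column-wise with calibration statistics
#'     before the solver so the C/gamma scales are comparable across
#'     preprocessing choices.}
#'   \item{ridge}{L2-regularized linear regression minimizing
#'     `||Xw - y||^2 + alpha ||w||^2` (`alpha`, `fit_intercept`; a `solver`
#'     label is accepted and recorded for provenance but the exact
#'     closed-form/dual solution is always used).}
#'   \item{lr}{ordinary least squares; with more wavenumbers than spectra
#'     the minimum-norm solution is returned, which interpolates the
#'     training data and can extrapolate catastrophically - by design this
#'     failure mode is surfaced, not masked.}
#' }
#'
#' @param family `"pls"`, `"svr"`, `"ridge"` or `"lr"`.
#' @param ... Family parameters, see above.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("pls", "svr", "ridge", "lr"), ...) {
  family <- match.arg(family)
  params <- list(...)
  defaults <- switch(family,
    pls = list(n_components = 10L),
    svr = list(C = 1, epsilon = 0.1, kernel = "linear", gamma = NULL,
               degree = 3L),
    ridge = list(alpha = 1, fit_intercept = TRUE, solver = "closed_form"),
    lr = list(fit_intercept = TRUE))
  params <- utils::modifyList(defaults, params)
  structure(list(family = family, params = params), class = "model_spec")
}

# Ridge solution for 0.5-free objective ||Xw - y||^2 + alpha ||w||^2.
# Uses the primal normal equations when p <= n, the exact dual form
# X'(XX' + alpha I)^{-1} y when p > n; alpha = 0 with p > n gives the
# minimum-norm least-squares solution.
ridge_coef <- function(X, y, alpha) {
  n <- nrow(X); p <- ncol(X)
  if (alpha == 0) return(as.numeric(MASS::ginv(X) %*% y))
  if (p <= n) {
    as.numeric(solve(crossprod(X) + diag(alpha, p), crossprod(X, y)))
  } else {
    as.numeric(crossprod(X, solve(tcrossprod(X) + diag(alpha, n), y)))
  }
}

#' Fit a calibration model
#'
#' One model per target protein; `y` is a single concentration vector.
#'
#' @param spec A [model_spec()].
#' @param X Calibration spectra matrix.
#' @param y Concentration vector.
#' @return A `fitted_model` exposing the learned parameters
#'   (`coefficients`/`intercept` for the linear families, the PLS
#'   decomposition, or the svm object) plus the input standardization used.
#' @export
fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) < 2) stopf("need at least 2 calibration rows")
  if (!all(is.finite(X))) stopf("X must be finite")
  pr <- spec$params
  fm <- list(spec = spec, p = ncol(X))
  if (spec$family == "pls") {
    if (pr$n_components > min(nrow(X) - 1L, ncol(X)))
      stopf("n_components = %d exceeds min(n - 1, p) = %d",
            pr$n_components, min(nrow(X) - 1L, ncol(X)))
    fm$pls <- pls_decompose(X, y, pr$n_components)
  } else if (spec$family == "svr") {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    kern <- switch(pr$kernel, linear = "linear", rbf = "radial",
                   poly = "polynomial",
                   stopf("unknown SVR kernel: %s", pr$kernel))
    gamma <- pr$gamma %||% (1 / ncol(X))
    fm$center <- ctr; fm$scale <- scl
    fm$svm <- e1071::svm(Xs, y, type = "eps-regression", kernel = kern,
                         cost = pr$C, epsilon = pr$epsilon, gamma = gamma,
                         degree = pr$degree, scale = FALSE)
  } else {  # ridge / lr
    alpha <- if (spec$family == "ridge") pr$alpha else 0
    if (alpha < 0) stopf("ridge alpha must be non-negative")
    if (isTRUE(pr$fit_intercept)) {
      xc <- colMeans(X); yc <- mean(y)
      w <- ridge_coef(sweep(X, 2, xc), y - yc, alpha)
      fm$coefficients <- w
      fm$intercept <- yc - sum(xc * w)
    } else {
      fm$coefficients <- ridge_coef(X, y, alpha)
      fm$intercept <- 0
    }
  }
  class(fm) <- "fitted_model"
  fm
}

#' Predict concentrations from a fitted model
#'
#' @param object A [fit_model()] result.
#' @param newdata Spectra matrix with the training wavenumber count.
#' @param ... Unused.
#' @return Numeric prediction vector.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stopf("newdata has %d columns; model was trained on %d",
          ncol(newdata), object$p)
  fam <- object$spec$family
  if (fam == "pls")
    return(predict(object$pls, newdata))
  if (fam == "svr") {
    Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
    return(as.numeric(stats::predict(object$svm, Xs)))
  }
  as.numeric(newdata %*% object$coefficients + object$intercept)
}

#' Hyperparameter search spaces for the four model families
#'
#' The tuner's default spaces: SVR `C` loguniform(5e-3, 1e3), `epsilon`
#' uniform(0.01, 0.9), `kernel` in linear/rbf/poly, `degree` in 1..4,
#' `gamma` loguniform(1e-5, 1e5); ridge `alpha` loguniform(1e-5, 10) with
#' `fit_intercept` in TRUE/FALSE; LR `fit_intercept`; PLS `n_components`
#' in 1..20.
#'
#' @return Named list of per-family spaces for [tune_model()].
#' @export
default_search_spaces <- function() {
  list(
    svr = list(C = list(type = "loguniform", lo = 5e-3, hi = 1e3),
               epsilon = list(type = "uniform", lo = 0.01, hi = 0.9),
               kernel = list(type = "categorical",
                             values = c("linear", "rbf", "poly")),
               degree = list(type = "categorical", values = 1:4),
               gamma = list(type = "loguniform", lo = 1e-5, hi = 1e5)),
    ridge = list(alpha = list(type = "loguniform", lo = 1e-5, hi = 10),
                 fit_intercept = list(type = "categorical",
                                      values = c(TRUE, FALSE))),
    lr = list(fit_intercept = list(type = "categorical",
                                   values = c(TRUE, FALSE))),
    pls = list(n_components = list(type = "int", lo = 1L, hi = 20L)))
}

#' Reference optimal hyperparameters
#'
#' Hyperparameter values reported as optimal for the original instrument
#' dataset this workflow was developed on, shipped for documentation and
#' as a starting configuration. They are data-dependent and are not
#' expected to be optimal on other (or synthetic) data.
#'
#' @return Named list of [model_spec()]s per protein.
#' @export
reference_hyperparameters <- function() {
  list(beta_lg = list(
         svr = model_spec("svr", C = 792.3681, epsilon = 0.0311,
                          gamma = 0.0126, degree = 3L, kernel = "linear"),
         ridge = model_spec("ridge", alpha = 0.00078, solver = "lsqr"),
         pls = model_spec("pls", n_components = 14L),
         lr = model_spec("lr")),
       alpha_la = list(
         svr = model_spec("svr", C = 96.3447, epsilon = 0.01069,
                          gamma = 284.4739, degree = 1L, kernel = "linear"),
         ridge = model_spec("ridge", alpha = 0.00095, solver = "sparse_cg"),
         pls = model_spec("pls", n_components = 14L),
         lr = model_spec("lr")))
}

sample_param <- function(def) {
  switch(def$type,
    loguniform = exp(stats::runif(1, log(def$lo), log(def$hi))),
    uniform = stats::runif(1, def$lo, def$hi),
    int = sample(seq.int(def$lo, def$hi), 1L),
    categorical = def$values[[sample.int(length(def$values), 1L)]],
    stopf("unknown search-space type: %s", def$type))
}

#' Budgeted random-search hyperparameter tuning
#'
#' Samples `budget` parameter sets from the space (loguniform / uniform /
#' integer / categorical per dimension), scores each by mean RMSE over
#' `nfolds`-fold cross-validation on the calibration data (folds fixed by
#' `seed`), and returns the best spec with the full trial log.
#'
#' @param family Model family, see [model_spec()].
#' @param X,y Calibration data.
#' @param space Search space (default from [default_search_spaces()]).
#' @param budget Number of trials.
#' @param nfolds CV folds for the objective.
#' @param seed Seed fixing both the sampling stream and the folds.
#' @return A list with `best_spec`, `best_rmse` and `trials` (data.frame,
#'   one row per trial with its parameters and CV RMSE).
#' @export
tune_model <- function(family, X, y, space = NULL, budget = 25L,
                       nfolds = 5L, seed = 1L) {
  if (is.null(space)) space <- default_search_spaces()[[family]]
  for (d in space)
    if (!is.null(d$lo) && !is.null(d$hi) && d$lo >= d$hi)
      stopf("invalid search space: lo >= hi")
  if (budget < 1) stopf("budget must be at least 1")
  X <- as.matrix(X); y <- as.numeric(y)
  folds <- make_folds(nrow(X), nfolds, seed)
  trials <- vector("list", budget)
  with_seed(derive_seed(seed, 1L), {
    for (t in seq_len(budget)) {
      pars <- lapply(space, sample_param)
      if (family == "pls")
        pars$n_components <- min(pars$n_components,
                                 nrow(X) - max(lengths(folds)) - 1L, ncol(X))
      spec <- do.call(model_spec, c(list(family = family), pars))
      se <- unlist(lapply(folds, function(f) {
        m <- tryCatch(fit_model(spec, X[-f, , drop = FALSE], y[-f]),
                      error = function(e) NULL)
        if (is.null(m)) return(rep(NA_real_, length(f)))
        (predict(m, X[f, , drop = FALSE]) - y[f])^2
      }))
      rmse <- if (anyNA(se)) Inf else sqrt(mean(se))
      trials[[t]] <- data.frame(trial = t,
                                lapply(pars, function(v)
                                  if (is.numeric(v) || is.logical(v)) v
                                  else as.character(v)),
                                cv_rmse = rmse)
    }
  })
  log <- do.call(rbind, trials)
  best <- which.min(log$cv_rmse)
  pars <- as.list(log[best, setdiff(names(log), c("trial", "cv_rmse")),
                      drop = FALSE])
  list(best_spec = do.call(model_spec, c(list(family = family), pars)),
       best_rmse = log$cv_rmse[best], trials = log)
}

# Fit/evaluate one model on one train/validation index pair, with optional
# preprocessing pipeline (fit on train only) and wavenumber mask.
eval_split <- function(spec, X, y, train, val, pipeline = NULL,
                       mask = NULL, wavenumbers = NULL) {
  Xtr <- X[train, , drop = FALSE]; Xva <- X[val, , drop = FALSE]
  if (!is.null(pipeline)) {
    fp <- fit_pipeline(pipeline, Xtr, wavenumbers)
    Xtr <- fp$X; Xva <- apply_pipeline(fp, Xva)
  }
  if (!is.null(mask)) {
    Xtr <- Xtr[, mask, drop = FALSE]; Xva <- Xva[, mask, drop = FALSE]
  }
  m <- fit_model(spec, Xtr, y[train])
  predict(m, Xva)
}

#' Compare calibration models across partitioning schemes
#'
#' Evaluates each model family for each protein under four schemes:
#' Kennard-Stone split (`KS`), random split (`RS`), leave-one-replicate-out
#' (`LORO`) and leave-one-sample-out (`LOSO`) cross-validation. For the
#' CV schemes, out-of-fold predictions are pooled before computing R2 and
#' RMSE. An optional preprocessing pipeline is re-fit on every training
#' portion (never on held-out spectra) and an optional per-protein
#' wavenumber mask restricts the input columns after preprocessing.
#'
#' @param s A `spectra_set`.
#' @param conc A [concentration_table()].
#' @param specs Named list mapping family label to either a [model_spec()]
#'   (used for both proteins) or a list with per-protein specs
#'   `list(beta_lg =, alpha_la =)`.
#' @param pipeline Optional [pipeline_spec()].
#' @param masks Optional list `list(beta_lg =, alpha_la =)` of column
#'   index vectors (after preprocessing).
#' @param validation_fraction Held-out fraction for KS and RS.
#' @param seed Seed for the random split.
#' @param schemes Subset of `c("KS", "RS", "LORO", "LOSO")`.
#' @return A data.frame with columns `model`, `protein`, `scheme`, `r2`,
#'   `rmse`.
#' @export
run_model_comparison <- function(s, conc, specs, pipeline = NULL,
                                 masks = NULL, validation_fraction = 0.30,
                                 seed = 1L,
                                 schemes = c("KS", "RS", "LORO", "LOSO")) {
  validate_spectra_set(s)
  yj <- join_concentrations(s, conc)
  X <- s$absorbance
  ids <- s$spectrum_id
  split_list <- list()
  if ("KS" %in% schemes)
    split_list$KS <- ks_split(s, conc, basis = "spectra",
                              validation_fraction = validation_fraction)
  if ("RS" %in% schemes)
    split_list$RS <- random_split(ids, validation_fraction, seed = seed)
  fold_list <- list()
  if ("LORO" %in% schemes) fold_list$LORO <- cv_folds(s, "LORO")
  if ("LOSO" %in% schemes) fold_list$LOSO <- cv_folds(s, "LOSO")

  rows <- list()
  for (model in names(specs)) {
    for (protein in c("beta_lg", "alpha_la")) {
      spec <- specs[[model]]
      if (!inherits(spec, "model_spec")) spec <- spec[[protein]]
      y <- yj[[protein]]
      mask <- if (!is.null(masks)) masks[[protein]] else NULL
      for (scheme in names(split_list)) {
        sp <- split_list[[scheme]]
        tr <- match(sp$calibration_ids, ids)
        va <- match(sp$validation_ids, ids)
        pred <- eval_split(spec, X, y, tr, va, pipeline, mask,
                           s$wavenumbers)
        met <- evaluate_predictions(y[va], pred)
        rows[[length(rows) + 1L]] <-
          data.frame(model = model, protein = protein, scheme = scheme,
                     r2 = met$r2, rmse = met$rmse)
      }
      for (scheme in names(fold_list)) {
        plan <- fold_list[[scheme]]
        pred <- rep(NA_real_, length(ids))
        for (fold in plan$folds) {
          tr <- match(fold$train, ids); va <- match(fold$validation, ids)
          pred[va] <- eval_split(spec, X, y, tr, va, pipeline, mask,
                                 s$wavenumbers)
        }
        keep <- !is.na(pred)
        met <- evaluate_predictions(y[keep], pred[keep])
        rows[[length(rows) + 1L]] <-
          data.frame(model = model, protein = protein, scheme = scheme,
                     r2 = met$r2, rmse = met$rmse)
      }
    }
  }
  do.call(rbind, rows)
}
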