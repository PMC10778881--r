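test_that("metrics follow their definitions", {
  expect_equal(evaluate_predictions(1:3, 1:3), list(r2 = 1, rmse = 0))
  # constant-mean prediction has R2 = 0
  y <- c(2, 4, 6, 8)
  m0 <- evaluate_predictions(y, rep(mean(y), 4))
  expect_equal(m0$r2, 0)
  # hand arithmetic
  m <- evaluate_predictions(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(m$r2, 0.5, tolerance = 1e-12)
  expect_error(evaluate_predictions(c(1, 1), c(1, 2)), "zero variance")
})

test_that("ridge reduces to OLS at alpha 0 and solves the stated objective", {
  set.seed(20)
  X <- matrix(rnorm(30 * 4), 30)
  y <- X %*% c(1, -2, 0.5, 3) + rnorm(30, sd = 0.1) + 2
  ols <- lm.fit(cbind(1, X), as.numeric(y))$coefficients
  m0 <- fit_model(model_spec("ridge", alpha = 0), X, y)
  expect_equal(unname(c(m0$intercept, m0$coefficients)), unname(ols),
               tolerance = 1e-8)
  # alpha > 0: coefficients minimize ||Xw - y||^2 + alpha ||w||^2
  # (independent numerical optimizer as the oracle)
  alpha <- 0.7
  m1 <- fit_model(model_spec("ridge", alpha = alpha, fit_intercept = FALSE),
                  X, y)
  obj <- function(w) sum((X %*% w - y)^2) + alpha * sum(w^2)
  opt <- optim(rep(0, 4), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(m1$coefficients, opt$par, tolerance = 1e-5)
  expect_lte(obj(m1$coefficients), opt$value + 1e-8)
})

test_that("ridge coefficients shrink monotonically with alpha and the dual
           form agrees with the primal", {
  set.seed(21)
  X <- matrix(rnorm(12 * 8), 12)
  y <- rnorm(12)
  alphas <- c(1e-3, 1e-2, 1e-1, 1, 10)
  norms <- vapply(alphas, function(a) {
    m <- fit_model(model_spec("ridge", alpha = a, fit_intercept = FALSE),
                   X, y)
    sqrt(sum(m$coefficients^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  # p > n path (dual) equals the direct regularized normal equations
  Xw <- matrix(rnorm(6 * 15), 6)
  yw <- rnorm(6)
  md <- fit_model(model_spec("ridge", alpha = 0.5, fit_intercept = FALSE),
                  Xw, yw)
  direct <- solve(crossprod(Xw) + diag(0.5, 15), crossprod(Xw, yw))
  expect_equal(md$coefficients, as.numeric(direct), tolerance = 1e-8)
})

test_that("linear SVR recovers a noiseless linear relationship", {
  set.seed(22)
  X <- matrix(runif(40, -2, 2), ncol = 1)
  y <- 2 * X[, 1] + 1
  m <- fit_model(model_spec("svr", kernel = "linear", C = 1000,
                            epsilon = 0.001), X, y)
  pred <- predict(m, X)
  expect_lt(max(abs(pred - y)), 0.01)
})

test_that("PLS interpolates noiseless linear data at full rank", {
  gen <- small_dataset(seed = 23, n_samples = 10, reps = 1, n_points = 50,
                       scatter_sd = 0, baseline_sd = 0, noise_sd = 0)
  X <- gen$spectra$absorbance
  y <- join_concentrations(gen$spectra, gen$truth$concentrations)$beta_lg
  m <- suppressWarnings(fit_model(model_spec("pls", n_components = 5),
                                  X, y))
  expect_equal(predict(m, X), y, tolerance = 1e-6)
  expect_error(fit_model(model_spec("pls", n_components = 40), X, y),
               "exceeds")
})

test_that("prediction linear algebra and contracts", {
  set.seed(24)
  X <- matrix(c(1, 2, 0, 1, 3, 1), nrow = 3)
  y <- c(1, 2, 3)
  m <- fit_model(model_spec("ridge", alpha = 0.1), X, y)
  # manual matrix product on a 3x2 toy
  manual <- as.numeric(X %*% m$coefficients + m$intercept)
  expect_equal(predict(m, X), manual, tolerance = 1e-12)
  # a no-intercept linear model is homogeneous
  m2 <- fit_model(model_spec("lr", fit_intercept = FALSE), X, y)
  expect_equal(predict(m2, 2 * X), 2 * predict(m2, X), tolerance = 1e-10)
  expect_error(predict(m, matrix(0, 2, 5)), "columns")
})

test_that("minimum-norm LR surfaces its p >> n failure mode unclipped", {
  gen <- small_dataset(seed = 25, n_samples = 12, reps = 2, n_points = 300)
  s <- gen$spectra
  y <- join_concentrations(s, gen$truth$concentrations)$beta_lg
  plan <- cv_folds(s, "LOSO")
  pred <- rep(NA_real_, n_spectra(s))
  for (f in plan$folds) {
    tr <- match(f$train, s$spectrum_id)
    va <- match(f$validation, s$spectrum_id)
    m <- fit_model(model_spec("lr"), s$absorbance[tr, ], y[tr])
    # training interpolation is exact for minimum-norm least squares
    expect_lt(max(abs(predict(m, s$absorbance[tr, ]) - y[tr])), 1e-6)
    pred[va] <- predict(m, s$absorbance[va, ])
  }
  met <- evaluate_predictions(y, pred)
  expect_true(is.finite(met$r2))
  # the reported value is whatever the arithmetic yields - typically far
  # below the R2 of a regularized model on the same folds
  mr <- fit_model(model_spec("ridge", alpha = 1e-2), s$absorbance, y)
  expect_lt(met$r2, 1)
})

test_that("tuner samples inside the declared spaces and beats the median
           trial", {
  gen <- small_dataset(seed = 26, n_samples = 15, reps = 2, n_points = 80)
  s <- gen$spectra
  y <- join_concentrations(s, gen$truth$concentrations)$beta_lg
  tn <- tune_model("svr", s$absorbance, y, budget = 12, seed = 5)
  expect_true(all(tn$trials$C >= 5e-3 & tn$trials$C <= 1e3))
  expect_true(all(tn$trials$epsilon >= 0.01 & tn$trials$epsilon <= 0.9))
  expect_true(all(tn$trials$kernel %in% c("linear", "rbf", "poly")))
  expect_lte(tn$best_rmse, median(tn$trials$cv_rmse))
  # budget 1 returns the single sampled spec
  t1 <- tune_model("ridge", s$absorbance, y, budget = 1, seed = 6)
  expect_equal(nrow(t1$trials), 1L)
  expect_s3_class(t1$best_spec, "model_spec")
  # reproducibility under the seed
  t2 <- tune_model("svr", s$absorbance, y, budget = 5, seed = 9)
  t3 <- tune_model("svr", s$absorbance, y, budget = 5, seed = 9)
  expect_equal(t2$trials, t3$trials)
  expect_error(tune_model("svr", s$absorbance, y,
                          space = list(C = list(type = "loguniform",
                                                lo = 10, hi = 1)),
                          budget = 2), "lo >= hi")
})

test_that("PLS predictions are reproducible across refits (no sign
           indeterminacy leaks)", {
  gen <- small_dataset(seed = 27, n_samples = 12, reps = 2, n_points = 60)
  s <- gen$spectra
  y <- join_concentrations(s, gen$truth$concentrations)$beta_lg
  m1 <- fit_model(model_spec("pls", n_components = 4), s$absorbance, y)
  m2 <- fit_model(model_spec("pls", n_components = 4), s$absorbance, y)
  expect_identical(predict(m1, s$absorbance), predict(m2, s$absorbance))
})

test_that("model comparison table covers every scheme, model and protein", {
  gen <- small_dataset(seed = 28, n_samples = 12, reps = 3, n_points = 120)
  specs <- list(pls = model_spec("pls", n_components = 5),
                ridge = model_spec("ridge", alpha = 1e-3))
  tab <- run_model_comparison(gen$spectra, gen$truth$concentrations, specs,
                              seed = 2)
  expect_equal(nrow(tab), 2 * 2 * 4)
  expect_setequal(unique(tab$scheme), c("KS", "RS", "LORO", "LOSO"))
  expect_true(all(is.finite(tab$rmse)) && all(tab$rmse >= 0))
})
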