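test_that("scaling operators meet their definitions", {
  # hand arithmetic: [3,4] has Euclidean norm 5
  r <- scale_spectra(matrix(c(3, 4), 1), "normalize")
  expect_equal(as.numeric(r$X), c(0.6, 0.8))
  expect_error(scale_spectra(matrix(0, 1, 3), "normalize"), "zero-norm")
  # mean-centering drives calibration column means to zero
  set.seed(1)
  Xc <- matrix(rnorm(40), 8)
  rc <- scale_spectra(Xc, "mean_center")
  expect_lt(max(abs(colMeans(rc$X))), 1e-12)
  # validation transformed with calibration means, not its own
  Xv <- matrix(rnorm(40, mean = 3), 8)
  rv <- scale_spectra(Xv, "mean_center", state = rc$state)
  expect_gt(max(abs(colMeans(rv$X))), 0.5)
})

test_that("SNV, RNV and LSNV row corrections", {
  # hand arithmetic with the sample (n-1) SD
  r <- scatter_correct(matrix(c(1, 2, 3), 1), "snv")
  expect_equal(as.numeric(r$X), c(-1, 0, 1))
  set.seed(2)
  X <- matrix(rnorm(5 * 200, sd = 2, mean = 4), 5)
  snv <- scatter_correct(X, "snv")$X
  expect_lt(max(abs(rowMeans(snv))), 1e-10)
  expect_lt(max(abs(apply(snv, 1, sd) - 1)), 1e-10)
  expect_error(scatter_correct(matrix(1, 1, 4), "snv"), "constant")
  # RNV: quantile arithmetic per row
  rnv <- scatter_correct(X, "rnv", params = list(percentiles = c(25, 75)))$X
  q <- t(apply(X, 1, quantile, probs = c(0.25, 0.75)))
  expect_equal(rnv, (X - q[, 1]) / (q[, 2] - q[, 1]), tolerance = 1e-12)
  # LSNV: with window >= p it degenerates to plain SNV
  lsnv <- scatter_correct(X, "lsnv", params = list(window = 500))$X
  expect_equal(lsnv, snv, tolerance = 1e-12)
  lsnv2 <- scatter_correct(X, "lsnv", params = list(window = 50))$X
  expect_false(isTRUE(all.equal(lsnv2, snv)))
})

test_that("MSC inverts a planted gain/offset model and fixes its reference", {
  gen <- small_dataset(seed = 4, n_samples = 6, reps = 1, n_points = 150,
                       scatter_sd = 0, baseline_sd = 0, noise_sd = 0)
  clean <- gen$spectra$absorbance
  ref <- colMeans(clean)
  # the reference spectrum itself is a fixed point (a = 1, b = 0)
  r <- scatter_correct(rbind(ref, clean), "msc",
                       state = list(reference = ref))
  expect_equal(r$X[1, ], ref, tolerance = 1e-10)
  # planted multiplicative gain and additive offset are removed
  gains <- c(2, 0.5, 1.5, 0.8, 1.2, 2.5)
  offs <- c(0.1, -0.05, 0.2, 0.0, 0.15, -0.1)
  distorted <- sweep(sweep(matrix(rep(ref, 6), 6, byrow = TRUE), 1, gains,
                           "*"), 1, offs, "+")
  fixed <- scatter_correct(distorted, "msc",
                           state = list(reference = ref))$X
  for (i in 1:6) expect_equal(fixed[i, ], ref, tolerance = 1e-8)
  # EMSC additionally removes a polynomial baseline
  z <- seq(-1, 1, length.out = length(ref))
  poly_base <- 0.3 * z^2 - 0.2 * z + 0.05
  distorted2 <- sweep(sweep(matrix(rep(ref, 6), 6, byrow = TRUE), 1, gains,
                            "*"), 2, poly_base, "+")
  fixed2 <- scatter_correct(distorted2, "emsc",
                            state = list(reference = ref),
                            wavenumbers = seq_along(ref))$X
  for (i in 1:6) expect_equal(fixed2[i, ], ref, tolerance = 1e-6)
})

test_that("Savitzky-Golay preserves polynomials and differentiates ramps", {
  p <- 101
  # constant spectrum is unchanged at derivative 0
  const <- matrix(5, 2, p)
  expect_equal(savgol(const, 11, 2, 0), const, tolerance = 1e-10)
  # any degree <= poly_order polynomial is reproduced at interior points
  x <- seq_len(p)
  poly3 <- rbind(2 + 0.5 * x - 0.01 * x^2 + 1e-4 * x^3)
  sm <- savgol(poly3, 15, 3, 0)
  interior <- 8:(p - 7)
  expect_equal(sm[1, interior], poly3[1, interior], tolerance = 1e-8)
  # linear ramp, derivative 1: constant equal to the slope per index step
  ramp <- rbind(0.25 * x)
  d1 <- savgol(ramp, 11, 1, 1)
  expect_equal(d1[1, interior], rep(0.25, length(interior)),
               tolerance = 1e-10)
  # the reference window configuration is accepted
  wide <- matrix(rnorm(2 * 200), 2)
  expect_silent(savgol(wide, 151, 1, 0))
  # config errors
  expect_error(savgol(const, 10, 2, 0), "odd")
  expect_error(savgol(const, 11, 2, 3), "deriv_order")
  expect_error(savgol(const, 5, 1, 2), "exceeds")
})

test_that("pipeline enumeration counts follow the product formula", {
  sg4 <- list("none",
              list(filter_win = 11L, poly_order = 1L, deriv_order = 0L),
              list(filter_win = 15L, poly_order = 2L, deriv_order = 0L),
              list(filter_win = 21L, poly_order = 2L, deriv_order = 1L))
  space <- list(scale = list("normalize", "mean_center"),
                scatter = list("snv", "rnv", "lsnv", "msc", "emsc"),
                savgol = sg4)
  specs <- enumerate_pipelines(space)
  expect_length(specs, 2 * (5 + 1) * 4)
  single <- enumerate_pipelines(list(scale = list("normalize"),
                                     scatter = list(),
                                     savgol = list("none")))
  expect_length(single, 1L)
  expect_length(enumerate_pipelines(default_pipeline_space()), 434L)
  expect_error(enumerate_pipelines(list(scale = list(), scatter = list(),
                                        savgol = list("none"))), "non-empty")
})

test_that("validation transforms never read validation statistics", {
  gen <- small_dataset(seed = 8, n_samples = 10, reps = 2, n_points = 200)
  X <- gen$spectra$absorbance
  cal <- X[1:12, ]; val <- X[13:20, ]
  spec <- pipeline_spec(scale = c("mean_center", "normalize"),
                        scatter = "msc",
                        savgol = list(filter_win = 11L, poly_order = 2L,
                                      deriv_order = 0L))
  fp <- fit_pipeline(spec, cal, gen$spectra$wavenumbers)
  full <- apply_pipeline(fp, val)
  # permuting or subsetting the validation rows leaves each row's
  # transform unchanged
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  expect_equal(apply_pipeline(fp, val[perm, ]), full[perm, ],
               tolerance = 1e-12)
  expect_equal(apply_pipeline(fp, val[2:3, ]), full[2:3, ],
               tolerance = 1e-12)
})

test_that("pipeline search favors scatter correction on scattered data and
           breaks ties toward fewer components", {
  # planted multiplicative scatter: a correcting chain should beat identity
  wins <- vapply(1:6, function(sd) {
    gen <- small_dataset(seed = sd, n_samples = 20, reps = 3, n_points = 250,
                         scatter_sd = 0.12, baseline_sd = 0.03)
    s <- gen$spectra
    Y <- as.matrix(join_concentrations(s, gen$truth$concentrations)[,
                                       c("beta_lg", "alpha_la")])
    sp <- ks_split(s, gen$truth$concentrations, "spectra")
    tr <- match(sp$calibration_ids, s$spectrum_id)
    va <- match(sp$validation_ids, s$spectrum_id)
    space <- list(scale = list("normalize"), scatter = list("msc"),
                  savgol = list("none"))
    res <- search_best_pipeline(list(X = s$absorbance[tr, ], Y = Y[tr, ]),
                                list(X = s$absorbance[va, ], Y = Y[va, ]),
                                space, ncomp_range = 1:8,
                                wavenumbers = s$wavenumbers)
    tab <- res$results
    tab$score[tab$pipeline == "normalize + MSC"] >
      tab$score[tab$pipeline == "normalize"]
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("scatter correction after mean-centering fails loudly, and the
           search records the failure while continuing", {
  set.seed(3)
  X <- matrix(rnorm(10 * 60), 10)
  ctr <- scale_spectra(X, "mean_center")$X
  expect_error(scatter_correct(ctr, "msc"), "zero variance")
  gen <- small_dataset(seed = 30, n_samples = 10, reps = 2, n_points = 80)
  s <- gen$spectra
  Y <- as.matrix(join_concentrations(s, gen$truth$concentrations)[,
                                     c("beta_lg", "alpha_la")])
  space <- list(scale = list("mean_center"), scatter = list("msc"),
                savgol = list("none"))
  res <- search_best_pipeline(list(X = s$absorbance[1:14, ],
                                   Y = Y[1:14, ]),
                              list(X = s$absorbance[15:20, ],
                                   Y = Y[15:20, ]),
                              space, ncomp_range = 1:4,
                              wavenumbers = s$wavenumbers)
  expect_true(res$results$failed[res$results$pipeline == "MC + MSC"])
  expect_equal(res$results$pipeline[res$winner], "MC")
})
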