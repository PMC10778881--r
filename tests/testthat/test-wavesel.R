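test_that("iPLS interval geometry and signal localization", {
  # 100 points in 20 intervals of exactly 5
  gen <- small_dataset(seed = 41, n_samples = 15, reps = 2, n_points = 100)
  X <- gen$spectra$absorbance
  y <- join_concentrations(gen$spectra, gen$truth$concentrations)$beta_lg
  rk <- ipls_rank(X, y, n_intervals = 20)
  expect_equal(rk$intervals$end - rk$intervals$start + 1L, rep(5L, 20))
  expect_equal(sort(rk$intervals$rank), 1:20)
  # signal planted in a single known interval ranks first in a majority
  # of seeds
  hits <- vapply(1:6, function(sd) {
    set.seed(sd)
    n <- 40; p <- 60
    Xs <- matrix(rnorm(n * p, sd = 0.3), n)
    ys <- runif(n, 1, 4)
    cols <- 21:30                           # interval 3 of 6
    Xs[, cols] <- Xs[, cols] + outer(ys, rep(1, 10))
    r <- ipls_rank(Xs, ys, n_intervals = 6, fold_seed = sd)
    r$rank_order[1] == 3
  }, logical(1))
  expect_gt(mean(hits), 0.5)
  expect_error(ipls_rank(X, y, n_intervals = 60), "narrower")
})

test_that("region restriction filters the axis and composes", {
  gen <- small_dataset(seed = 43, n_samples = 5, reps = 1, n_points = 360)
  s <- gen$spectra
  full <- restrict_region(s, min(s$wavenumbers), max(s$wavenumbers))
  expect_equal(full$absorbance, s$absorbance)
  r <- restrict_region(s, 1000, 3000)
  expect_true(all(r$wavenumbers >= 1000 & r$wavenumbers <= 3000))
  expect_true(all(diff(r$wavenumbers) < 0))
  # nesting inside a wider window is idempotent
  r2 <- restrict_region(r, 500, 3500)
  expect_equal(r2$absorbance, r$absorbance)
  expect_error(restrict_region(s, 100, 150), "inside")
})

test_that("binning arithmetic: counts, sums and expansion", {
  set.seed(5)
  X <- matrix(rnorm(2 * 10268), 2)
  B <- suppressWarnings(bin_wavenumbers(X, 17))
  expect_length(B$index_map, 604L)
  expect_equal(ncol(B$binned), 604L)
  # constant spectrum: every bin is 17c
  Bc <- bin_wavenumbers(matrix(3, 1, 85), 17)
  expect_equal(as.numeric(Bc$binned), rep(51, 5))
  # conservation in the exact-division case
  Xe <- matrix(rnorm(3 * 170), 3)
  Be <- bin_wavenumbers(Xe, 17)
  expect_equal(rowSums(Be$binned), rowSums(Xe), tolerance = 1e-12)
  # mask expansion arithmetic
  m85 <- c(rep(TRUE, 85), rep(FALSE, 604 - 85))
  m51 <- c(rep(TRUE, 51), rep(FALSE, 604 - 51))
  expect_length(expand_selection(m85, B), 85L * 17L)   # 1445
  expect_length(expand_selection(m51, B), 51L * 17L)   # 867
  expect_length(expand_selection(rep(FALSE, 604), B), 0L)
  # expansion is injective over bins
  all_idx <- expand_selection(rep(TRUE, 604), B)
  expect_equal(anyDuplicated(all_idx), 0L)
  expect_error(expand_selection(rep(TRUE, 10), B), "mask length")
  # remainder points are dropped with a warning
  expect_warning(bin_wavenumbers(matrix(1, 1, 40), 17), "trailing")
})

test_that("GA fixed points and elitism guarantee", {
  set.seed(6)
  Xb <- matrix(rnorm(30 * 8), 30)
  y <- rnorm(30)
  # rates zero and an identical population: generations change nothing
  cfg0 <- ga_config(population_size = 6, generations = 4,
                    crossover_rate = 0, mutation_rate = 0, elitism = 0,
                    runs = 1, seed = 3)
  fixed_fit <- function(mask) sum(mask)          # cheap deterministic
  r0 <- ga_select(Xb, cfg = cfg0, fitness = fixed_fit)
  expect_equal(r0$traces[[1]], rep(r0$traces[[1]][1], 4))
  # elitism >= 1: best fitness trace is non-decreasing under the noisy
  # PLS fitness
  cfg1 <- ga_config(population_size = 12, generations = 8, elitism = 2,
                    runs = 1, seed = 4, nfolds = 3)
  r1 <- ga_select(Xb, y, cfg1)
  expect_true(all(diff(r1$traces[[1]]) >= 0))
  # config validation
  expect_error(ga_config(population_size = 1), "at least 2")
  expect_error(ga_config(population_size = 4, elitism = 4), "elitism")
})

test_that("GA matches the exhaustive optimum on a small cheap problem", {
  n_bins <- 12
  set.seed(10)
  w <- runif(n_bins, -1, 1)
  target <- sum(w[w > 0]) * 0.6
  cheap <- function(mask) 100 - (sum(w[mask]) - target)^2
  # exhaustive optimum over all 2^12 masks
  best <- -Inf
  for (code in 0:(2^n_bins - 1)) {
    mask <- as.logical(bitwAnd(bitwShiftR(code, 0:(n_bins - 1)), 1L))
    if (any(mask)) best <- max(best, cheap(mask))
  }
  cfg <- ga_config(population_size = 40, generations = 30, runs = 1,
                   seed = 11)
  r <- ga_select(matrix(0, 2, n_bins), cfg = cfg, fitness = cheap)
  achieved <- cheap(r$best_masks[1, ])
  expect_gte(achieved, 0.99 * best)
})

test_that("GA recovers planted informative bins", {
  # 20 bins, protein signal planted in 5 of them, default noise scales
  hits <- vapply(1:6, function(sd) {
    grid_n <- 340                       # 20 bins of 17 points
    wn <- seq(4000, 400, length.out = grid_n)
    bin_centers <- vapply(1:20, function(b)
      mean(wn[((b - 1) * 17 + 1):(b * 17)]), numeric(1))
    planted_bins <- c(3, 7, 10, 14, 18)
    lib <- planted_band_library(bin_centers[planted_bins])
    gen <- generate_dataset(sim_config(
      n_samples = 30, replicates_per_sample = 3, total_spectra = 90,
      jitter_replicates = FALSE, wavenumber_grid = c(4000, 400, grid_n),
      band_library = lib, seed = sd))
    s <- gen$spectra
    y <- join_concentrations(s, gen$truth$concentrations)$beta_lg
    B <- bin_wavenumbers(s, 17)
    cfg <- ga_config(population_size = 30, generations = 20, runs = 5,
                     seed = sd)
    r <- ga_select(B, y, cfg)
    sum(r$mask[planted_bins]) >= 4      # >= 80% of the planted bins
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
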