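#' Cross-validated PLS error over a component range
#'
#' Shared by the iPLS interval ranking, the GA fitness and component-count
#' selection: K-fold cross-validated RMSE of a PLS model for every
#' component count up to `ncomp_max`, with the folds fixed by `seed` so
#' repeated calls are comparable.
#'
#' @param X Spectra matrix.
#' @param y Concentration vector.
#' @param ncomp_max Largest component count to evaluate.
#' @param nfolds Number of CV folds.
#' @param seed Fold-assignment seed.
#' @return A list with `rmse` (per component count), `best_rmse` and
#'   `best_ncomp`.
#' @export
pls_rmsecv <- function(X, y, ncomp_max = 10L, nfolds = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  kmax <- max(1L, min(ncomp_max, ncol(X), n - ceiling(n / nfolds) - 1L))
  folds <- make_folds(n, nfolds, seed)
  se <- matrix(NA_real_, n, kmax)
  for (f in folds) {
    d <- suppressWarnings(pls_decompose(X[-f, , drop = FALSE], y[-f], kmax))
    ks <- seq_len(d$k)
    pred <- as.matrix(predict(d, X[f, , drop = FALSE], ncomp = ks))
    se[f, ks] <- (pred - y[f])^2
  }
  rmse <- sqrt(colMeans(se, na.rm = TRUE))
  best <- which.min(rmse)
  list(rmse = rmse, best_rmse = rmse[best], best_ncomp = best)
}

#' Rank equidistant spectral intervals by cross-validated PLS error
#'
#' Interval PLS (iPLS): the wavenumber axis is split into `n_intervals`
#' near-equidistant contiguous intervals; a PLS model restricted to each
#' interval is scored by cross-validated RMSE (best over the component
#' range), and intervals are ranked ascending by that error. Low-error
#' intervals carry the protein signal.
#'
#' @param X Spectra matrix.
#' @param y Concentration vector.
#' @param n_intervals Number of intervals (the reference protocol tests 20,
#'   25 and 30).
#' @param ncomp_max Upper bound on PLS components per interval.
#' @param nfolds,fold_seed Internal CV folds and their fixed seed.
#' @return An `interval_ranking` list: `intervals` data.frame (start/end
#'   column indices, rmse, ncomp, rank) and `rank_order` (interval indices
#'   sorted best-first).
#' @export
ipls_rank <- function(X, y, n_intervals = 20L, ncomp_max = 10L,
                      nfolds = 5L, fold_seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (n_intervals > p) stopf("more intervals (%d) than points (%d)",
                             n_intervals, p)
  bounds <- floor(seq(0, p, length.out = n_intervals + 1))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  if (any(ends - starts + 1L < 2L))
    stopf("an interval would be narrower than 2 points; reduce n_intervals")
  rec <- lapply(seq_len(n_intervals), function(i) {
    r <- pls_rmsecv(X[, starts[i]:ends[i], drop = FALSE], y,
                    ncomp_max, nfolds, fold_seed)
    data.frame(interval = i, start = starts[i], end = ends[i],
               rmse = r$best_rmse, ncomp = r$best_ncomp)
  })
  tab <- do.call(rbind, rec)
  tab$rank <- rank(tab$rmse, ties.method = "first")
  structure(list(intervals = tab, rank_order = order(tab$rmse)),
            class = "interval_ranking")
}

#' Restrict a spectra set to a wavenumber window
#'
#' @param s A `spectra_set`.
#' @param lo,hi Window bounds in cm^-1 (`lo < hi`).
#' @return A `spectra_set` keeping only columns with wavenumber in
#'   `[lo, hi]`, order preserved.
#' @export
restrict_region <- function(s, lo, hi) {
  validate_spectra_set(s)
  if (lo >= hi) stopf("need lo < hi, got [%g, %g]", lo, hi)
  keep <- s$wavenumbers >= lo & s$wavenumbers <= hi
  if (!any(keep)) stopf("no wavenumbers inside [%g, %g]", lo, hi)
  spectra_set(s$wavenumbers[keep], s$absorbance[, keep, drop = FALSE],
              s$spectrum_id, s$sample_id, s$replicate)
}

#' Bin contiguous wavenumber data points
#'
#' Each bin is the sum of `bin_width` contiguous data points;
#' `n_bins = floor(n_points / bin_width)` and trailing remainder points are
#' dropped with a warning. Binning a 10,268-point region at width 17 gives
#' 604 bins.
#'
#' @param s A `spectra_set` or a plain spectra matrix.
#' @param bin_width Points per bin (default 17).
#' @param wavenumbers Axis values when `s` is a matrix.
#' @return A `binned_spectra` list: `binned` (n x n_bins matrix of sums),
#'   `bin_width`, `index_map` (list, source column indices per bin),
#'   `bin_wavenumbers` (mean axis value per bin).
#' @export
bin_wavenumbers <- function(s, bin_width = 17L, wavenumbers = NULL) {
  if (inherits(s, "spectra_set")) {
    X <- s$absorbance; wavenumbers <- s$wavenumbers
  } else X <- as.matrix(s)
  if (bin_width < 1) stopf("bin_width must be at least 1")
  p <- ncol(X)
  if (p < bin_width) stopf("fewer points (%d) than bin_width (%d)",
                           p, bin_width)
  n_bins <- p %/% bin_width
  used <- n_bins * bin_width
  if (used < p)
    warnf("dropping %d trailing point(s) not filling a bin", p - used)
  index_map <- lapply(seq_len(n_bins), function(b)
    ((b - 1L) * bin_width + 1L):(b * bin_width))
  grp <- rep(seq_len(n_bins), each = bin_width)
  binned <- t(rowsum(t(X[, seq_len(used), drop = FALSE]), grp))
  dimnames(binned) <- NULL
  structure(list(binned = binned, bin_width = as.integer(bin_width),
                 index_map = index_map,
                 bin_wavenumbers = if (!is.null(wavenumbers))
                   vapply(index_map, function(i) mean(wavenumbers[i]),
                          numeric(1)) else NULL),
            class = "binned_spectra")
}

#' Genetic-algorithm configuration for wavenumber selection
#'
#' @param population_size Chromosomes per generation (default 200).
#' @param generations Generations per run (default 100).
#' @param crossover_rate,mutation_rate Single-point crossover probability
#'   and per-bit flip probability.
#' @param elitism Number of best chromosomes copied unchanged.
#' @param tournament_size Tournament selection size.
#' @param runs Independent GA repetitions whose best chromosomes are
#'   tallied into selection frequencies.
#' @param frequency_threshold Fraction of runs a bin must be selected in to
#'   enter the final mask (default 0.5).
#' @param ncomp_cap Cap on PLS components inside the fitness.
#' @param nfolds,fold_seed Fitness cross-validation folds and fixed seed.
#' @param seed Master seed; each run derives its own stream from it.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 200L, generations = 100L,
                      crossover_rate = 0.8, mutation_rate = 0.01,
                      elitism = 2L, tournament_size = 3L, runs = 5L,
                      frequency_threshold = 0.5, ncomp_cap = 10L,
                      nfolds = 5L, fold_seed = 1L, seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              generations = as.integer(generations),
              crossover_rate = crossover_rate,
              mutation_rate = mutation_rate,
              elitism = as.integer(elitism),
              tournament_size = as.integer(tournament_size),
              runs = as.integer(runs),
              frequency_threshold = frequency_threshold,
              ncomp_cap = as.integer(ncomp_cap),
              nfolds = as.integer(nfolds),
              fold_seed = as.integer(fold_seed),
              seed = as.integer(seed))
  if (cfg$population_size < 2) stopf("population_size must be at least 2")
  if (cfg$crossover_rate < 0 || cfg$crossover_rate > 1 ||
      cfg$mutation_rate < 0 || cfg$mutation_rate > 1)
    stopf("rates must be probabilities in [0, 1]")
  if (cfg$elitism >= cfg$population_size)
    stopf("elitism (%d) must be smaller than the population (%d)",
          cfg$elitism, cfg$population_size)
  class(cfg) <- "ga_config"
  cfg
}

#' Genetic-algorithm selection of wavenumber bins
#'
#' Evolves binary masks over the bins with tournament selection,
#' single-point crossover, bit-flip mutation and elitism. Fitness defaults
#' to the negative cross-validated PLS RMSE of the model restricted to the
#' selected bins (components capped at `min(ncomp_cap, n selected)`). The
#' algorithm is repeated `cfg$runs` times; each run's best chromosome is
#' recorded, per-bin selection counts are tallied across runs, and the
#' final mask keeps bins selected in at least `frequency_threshold` of the
#' runs.
#'
#' @param B A [bin_wavenumbers()] result or plain feature matrix.
#' @param y Concentration vector (ignored when `fitness` is supplied).
#' @param cfg A [ga_config()].
#' @param fitness Optional fitness function taking a logical mask and
#'   returning a scalar to maximize.
#' @param init_bins Optional integer bin indices (e.g. the bins of
#'   top-ranked iPLS intervals) seeded into every run's initial population.
#' @return A `ga_result` list: `frequency` (per-bin counts over runs),
#'   `mask` (final logical mask), `best_masks` (per run), `traces` (best
#'   fitness per generation, per run), `runs`.
#' @export
ga_select <- function(B, y = NULL, cfg = ga_config(), fitness = NULL,
                      init_bins = NULL) {
  Xb <- if (inherits(B, "binned_spectra")) B$binned else as.matrix(B)
  n_bins <- ncol(Xb)
  if (n_bins < 2) stopf("need at least 2 bins")
  if (is.null(fitness)) {
    if (is.null(y)) stopf("y is required for the default PLS fitness")
    fitness <- function(mask) {
      -pls_rmsecv(Xb[, mask, drop = FALSE], y,
                  ncomp_max = min(cfg$ncomp_cap, sum(mask)),
                  nfolds = cfg$nfolds, seed = cfg$fold_seed)$best_rmse
    }
  }
  cache <- new.env(parent = emptyenv())
  eval_mask <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- fitness(mask)
    cache[[key]] <- val
    val
  }
  repair <- function(mask) {
    if (!any(mask)) mask[sample.int(length(mask), 1L)] <- TRUE
    mask
  }

  best_masks <- matrix(FALSE, cfg$runs, n_bins)
  traces <- vector("list", cfg$runs)
  for (run in seq_len(cfg$runs)) {
    with_seed(derive_seed(cfg$seed, run), {
      pop <- matrix(stats::runif(cfg$population_size * n_bins) < 0.5,
                    cfg$population_size, n_bins)
      if (!is.null(init_bins)) {
        n_seeded <- max(1L, cfg$population_size %/% 10L)
        for (i in seq_len(n_seeded)) pop[i, init_bins] <- TRUE
      }
      pop <- t(apply(pop, 1, repair))
      fit <- apply(pop, 1, eval_mask)
      trace <- numeric(cfg$generations)
      for (gen in seq_len(cfg$generations)) {
        ord <- order(fit, decreasing = TRUE)
        newpop <- matrix(FALSE, cfg$population_size, n_bins)
        if (cfg$elitism > 0)
          newpop[seq_len(cfg$elitism), ] <-
            pop[ord[seq_len(cfg$elitism)], , drop = FALSE]
        i <- cfg$elitism
        while (i < cfg$population_size) {
          pick <- function() {
            cand <- sample.int(cfg$population_size, cfg$tournament_size,
                               replace = TRUE)
            cand[which.max(fit[cand])]
          }
          p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
          if (stats::runif(1) < cfg$crossover_rate && n_bins > 1) {
            cut <- sample.int(n_bins - 1L, 1L)
            c1 <- c(p1[seq_len(cut)], p2[(cut + 1L):n_bins])
            c2 <- c(p2[seq_len(cut)], p1[(cut + 1L):n_bins])
          } else { c1 <- p1; c2 <- p2 }
          for (child in list(c1, c2)) {
            if (i >= cfg$population_size) break
            flip <- stats::runif(n_bins) < cfg$mutation_rate
            child <- xor(child, flip)
            i <- i + 1L
            newpop[i, ] <- repair(child)
          }
        }
        pop <- newpop
        fit <- apply(pop, 1, eval_mask)
        trace[gen] <- max(fit)
      }
      best_masks[run, ] <- pop[which.max(fit), ]
      traces[[run]] <- trace
    })
  }
  freq <- colSums(best_masks)
  mask <- freq / cfg$runs >= cfg$frequency_threshold
  if (!any(mask)) mask <- freq == max(freq)
  structure(list(frequency = freq, mask = mask, best_masks = best_masks,
                 traces = traces, runs = cfg$runs),
            class = "ga_result")
}

#' Expand a bin mask to wavenumber data-point indices
#'
#' The returned index count is `(#selected bins) * bin_width`; e.g. 85
#' width-17 bins expand to 1445 data points and 51 bins to 867.
#'
#' @param mask Logical vector over bins.
#' @param B The [bin_wavenumbers()] result the mask refers to.
#' @return Sorted integer vector of source column indices.
#' @export
expand_selection <- function(mask, B) {
  stopifnot(inherits(B, "binned_spectra"))
  if (length(mask) != length(B$index_map))
    stopf("mask length (%d) does not match bin count (%d)",
          length(mask), length(B$index_map))
  sort(unlist(B$index_map[mask], use.names = FALSE))
}
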