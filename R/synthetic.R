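#' Default MIR band library for simulated milk spectra
#'
#' Gaussian absorption bands used by [generate_dataset()]. Protein signal is
#' placed where whey proteins absorb in real milk spectra: amide I
#' (1600-1690 cm^-1, secondary-structure sensitive; beta-sheet components
#' near 1632 cm^-1 for beta-lactoglobulin, alpha-helix near 1658 cm^-1 for
#' alpha-lactalbumin) and amide II (1480-1575 cm^-1). Milk fat contributes
#' C-H stretch bands near 2920/2852 cm^-1 and the ester carbonyl near
#' 1745 cm^-1, lactose a broad C-O band near 1045 cm^-1, and water a broad
#' band overlapping amide I.
#'
#' @return A `data.frame` with columns `center` (cm^-1), `width` (cm^-1,
#'   Gaussian sigma), `weight` (absorbance per unit concentration) and
#'   `component` (which concentration multiplies the band).
#' @export
default_band_library <- function() {
  data.frame(
    center    = c(1632, 1530, 1658, 1548, 2920, 2852, 1745, 1045, 1640),
    width     = c(  22,   18,   20,   16,   15,   12,   14,   40,  180),
    weight    = c(0.045, 0.030, 0.050, 0.035, 0.020, 0.015, 0.025, 0.020, 0.35),
    component = c("beta_lg", "beta_lg", "alpha_la", "alpha_la",
                  "fat", "fat", "fat", "lactose", "water"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration for synthetic MIR milk spectra
#'
#' Defaults emulate the reference scenario the package is tested against:
#' 42 unique milk samples measured in about 5 replicate spectra each (212
#' spectra in total, replicate counts jittered between 4 and 6),
#' beta-lactoglobulin in 2.22-4.60 mg/mL and alpha-lactalbumin in
#' 1.08-2.08 mg/mL with a positive linear dependence between the two
#' proteins, on a descending 4000-400 cm^-1 axis.
#'
#' @param n_samples Number of unique samples.
#' @param replicates_per_sample Target replicates per sample.
#' @param total_spectra Total spectrum count to hit exactly by distributing
#'   a remainder over samples; `NULL` uses `n_samples * replicates_per_sample`.
#' @param jitter_replicates If `TRUE`, a few +1/-1 replicate swaps make the
#'   per-sample counts uneven (4-6 under the defaults) while keeping the
#'   total fixed, which exercises replicate-aware fold logic downstream.
#' @param wavenumber_grid `c(start, end, n_points)` in cm^-1, descending.
#' @param beta_lg_range,alpha_la_range Concentration ranges in mg/mL.
#' @param concentration_correlation Target Pearson correlation between the
#'   two protein concentrations (a shared total-whey factor).
#' @param band_library Band table as in [default_band_library()].
#' @param scatter_sd Log-scale SD of the per-spectrum multiplicative gain
#'   (the standard generative model for multiplicative scatter).
#' @param baseline_sd SD of the per-spectrum additive baseline (offset plus
#'   linear drift), in absorbance units.
#' @param noise_sd SD of additive white Gaussian noise, absorbance units.
#' @param seed Integer seed; the same seed reproduces the dataset bit for bit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 42L,
                       replicates_per_sample = 5L,
                       total_spectra = NULL,
                       jitter_replicates = TRUE,
                       wavenumber_grid = c(4000, 400, 3600),
                       beta_lg_range = c(2.22, 4.60),
                       alpha_la_range = c(1.08, 2.08),
                       concentration_correlation = 0.6,
                       band_library = default_band_library(),
                       scatter_sd = 0.04,
                       baseline_sd = 0.01,
                       noise_sd = 0.002,
                       seed = 1L) {
  if (is.null(total_spectra)) {
    total_spectra <- if (n_samples == 42L && replicates_per_sample == 5L)
      212L else n_samples * replicates_per_sample
  }
  cfg <- list(n_samples = as.integer(n_samples),
              replicates_per_sample = as.integer(replicates_per_sample),
              total_spectra = as.integer(total_spectra),
              jitter_replicates = isTRUE(jitter_replicates),
              wavenumber_grid = as.numeric(wavenumber_grid),
              beta_lg_range = as.numeric(beta_lg_range),
              alpha_la_range = as.numeric(alpha_la_range),
              concentration_correlation = as.numeric(concentration_correlation),
              band_library = band_library,
              scatter_sd = as.numeric(scatter_sd),
              baseline_sd = as.numeric(baseline_sd),
              noise_sd = as.numeric(noise_sd),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (abs(cfg$concentration_correlation) > 1)
    stopf("concentration_correlation must lie in [-1, 1]")
  if (cfg$wavenumber_grid[3] < 2)
    stopf("wavenumber grid needs at least 2 points")
  if (diff(cfg$beta_lg_range) <= 0 || diff(cfg$alpha_la_range) <= 0)
    stopf("concentration ranges must be ordered (min, max)")
  if (cfg$scatter_sd < 0 || cfg$baseline_sd < 0 || cfg$noise_sd < 0)
    stopf("noise scales must be non-negative")
  if (cfg$total_spectra < cfg$n_samples)
    stopf("total_spectra must be at least n_samples")
  invisible(cfg)
}

# Replicate counts per sample: base count plus remainder, optionally with
# +1/-1 swaps so counts are uneven while the total stays exact.
replicate_counts <- function(cfg) {
  n <- cfg$n_samples
  base <- cfg$total_spectra %/% n
  counts <- rep(base, n)
  rem <- cfg$total_spectra - base * n
  if (rem > 0) counts[sample.int(n, rem)] <- base + 1L
  if (cfg$jitter_replicates && base >= 2 && n >= 4) {
    k <- max(1L, n %/% 14L)
    donors <- sample(which(counts == base), k)
    pool <- setdiff(which(counts == base), donors)
    k <- min(k, length(pool))
    donors <- donors[seq_len(k)]
    takers <- sample(pool, k)
    counts[donors] <- counts[donors] - 1L
    counts[takers] <- counts[takers] + 1L
  }
  counts
}

# Gaussian-copula draw of the two protein concentrations with a shared
# latent whey factor; marginals uniform over the configured ranges. The
# latent normal correlation is adjusted so the Pearson correlation of the
# uniform marginals lands on the requested target.
draw_concentrations <- function(cfg) {
  rho <- cfg$concentration_correlation
  rho_lat <- 2 * sin(pi * rho / 6)
  z_whey <- stats::rnorm(cfg$n_samples)
  z1 <- sqrt(abs(rho_lat)) * z_whey +
    sqrt(1 - abs(rho_lat)) * stats::rnorm(cfg$n_samples)
  z2 <- sign(rho_lat) * sqrt(abs(rho_lat)) * z_whey +
    sqrt(1 - abs(rho_lat)) * stats::rnorm(cfg$n_samples)
  u1 <- stats::pnorm(z1); u2 <- stats::pnorm(z2)
  concentration_table(
    sample_id = sprintf("S%02d", seq_len(cfg$n_samples)),
    beta_lg  = cfg$beta_lg_range[1] + u1 * diff(cfg$beta_lg_range),
    alpha_la = cfg$alpha_la_range[1] + u2 * diff(cfg$alpha_la_range))
}

#' Generate a synthetic MIR milk dataset with known ground truth
#'
#' The clean signal is a Beer-Lambert mixture, absorbance(v) =
#' sum_k c_k * eps_k(v), with Gaussian band shapes from the configured band
#' library; protein bands carry the per-sample beta-lactoglobulin and
#' alpha-lactalbumin concentrations, fat/lactose bands carry nuisance
#' concentrations and a broad fixed water band overlaps amide I. Replicates
#' of a sample share the concentrations but get independent draws of
#' multiplicative gain (`a*x`, LogNormal), additive baseline (offset plus
#' linear drift) and white noise, so scatter- and baseline-correcting
#' preprocessing is meaningfully testable.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `spectra` (a [spectra_set()]), `truth` (a
#'   list with `concentrations`, per-protein `informative_bands` intervals,
#'   `nuisance` per-sample fat/lactose levels, and an empty `outlier_ids`)
#'   and `config`.
#' @export
generate_dataset <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    grid <- cfg$wavenumber_grid
    wn <- seq(grid[1], grid[2], length.out = grid[3])
    conc <- draw_concentrations(cfg)
    nuisance <- data.frame(sample_id = conc$sample_id,
                           fat = stats::runif(cfg$n_samples, 3.5, 4.5),
                           lactose = stats::runif(cfg$n_samples, 4.5, 5.0))
    counts <- replicate_counts(cfg)

    bl <- cfg$band_library
    # band profiles: p x n_bands matrix of weight * gaussian(center, width)
    profiles <- vapply(seq_len(nrow(bl)), function(b) {
      bl$weight[b] * exp(-0.5 * ((wn - bl$center[b]) / bl$width[b])^2)
    }, numeric(length(wn)))
    comp_of <- bl$component

    conc_for <- function(i, comp) {
      switch(comp,
             beta_lg = conc$beta_lg[i],
             alpha_la = conc$alpha_la[i],
             fat = nuisance$fat[i],
             lactose = nuisance$lactose[i],
             water = 1)
    }

    n_tot <- sum(counts)
    X <- matrix(0, n_tot, length(wn))
    sample_id <- character(n_tot); replicate <- integer(n_tot)
    row <- 0L
    ramp <- seq(-0.5, 0.5, length.out = length(wn))
    for (i in seq_len(cfg$n_samples)) {
      ck <- vapply(comp_of, function(cp) conc_for(i, cp), numeric(1))
      clean <- as.numeric(profiles %*% ck)
      for (r in seq_len(counts[i])) {
        row <- row + 1L
        gain <- if (cfg$scatter_sd > 0)
          stats::rlnorm(1, 0, cfg$scatter_sd) else 1
        base <- if (cfg$baseline_sd > 0)
          stats::rnorm(1, 0, cfg$baseline_sd) +
            stats::rnorm(1, 0, cfg$baseline_sd) * ramp else 0
        noise <- if (cfg$noise_sd > 0)
          stats::rnorm(length(wn), 0, cfg$noise_sd) else 0
        X[row, ] <- gain * clean + base + noise
        sample_id[row] <- conc$sample_id[i]
        replicate[row] <- r
      }
    }
    s <- spectra_set(wn, X,
                     spectrum_id = sprintf("%s_r%d", sample_id, replicate),
                     sample_id = sample_id, replicate = replicate)
    bands <- lapply(split(bl, bl$component), function(d)
      cbind(lo = pmax(min(wn[length(wn)]), d$center - d$width),
            hi = pmin(wn[1], d$center + d$width)))
    truth <- list(concentrations = conc,
                  informative_bands = bands[c("beta_lg", "alpha_la")],
                  nuisance = nuisance,
                  outlier_ids = character(0))
    list(spectra = s, truth = truth, config = cfg)
  })
}

#' Inject gross outlier spectra
#'
#' Perturbs `n_outliers` randomly chosen rows with a gross additive baseline
#' shift plus a Gaussian-bump shape distortion, each scaled to `magnitude`
#' times the row's own standard deviation. This is the test harness for the
#' T2/Q-residual screening stage.
#'
#' @param s A `spectra_set`.
#' @param n_outliers How many rows to perturb.
#' @param magnitude Perturbation scale in multiples of the row SD.
#' @param seed Integer seed.
#' @return A list with `spectra` (perturbed set) and `outlier_ids`
#'   (spectrum ids of the perturbed rows).
#' @export
inject_outliers <- function(s, n_outliers, magnitude = 10, seed = 1L) {
  validate_spectra_set(s)
  n <- n_spectra(s)
  if (n_outliers > n)
    stopf("n_outliers (%d) exceeds number of spectra (%d)", n_outliers, n)
  if (n_outliers == 0)
    return(list(spectra = s, outlier_ids = character(0)))
  with_seed(seed, {
    rows <- sort(sample.int(n, n_outliers))
    p <- length(s$wavenumbers)
    X <- s$absorbance
    for (i in rows) {
      amp <- magnitude * stats::sd(X[i, ])
      center <- sample.int(p, 1)
      bump <- exp(-0.5 * ((seq_len(p) - center) / (p / 25))^2)
      X[i, ] <- X[i, ] + amp + amp * bump
    }
    out <- s
    out$absorbance <- X
    list(spectra = out, outlier_ids = s$spectrum_id[rows])
  })
}
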