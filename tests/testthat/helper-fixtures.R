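# Shared fixtures and independent oracles used across test files.

# A small synthetic dataset; all generation goes through the package's
# simulator with explicit, test-local sizes.
small_dataset <- function(seed = 1, n_samples = 20, reps = 3, n_points = 400,
                          ...) {
  generate_dataset(sim_config(
    n_samples = n_samples, replicates_per_sample = reps,
    total_spectra = n_samples * reps, jitter_replicates = FALSE,
    wavenumber_grid = c(4000, 400, n_points), seed = seed, ...))
}

# Independent Kennard-Stone oracle: a literal transcription of the greedy
# definition with no shared code with the implementation (explicit loops,
# recomputing every candidate's min distance from scratch each step).
ks_oracle <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  d2 <- function(i, j) sum((X[i, ] - X[j, ])^2)
  best <- c(NA, NA); bestd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d2(i, j) > bestd) { bestd <- d2(i, j); best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_select) {
    cand_best <- NA; cand_d <- -Inf
    for (i in seq_len(n)) {
      if (i %in% sel) next
      mind <- Inf
      for (j in sel) mind <- min(mind, d2(i, j))
      if (mind > cand_d) { cand_d <- mind; cand_best <- i }
    }
    sel <- c(sel, cand_best)
  }
  sel
}

# Band library that plants one protein's signal in known spectral spots,
# used for planted-band recovery tests. `centers` are in cm^-1; nuisance
# bands (correlated other protein, fat, water) are kept away from the
# planted centers so the ground-truth bin set is unambiguous.
planted_band_library <- function(centers, width = 60, weight = 0.008) {
  rbind(
    data.frame(center = centers, width = width, weight = weight,
               component = "beta_lg", stringsAsFactors = FALSE),
    data.frame(center = 3730, width = 40, weight = 0.03,
               component = "alpha_la", stringsAsFactors = FALSE),
    data.frame(center = c(2300, 700), width = c(50, 60),
               weight = c(0.02, 0.02), component = "fat",
               stringsAsFactors = FALSE),
    data.frame(center = 1200, width = 120, weight = 0.2,
               component = "water", stringsAsFactors = FALSE))
}
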