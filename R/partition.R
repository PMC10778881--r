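#' Kennard-Stone sample selection
#'
#' Deterministic max-min-distance selection: the first two picks realize
#' the maximum pairwise Euclidean distance in the feature space; every
#' subsequent pick maximizes its minimum distance to the already-selected
#' set. Ties are broken by the lowest row index.
#'
#' @param features Numeric matrix (rows = candidates) or vector.
#' @param n_select How many rows to select (>= 2).
#' @return Integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(features, n_select) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n_select > n)
    stopf("n_select (%d) exceeds the %d available rows", n_select, n)
  if (n_select < 2) stopf("n_select must be at least 2")
  D <- unname(as.matrix(stats::dist(X)))
  # first pair: maximum distance, lexicographically smallest index pair on ties
  m <- max(D)
  hit <- which(D == m, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  sel <- c(hit[1, 1], hit[1, 2])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_select) {
    nxt <- which.max(mind)  # which.max takes the lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  as.integer(sel)
}

#' Random calibration/validation split
#'
#' Validation size is `floor(fraction * n)` exactly (so 197 spectra at 30%
#' give 59 validation / 138 calibration); the remainder is calibration.
#'
#' @param ids Character vector of spectrum ids.
#' @param validation_fraction Fraction held out (0 < f < 1), default 0.30.
#' @param seed Integer seed for reproducibility.
#' @return A `split_result` list: `calibration_ids`, `validation_ids`,
#'   `method`, `seed`.
#' @export
random_split <- function(ids, validation_fraction = 0.30, seed = NULL) {
  n <- length(ids)
  if (n < 2) stopf("need at least 2 ids to split")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stopf("validation_fraction must be in (0, 1)")
  n_val <- floor(validation_fraction * n)
  val <- with_seed(seed, sample(ids, n_val))
  structure(list(calibration_ids = setdiff(ids, val),
                 validation_ids = val,
                 method = "random", basis = NULL, seed = seed),
            class = "split_result")
}

#' Kennard-Stone calibration/validation split
#'
#' The calibration set is the Kennard-Stone selection of
#' `n - floor(fraction * n)` spectra; validation is the remainder. The
#' selection space is either the spectra themselves or one protein's
#' concentration values (the 1-D bases are faster and, when the two
#' proteins are positively dependent, give similar splits).
#'
#' @param s A `spectra_set`.
#' @param conc A [concentration_table()]; needed for concentration bases.
#' @param basis `"spectra"`, `"beta_lg"` or `"alpha_la"`.
#' @param validation_fraction Fraction held out, default 0.30.
#' @return A `split_result` as in [random_split()] with `method = "kennard_stone"`.
#' @export
ks_split <- function(s, conc = NULL,
                     basis = c("spectra", "beta_lg", "alpha_la"),
                     validation_fraction = 0.30) {
  basis <- match.arg(basis)
  validate_spectra_set(s)
  feats <- if (basis == "spectra") s$absorbance else {
    if (is.null(conc)) stopf("concentration basis needs a concentration table")
    join_concentrations(s, conc)[[basis]]
  }
  n <- n_spectra(s)
  n_cal <- n - floor(validation_fraction * n)
  sel <- kennard_stone(feats, n_cal)
  structure(list(calibration_ids = s$spectrum_id[sort(sel)],
                 validation_ids = s$spectrum_id[-sel],
                 method = "kennard_stone", basis = basis, seed = NULL),
            class = "split_result")
}

#' Replicate-aware cross-validation fold plans
#'
#' `"LOSO"` (leave one sample out) builds one fold per sample whose
#' validation part holds every replicate of that sample, so no replicate of
#' a held-out sample ever leaks into training. `"LORO"` (leave one
#' replicate out) builds one fold per replicate index; fold r's validation
#' holds replicate r of every sample that has one (samples with fewer
#' replicates simply contribute nothing to that fold).
#'
#' @param s A `spectra_set` with populated replicate indices.
#' @param scheme `"LORO"` or `"LOSO"`.
#' @return A `fold_plan` list: `scheme` and `folds`, each fold a list with
#'   `train` and `validation` spectrum-id vectors.
#' @export
cv_folds <- function(s, scheme = c("LORO", "LOSO")) {
  scheme <- match.arg(scheme)
  validate_spectra_set(s)
  ids <- s$spectrum_id
  folds <- if (scheme == "LOSO") {
    lapply(unique(s$sample_id), function(sm) {
      v <- ids[s$sample_id == sm]
      list(train = setdiff(ids, v), validation = v)
    })
  } else {
    lapply(seq_len(max(s$replicate)), function(r) {
      v <- ids[s$replicate == r]
      list(train = setdiff(ids, v), validation = v)
    })
  }
  structure(list(scheme = scheme, folds = folds), class = "fold_plan")
}
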