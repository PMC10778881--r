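#' Construct a spectra set
#'
#' A `spectra_set` bundles an absorbance matrix with its wavenumber axis and
#' the identity of every row: which physical sample it came from and which
#' replicate measurement it is. It is the `X` of every downstream model.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   monotonic descending (the MIR plotting convention, 4000 -> 400).
#' @param absorbance Numeric matrix, one row per spectrum, one column per
#'   wavenumber, in absorbance units. All values must be finite.
#' @param spectrum_id Character vector of unique per-row identifiers.
#' @param sample_id Character vector naming the physical sample of each row;
#'   shared across replicate spectra.
#' @param replicate Positive integer replicate index per row.
#'
#' @return An object of class `spectra_set` with fields `wavenumbers`,
#'   `absorbance`, `spectrum_id`, `sample_id`, `replicate`.
#' @export
spectra_set <- function(wavenumbers, absorbance, spectrum_id, sample_id,
                        replicate) {
  absorbance <- as.matrix(absorbance)
  wavenumbers <- as.numeric(wavenumbers)
  spectrum_id <- as.character(spectrum_id)
  sample_id <- as.character(sample_id)
  replicate <- as.integer(replicate)
  s <- structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         spectrum_id = spectrum_id, sample_id = sample_id,
         replicate = replicate),
    class = "spectra_set")
  validate_spectra_set(s)
  s
}

#' Validate spectra-set invariants
#'
#' Checks identity uniqueness, axis monotonicity, shape agreement and
#' finiteness; called by the constructor and the readers.
#'
#' @param s A `spectra_set`.
#' @return `s`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_spectra_set <- function(s) {
  n <- nrow(s$absorbance)
  p <- length(s$wavenumbers)
  if (ncol(s$absorbance) != p)
    stopf("absorbance has %d columns but axis has %d wavenumbers",
          ncol(s$absorbance), p)
  if (p >= 2 && any(diff(s$wavenumbers) >= 0))
    stopf("wavenumber axis must be strictly monotonic descending")
  if (anyDuplicated(s$spectrum_id))
    stopf("duplicate spectrum_id: %s",
          s$spectrum_id[anyDuplicated(s$spectrum_id)])
  if (length(s$spectrum_id) != n || length(s$sample_id) != n ||
      length(s$replicate) != n)
    stopf("identity columns must have one entry per spectrum row")
  if (n > 0 && !all(is.finite(s$absorbance)))
    stopf("absorbance values must all be finite")
  if (n > 0 && any(s$replicate < 1L))
    stopf("replicate indices must be positive integers")
  invisible(s)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(
    "spectra_set: %d spectra x %d wavenumbers (%.1f to %.1f cm-1), %d samples\n",
    nrow(x$absorbance), length(x$wavenumbers),
    if (length(x$wavenumbers)) x$wavenumbers[1] else NA_real_,
    if (length(x$wavenumbers)) x$wavenumbers[length(x$wavenumbers)] else NA_real_,
    length(unique(x$sample_id))))
  invisible(x)
}

#' Number of spectra / unique samples in a spectra set
#' @param s A `spectra_set`.
#' @return Integer count.
#' @export
n_spectra <- function(s) nrow(s$absorbance)

#' @rdname n_spectra
#' @export
n_samples <- function(s) length(unique(s$sample_id))

#' Subset a spectra set by row
#'
#' @param s A `spectra_set`.
#' @param i Integer or logical row index.
#' @return A `spectra_set` with the selected spectra.
#' @export
subset_spectra <- function(s, i) {
  spectra_set(s$wavenumbers, s$absorbance[i, , drop = FALSE],
              s$spectrum_id[i], s$sample_id[i], s$replicate[i])
}

#' Read spectra from the canonical wide CSV format
#'
#' The canonical layout is one row per replicate spectrum:
#' `spectrum_id,sample_id,replicate,<wn1>,<wn2>,...` with wavenumber header
#' cells as decimal cm^-1 strings in descending order.
#'
#' @param path Path to a CSV file.
#' @return A validated [spectra_set()].
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- suppressWarnings(
    utils::read.csv(path, check.names = FALSE,
                    colClasses = c(spectrum_id = "character",
                                   sample_id = "character")))
  need <- c("spectrum_id", "sample_id", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("spectra file is missing required column(s): %s",
          paste(miss, collapse = ", "))
  wn_cols <- setdiff(names(df), need)
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (anyNA(wn))
    stopf("non-numeric wavenumber header cell(s): %s",
          paste(utils::head(wn_cols[is.na(wn)], 3), collapse = ", "))
  if (length(wn) >= 2 && any(diff(wn) >= 0))
    stopf("wavenumber axis in %s is not strictly descending", path)
  X <- as.matrix(df[, wn_cols, drop = FALSE])
  storage.mode(X) <- "double"
  dimnames(X) <- NULL
  spectra_set(wn, X, df$spectrum_id, df$sample_id, df$replicate)
}

#' Write spectra to the canonical wide CSV format
#'
#' Numeric values are written with 15 significant digits so that a
#' write/read round trip reproduces absorbance to better than 1e-12
#' relative error and identities exactly.
#'
#' @param s A `spectra_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path) {
  validate_spectra_set(s)
  df <- data.frame(spectrum_id = s$spectrum_id, sample_id = s$sample_id,
                   replicate = s$replicate, check.names = FALSE,
                   stringsAsFactors = FALSE)
  X <- s$absorbance
  colnames(X) <- format(s$wavenumbers, digits = 15, trim = TRUE,
                        scientific = FALSE)
  old <- options(digits = 15)
  on.exit(options(old), add = TRUE)
  utils::write.csv(cbind(df, as.data.frame(X, check.names = FALSE)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a concentration table
#'
#' Per-sample reference concentrations of the two target whey proteins,
#' beta-lactoglobulin and alpha-lactalbumin, in mg/mL. This is the `Y` of
#' every calibration model.
#'
#' @param sample_id Character vector of unique sample names.
#' @param beta_lg,alpha_la Non-negative concentrations in mg/mL.
#' @return A `data.frame` with class `concentration_table`.
#' @export
concentration_table <- function(sample_id, beta_lg, alpha_la) {
  tab <- data.frame(sample_id = as.character(sample_id),
                    beta_lg = as.numeric(beta_lg),
                    alpha_la = as.numeric(alpha_la),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$sample_id))
    stopf("duplicated sample_id in concentration table: %s",
          tab$sample_id[anyDuplicated(tab$sample_id)])
  if (any(tab$beta_lg < 0) || any(tab$alpha_la < 0))
    stopf("concentrations must be non-negative")
  class(tab) <- c("concentration_table", "data.frame")
  tab
}

#' Read a concentration table from CSV
#'
#' Expects header `sample_id,beta_lg_mg_ml,alpha_la_mg_ml`.
#'
#' @param path Path to a CSV file.
#' @return A [concentration_table()].
#' @export
read_concentrations <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = c(sample_id = "character"))
  need <- c("sample_id", "beta_lg_mg_ml", "alpha_la_mg_ml")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("concentration file is missing required column(s): %s",
          paste(miss, collapse = ", "))
  concentration_table(df$sample_id, df$beta_lg_mg_ml, df$alpha_la_mg_ml)
}

#' Write a concentration table to CSV
#' @param conc A [concentration_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(conc, path) {
  out <- data.frame(sample_id = conc$sample_id,
                    beta_lg_mg_ml = conc$beta_lg,
                    alpha_la_mg_ml = conc$alpha_la)
  old <- options(digits = 15)
  on.exit(options(old), add = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Join spectra to their reference concentrations
#'
#' Every spectrum row is matched to exactly one concentration pair by
#' `sample_id`; a spectrum whose sample is missing from the table is an
#' error.
#'
#' @param s A `spectra_set`.
#' @param conc A [concentration_table()].
#' @return A `data.frame` with one row per spectrum: `spectrum_id`,
#'   `sample_id`, `replicate`, `beta_lg`, `alpha_la`.
#' @export
join_concentrations <- function(s, conc) {
  idx <- match(s$sample_id, conc$sample_id)
  if (anyNA(idx))
    stopf("sample_id without concentrations: %s",
          paste(unique(s$sample_id[is.na(idx)]), collapse = ", "))
  data.frame(spectrum_id = s$spectrum_id, sample_id = s$sample_id,
             replicate = s$replicate,
             beta_lg = conc$beta_lg[idx], alpha_la = conc$alpha_la[idx],
             stringsAsFactors = FALSE)
}
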