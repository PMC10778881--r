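# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` leaves the stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage child seed from a master seed, keeping the result a
# valid 32-bit integer.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + offset) %% .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Contiguous fold assignment used by internal cross-validation: rows are
# shuffled under `seed`, then dealt round-robin into `nfolds` folds.
make_folds <- function(n, nfolds, seed = NULL) {
  nfolds <- min(nfolds, n)
  idx <- with_seed(seed, sample.int(n))
  split(idx, rep_len(seq_len(nfolds), n))
}
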