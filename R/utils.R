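# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required for reproducibility")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-stage seed derived from a global seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 2011L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_acgt <- function(sequences) {
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad)) {
    stop("non-ACGT characters in sequence(s): ",
         paste(utils::head(names(sequences)[bad] %||% which(bad), 5), collapse = ", "))
  }
  invisible(sequences)
}

# Laplace-corrected permutation p-value.
perm_p <- function(n_exceed, n_perm) (1 + n_exceed) / (1 + n_perm)
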