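# Fixture builders shared across test files. Everything is generated in code;
# the default synthetic study and its decontamination run are computed once
# per session and cached, since several files exercise them.

.cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.cache$study))
    .cache$study <- generate_study(simulation_config(seed = 1))
  .cache$study
}

default_decontam <- function() {
  if (is.null(.cache$decontam)) {
    st <- default_study()
    .cache$decontam <- run_decontamination(
      st$table, st$sequences, lab_reference = st$lab_reference, seed = 11)
  }
  .cache$decontam
}

# small hand-sized table: `n` samples x `p` ASVs of Poisson counts
tiny_table <- function(n = 6, p = 5, lambda = 20, seed = 99,
                       types = rep("concrete", n)) {
  set.seed(seed)
  counts <- matrix(rpois(n * p, lambda), n, p,
                   dimnames = list(sprintf("s%d", seq_len(n)),
                                   sprintf("asv%d", seq_len(p))))
  meta <- data.frame(sample_id = rownames(counts), sample_type = types,
                     series = "none", months = 0, temperature = 10,
                     replicate = as.character(seq_len(n)))
  asv_table(counts, meta)
}

# log-normal compositional counts with a planted correlation block
planted_block_counts <- function(n = 200, p = 50, block = 1:10, r = 0.8,
                                 depth = 5e4, seed = 42) {
  set.seed(seed)
  Sig <- diag(p)
  Sig[block, block] <- r
  diag(Sig) <- 1
  z <- matrix(rnorm(n * p), n, p) %*% chol(Sig)
  basis <- exp(z + 2)
  fr <- basis / rowSums(basis)
  counts <- t(apply(fr, 1, function(f) rmultinom(1, depth, f)[, 1]))
  dimnames(counts) <- list(sprintf("s%03d", seq_len(n)),
                           sprintf("A%02d", seq_len(p)))
  attr(counts, "log_basis") <- z
  counts
}

# brute-force Levenshtein distance by textbook recursion (memoised)
lev_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  memo <- matrix(NA_integer_, length(a) + 1, length(b) + 1)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- if (i == 0) j else if (j == 0) i else
      min(rec(i - 1, j) + 1L, rec(i, j - 1) + 1L,
          rec(i - 1, j - 1) + (a[i] != b[j]))
    memo[i + 1, j + 1] <<- v
    v
  }
  rec(length(a), length(b))
}

# disjoint synthetic sources: V sources each owning `per` exclusive taxa
disjoint_sources <- function(V = 3, per = 30, depth = 20000, seed = 2) {
  set.seed(seed)
  taxa <- sprintf("t%03d", seq_len(V * per))
  src <- matrix(0L, V, length(taxa),
                dimnames = list(sprintf("src%d", seq_len(V)), taxa))
  for (v in seq_len(V)) {
    own <- seq((v - 1) * per + 1, v * per)
    prof <- rgamma(per, 1); prof <- prof / sum(prof)
    src[v, own] <- rmultinom(1, depth, prof)[, 1]
  }
  src
}

mixture_sink <- function(src, weights, depth = 2000, seed = 3) {
  set.seed(seed)
  prof <- as.vector(weights %*% (src / rowSums(src)))
  sink <- rmultinom(1, depth, prof)[, 1]
  matrix(sink, nrow = 1, dimnames = list("sink1", colnames(src)))
}

fast_params <- function(seed = 1)
  sourcetrack_params(restarts = 4, burn_in = 50, draws = 20, thinning = 5,
                     source_depth = 5000, sink_depth = 635, seed = seed)

# a scaled-down study + fast stage settings for the pipeline tests
small_pipeline_config <- function(outdir, seed = 5) {
  if (is.null(.cache$small_study))
    .cache$small_study <- generate_study(simulation_config(
      seed = 3, n_true_asvs = 60, n_reagent_contaminants = 12,
      n_lab_contaminants = 8, n_edit_variants = 4, n_timepoints = 8,
      library_size_log_mean = log(2e4)))
  st <- .cache$small_study
  pipeline_config(
    table = st$table, sequences = st$sequences, tree = st$tree,
    lab_reference = st$lab_reference, outdir = outdir, seed = seed,
    sparcc_permutations = 100, rarefaction_depth = 500,
    permanova_permutations = 99, indicator_permutations = 99,
    interval_permutations = 49,
    sourcetrack = sourcetrack_params(restarts = 2, burn_in = 30, draws = 10,
                                     thinning = 3, source_depth = 2000,
                                     sink_depth = 300))
}

random_seqs <- function(n, len, seed = 1) {
  set.seed(seed)
  setNames(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)), sprintf("sq%d", seq_len(n)))
}
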