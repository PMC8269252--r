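#' Pairwise ASV association networks on compositional counts
#'
#' Amplicon counts are compositional: only relative information survives
#' sequencing, so naive correlations on proportions are spurious. The two
#' metrics provided infer association from log-ratio structure instead:
#' SparCC estimates "basis" correlations of absolute abundances under a
#' sparsity assumption, and proportionality rho scores agreement of
#' centered-log-ratio-transformed components. Both return a
#' `correlation_network`: a symmetric score matrix with unit diagonal, an
#' optional permutation p-value matrix, and a significance mask
#' (SparCC: |rho| > 0.35 and p < 0.05; rho: > 0.65 or < -0.5).
#'
#' @name correlation_network
NULL

new_network <- function(metric, scores, p = NULL, mask) {
  structure(list(metric = metric, scores = scores, p = p, mask = mask,
                 ids = colnames(scores)),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  n <- ncol(x$scores)
  cat(sprintf("correlation_network (%s): %d ASVs, %d significant edges\n",
              x$metric, n, sum(x$mask[upper.tri(x$mask)])))
  invisible(x)
}

# log fractions under the posterior-mean (add-one) estimate
point_log_fractions <- function(counts) {
  f <- (counts + 1) / rowSums(counts + 1)
  log(f)
}

# SparCC variation matrix and basis solve for a given log-fraction matrix.
# Exclusion state is an adjacency (inclusion) matrix over pairs.
sparcc_tmat <- function(logf) {
  C <- stats::cov(logf)
  v <- diag(C)
  outer(v, v, "+") - 2 * C
}

sparcc_basis_solve <- function(tmat, include) {
  d <- rowSums(include)
  A <- diag(d) + include
  b <- rowSums(tmat * include)
  omega <- solve(A, b)
  omega
}

sparcc_rho_from <- function(tmat, omega) {
  omega <- pmax(omega, 1e-12)
  r <- (outer(omega, omega, "+") - tmat) / (2 * sqrt(outer(omega, omega)))
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  r
}

# One full SparCC correlation estimate from a log-fraction matrix,
# with iterative strong-pair exclusion.
sparcc_correlate <- function(logf, exclusion_threshold, exclusion_rounds) {
  p <- ncol(logf)
  tmat <- sparcc_tmat(logf)
  include <- matrix(1, p, p) - diag(p)
  omega <- sparcc_basis_solve(tmat, include)
  rho <- sparcc_rho_from(tmat, omega)
  excluded <- matrix(FALSE, p, p)
  rounds <- 0
  while (rounds < exclusion_rounds) {
    cand <- abs(rho)
    diag(cand) <- 0
    cand[excluded] <- 0
    m <- max(cand)
    if (m <= exclusion_threshold) break
    ij <- which(cand == m, arr.ind = TRUE)[1, ]
    excluded[ij[1], ij[2]] <- excluded[ij[2], ij[1]] <- TRUE
    include[ij[1], ij[2]] <- include[ij[2], ij[1]] <- 0
    omega_new <- try(sparcc_basis_solve(tmat, include), silent = TRUE)
    if (inherits(omega_new, "try-error")) {
      warning("singular basis system after exclusions; using no-exclusion solve")
      include <- matrix(1, p, p) - diag(p)
      omega <- sparcc_basis_solve(tmat, include)
      rho <- sparcc_rho_from(tmat, omega)
      break
    }
    omega <- omega_new
    rho <- sparcc_rho_from(tmat, omega)
    rounds <- rounds + 1
  }
  list(rho = rho, omega = omega)
}

#' SparCC compositional correlation with permutation significance
#'
#' Fractions are estimated by averaging `iterations` Dirichlet(counts + 1)
#' posterior draws per sample; the variation matrix t_ij = var log(f_i/f_j) is
#' inverted for basis variances under the sparsity approximation, with the
#' strongest correlated pair iteratively excluded and the system re-solved.
#' Permutation p-values shuffle each ASV's counts across samples independently
#' and score the permuted data with the point-estimate fractions (no
#' re-resampling, no exclusions), a conservative and much cheaper null.
#'
#' @param table an [asv_table] (>= 4 ASVs, >= 3 samples).
#' @param iterations Dirichlet resamplings used for the fraction estimate.
#' @param exclusion_threshold,exclusion_rounds strong-pair exclusion controls.
#' @param permutations permutation count for p-values (0 disables).
#' @param seed integer RNG seed.
#' @param score_threshold,p_threshold significance-mask cutoffs.
#' @return A `correlation_network` with metric `"sparcc"`.
#' @export
sparcc <- function(table, iterations = 50, exclusion_threshold = 0.1,
                   exclusion_rounds = 10, permutations = 1000, seed = 1,
                   score_threshold = 0.35, p_threshold = 0.05) {
  counts <- if (inherits(table, "asv_table")) table$counts else as.matrix(table)
  if (ncol(counts) < 4) stop("sparcc needs >= 4 ASVs")
  if (nrow(counts) < 3) stop("sparcc needs >= 3 samples")
  if (any(counts < 0)) stop("negative counts")
  n <- nrow(counts); p <- ncol(counts)
  with_seed(seed, {
    if (iterations == 0) {
      # plug-in fractions without smoothing: exact algebra on positive data
      if (any(counts <= 0))
        stop("iterations = 0 (plug-in fractions) requires strictly positive data")
      logf <- log(counts / rowSums(counts))
    } else {
      fbar <- matrix(0, n, p)
      for (it in seq_len(iterations)) {
        g <- matrix(stats::rgamma(n * p, shape = counts + 1), n, p)
        fbar <- fbar + g / rowSums(g)
      }
      fbar <- fbar / iterations
      logf <- log(fbar)
    }
    fit <- sparcc_correlate(logf, exclusion_threshold, exclusion_rounds)
    rho <- fit$rho
    dimnames(rho) <- list(colnames(counts), colnames(counts))

    pmat <- NULL
    if (permutations > 0) {
      exceed <- matrix(0, p, p)
      target <- abs(rho)
      for (k in seq_len(permutations)) {
        perm <- apply(counts, 2, sample)
        lf <- if (iterations == 0) log(perm / rowSums(perm))
              else point_log_fractions(perm)
        tm <- sparcc_tmat(lf)
        om <- sparcc_basis_solve(tm, matrix(1, p, p) - diag(p))
        rp <- sparcc_rho_from(tm, om)
        exceed <- exceed + (abs(rp) >= target)
      }
      pmat <- (1 + exceed) / (1 + permutations)
      diag(pmat) <- 1
      dimnames(pmat) <- dimnames(rho)
    }
    mask <- abs(rho) > score_threshold &
      (if (is.null(pmat)) TRUE else pmat < p_threshold)
    diag(mask) <- FALSE
    attr(rho, "omega") <- stats::setNames(fit$omega, colnames(counts))
    new_network("sparcc", rho, pmat, mask)
  })
}

#' Proportionality rho on centered-log-ratio data
#'
#' rho_ij = 1 - var(a_i - a_j) / (var a_i + var a_j) on the clr transform of
#' counts + pseudocount. Significance is by fixed score cutoffs (> 0.65 or
#' < -0.5), the recommended FDR-controlling thresholds; no permutations.
#'
#' @param table an [asv_table] (>= 2 ASVs, >= 3 samples).
#' @param pseudocount added before the log transform.
#' @param pos_threshold,neg_threshold mask cutoffs.
#' @return A `correlation_network` with metric `"rho"`.
#' @export
proportionality_rho <- function(table, pseudocount = 1, pos_threshold = 0.65,
                                neg_threshold = -0.5) {
  counts <- if (inherits(table, "asv_table")) table$counts else as.matrix(table)
  if (ncol(counts) < 2) stop("rho needs >= 2 ASVs")
  if (nrow(counts) < 3) stop("rho needs >= 3 samples")
  lx <- log(counts + pseudocount)
  a <- lx - rowMeans(lx)           # clr per sample
  C <- stats::cov(a)
  v <- diag(C)
  denom <- outer(v, v, "+")
  rho <- 2 * C / denom
  zero_var <- v <= .Machine$double.eps * 100
  if (any(zero_var)) {
    warning("zero clr variance for ASV(s): ",
            paste(colnames(counts)[zero_var], collapse = ", "),
            "; their rho set to 0 and left unmasked")
    rho[zero_var, ] <- 0
    rho[, zero_var] <- 0
  }
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(counts), colnames(counts))
  mask <- rho > pos_threshold | rho < neg_threshold
  mask[zero_var, ] <- FALSE
  mask[, zero_var] <- FALSE
  diag(mask) <- FALSE
  new_network("rho", rho, NULL, mask)
}

#' Pairwise chi-square tests of count distributions
#'
#' For each ASV pair, a chi-square test on the 2 x S contingency table of
#' their counts across samples, with Monte-Carlo p-values under fixed margins.
#' Pairs with an all-zero margin get p = 1 and are flagged.
#'
#' @param table an [asv_table].
#' @param permutations Monte-Carlo tables per pair.
#' @param seed integer RNG seed.
#' @return list with symmetric matrices `p`, `statistic` and logical
#'   `degenerate`.
#' @export
pairwise_chisq <- function(table, permutations = 100000, seed = 1) {
  counts <- if (inherits(table, "asv_table")) table$counts else as.matrix(table)
  p_n <- ncol(counts)
  if (p_n < 2) stop("need >= 2 ASVs")
  ids <- colnames(counts)
  pm <- matrix(1, p_n, p_n, dimnames = list(ids, ids))
  sm <- matrix(0, p_n, p_n, dimnames = list(ids, ids))
  deg <- matrix(FALSE, p_n, p_n, dimnames = list(ids, ids))
  with_seed(seed, {
    for (i in seq_len(p_n - 1)) {
      for (j in seq(i + 1, p_n)) {
        tab <- rbind(counts[, i], counts[, j])
        tab <- tab[, colSums(tab) > 0, drop = FALSE]
        if (nrow(tab) < 2 || any(rowSums(tab) == 0) || ncol(tab) < 2) {
          deg[i, j] <- deg[j, i] <- TRUE
          next
        }
        if (identical(tab[1, ], tab[2, ])) {
          sm[i, j] <- sm[j, i] <- 0
          pm[i, j] <- pm[j, i] <- 1
          next
        }
        ct <- suppressWarnings(
          stats::chisq.test(tab, simulate.p.value = TRUE, B = permutations))
        pm[i, j] <- pm[j, i] <- ct$p.value
        sm[i, j] <- sm[j, i] <- unname(ct$statistic)
      }
    }
  })
  list(p = pm, statistic = sm, degenerate = deg)
}

#' Pairwise Levenshtein edit distances between ASV sequences
#'
#' Unit-cost substitutions, insertions and deletions; only A/C/G/T sequences
#' are accepted.
#'
#' @param records named character vector of DNA sequences.
#' @return symmetric integer matrix of edit distances with zero diagonal.
#' @export
edit_distances <- function(records) {
  if (!length(records) || any(!nzchar(records))) stop("non-empty sequences required")
  assert_acgt(records)
  d <- utils::adist(records)
  dimnames(d) <- list(names(records), names(records))
  storage.mode(d) <- "integer"
  d
}

#' Edge statistics between a candidate ASV and a focus set
#'
#' Counts significant (masked) positive and negative edges from `candidate`
#' to the focus set, and the mean of the raw scores to all focus members
#' (self-pairs excluded). This raw-score mean is what the classifier's "mean
#' correlation" thresholds consume.
#'
#' @param network a `correlation_network`.
#' @param focus character vector of ASV ids.
#' @param candidate single ASV id.
#' @return list with `n_pos`, `n_neg`, `mean_score`.
#' @export
neighborhood_stats <- function(network, focus, candidate) {
  if (!length(focus)) stop("focus set must be non-empty")
  focus <- setdiff(focus, candidate)
  if (!length(focus)) return(list(n_pos = 0L, n_neg = 0L, mean_score = NaN))
  sc <- network$scores[candidate, focus]
  mk <- network$mask[candidate, focus]
  list(n_pos = sum(mk & sc > 0), n_neg = sum(mk & sc < 0),
       mean_score = mean(sc))
}

#' Serialize a network as a TSV edge list
#'
#' @param network a `correlation_network`.
#' @param path output TSV (columns asv_i, asv_j, score, p, significant).
#' @export
write_network <- function(network, path) {
  idx <- which(upper.tri(network$scores), arr.ind = TRUE)
  df <- data.frame(asv_i = network$ids[idx[, 1]], asv_j = network$ids[idx[, 2]],
                   score = network$scores[idx],
                   p = if (is.null(network$p)) NA_real_ else network$p[idx],
                   significant = network$mask[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
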