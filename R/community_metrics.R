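#' Rarefy an ASV table to even depth
#'
#' Each sample is subsampled uniformly without replacement to exactly `depth`
#' reads; samples below `depth` are dropped and listed in the
#' `"dropped"` attribute.
#'
#' @param table an [asv_table].
#' @param depth target reads per sample (default 1000).
#' @param seed integer RNG seed.
#' @return A rarefied [asv_table].
#' @export
rarefy <- function(table, depth = 1000, seed = 1) {
  if (depth <= 0) stop("depth must be positive")
  depths <- rowSums(table$counts)
  dropped <- names(depths)[depths < depth]
  keep <- setdiff(sample_ids(table), dropped)
  if (!length(keep)) stop("no sample reaches the rarefaction depth")
  # rrarefy warns heuristically when tables lack singleton counts; depth
  # validity is enforced above, so the warning is noise here
  sub <- with_seed(seed, suppressWarnings(
    vegan::rrarefy(table$counts[keep, , drop = FALSE], depth)))
  out <- asv_table(sub, table$metadata[keep, , drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

#' Shannon diversity
#'
#' H = -sum p log_base p over nonzero proportions; base 2 (bits) by default.
#'
#' @param x a counts vector, a samples x ASVs matrix, or an [asv_table].
#' @param base logarithm base (2 for bits, `exp(1)` for nats).
#' @return numeric vector of per-sample diversities.
#' @export
shannon <- function(x, base = 2) {
  counts <- if (inherits(x, "asv_table")) x$counts else x
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  if (any(rowSums(counts) == 0)) stop("all-zero sample")
  vegan::diversity(counts, index = "shannon", base = base)
}

# edges on the path from each tip to the root, as a tips x edges indicator
tip_edge_paths <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  child_of <- tree$edge[, 2]
  edge_above <- integer(max(tree$edge))     # edge index whose child is node
  edge_above[child_of] <- seq_len(n_edge)
  root <- n_tip + 1L
  paths <- matrix(FALSE, n_tip, n_edge,
                  dimnames = list(tree$tip.label, NULL))
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  for (tip in seq_len(n_tip)) {
    node <- tip
    while (node != root) {
      paths[tip, edge_above[node]] <- TRUE
      node <- parent_of[node]
    }
  }
  paths
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths on the union of root-to-leaf paths of the taxa
#' observed in a sample.
#'
#' @param x a counts vector (named by ASV), matrix, or [asv_table].
#' @param tree rooted `phylo` with branch lengths; must cover all observed
#'   ASVs as leaves.
#' @return numeric vector of per-sample PD in branch-length units.
#' @export
faith_pd <- function(x, tree) {
  counts <- if (inherits(x, "asv_table")) x$counts else x
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list("s", names(x)))
  missing <- setdiff(colnames(counts)[colSums(counts) > 0], tree$tip.label)
  if (length(missing))
    stop("observed ASV(s) not in tree: ", paste(utils::head(missing, 5), collapse = ", "))
  if (any(rowSums(counts) == 0)) stop("all-zero sample")
  paths <- tip_edge_paths(tree)
  vapply(seq_len(nrow(counts)), function(i) {
    tips <- colnames(counts)[counts[i, ] > 0]
    used <- colSums(paths[tips, , drop = FALSE]) > 0
    sum(tree$edge.length[used])
  }, numeric(1))
}

# per-sample branch proportions: samples x edges matrix of descendant mass
branch_proportions <- function(props, tree) {
  paths <- tip_edge_paths(tree)            # tips x edges
  common <- intersect(colnames(props), rownames(paths))
  props[, common, drop = FALSE] %*% paths[common, , drop = FALSE]
}

#' Between-sample distance matrices
#'
#' Bray-Curtis and Jaccard (presence/absence) via their standard definitions;
#' the UniFrac family is computed from per-branch descendant mass on a rooted
#' tree. Generalized UniFrac with exponent `alpha` interpolates between
#' unweighted (branch presence) and weighted (branch mass) emphasis; at
#' `alpha = 1` it coincides with normalized weighted UniFrac.
#'
#' @param table an [asv_table].
#' @param metric one of `bray_curtis`, `jaccard`, `unweighted_unifrac`,
#'   `weighted_unifrac_raw`, `weighted_unifrac_normalized`,
#'   `generalized_unifrac`.
#' @param tree rooted `phylo`; required for the UniFrac family.
#' @param alpha generalized-UniFrac exponent in `[0, 1]` (default 0.5).
#' @return a `dist` object with the metric name as attribute `method`.
#' @export
distance_matrix <- function(table,
                            metric = c("bray_curtis", "jaccard",
                                       "unweighted_unifrac",
                                       "weighted_unifrac_raw",
                                       "weighted_unifrac_normalized",
                                       "generalized_unifrac"),
                            tree = NULL, alpha = 0.5) {
  metric <- match.arg(metric)
  counts <- table$counts
  props <- counts / rowSums(counts)
  if (metric == "bray_curtis") {
    d <- vegan::vegdist(counts, method = "bray")
  } else if (metric == "jaccard") {
    d <- vegan::vegdist(counts > 0, method = "jaccard")
  } else {
    if (is.null(tree)) stop("metric '", metric, "' requires a phylogenetic tree")
    bp <- branch_proportions(props, tree)
    bl <- tree$edge.length
    n <- nrow(bp)
    dm <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      pa <- bp[i, ]; pb <- bp[j, ]
      dm[i, j] <- dm[j, i] <- switch(metric,
        unweighted_unifrac = {
          ia <- pa > 0; ib <- pb > 0
          sum(bl[xor(ia, ib)]) / sum(bl[ia | ib])
        },
        weighted_unifrac_raw = sum(bl * abs(pa - pb)),
        weighted_unifrac_normalized =
          sum(bl * abs(pa - pb)) / sum(bl * (pa + pb)),
        generalized_unifrac = {
          s <- pa + pb
          keep <- s > 0
          w <- bl[keep] * s[keep]^alpha
          sum(w * abs(pa[keep] - pb[keep]) / s[keep]) / sum(w)
        })
    }
    d <- stats::as.dist(dm)
  }
  attr(d, "method") <- metric
  attr(d, "Labels") <- rownames(counts)
  d
}

#' Principal-coordinate analysis
#'
#' Eigendecomposition of the Gower-centered matrix -1/2 J d^2 J. Axes are
#' ordered by eigenvalue; negative eigenvalues are reported, not corrected.
#'
#' @param d a `dist` or symmetric matrix.
#' @param k number of axes to return (default all positive).
#' @return list with `coordinates`, `eigenvalues`, `proportion_explained`.
#' @export
pcoa_ordination <- function(d, k = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 3) stop("PCoA needs at least 3 samples")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > sqrt(.Machine$double.eps))
  k <- min(k %||% npos, ncol(fit$points))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- sprintf("PC%d", seq_len(k))
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = eig / sum(eig[eig > 0]))
}

#' PERMANOVA on a distance matrix
#'
#' McArdle-Anderson partition of the Gower-centered inner-product matrix over
#' the model terms, with pseudo-F and p-values by free permutation of sample
#' rows. Terms can be assessed sequentially (Type-I, in the order given) or
#' marginally (each term adjusted for all others).
#'
#' @param d a `dist` over the samples.
#' @param metadata data frame of covariates, rows aligned with `d` labels.
#' @param terms character vector of term names (columns of `metadata`).
#' @param mode `"sequential"` or `"marginal"`.
#' @param permutations number of permutations (default 999).
#' @param seed integer RNG seed.
#' @return data frame with columns `term`, `df`, `R2`, `F`, `p` (the
#'   sequential table also carries Residual and Total rows).
#' @export
permanova <- function(d, metadata, terms, mode = c("sequential", "marginal"),
                      permutations = 999, seed = 1) {
  mode <- match.arg(mode)
  metadata <- as.data.frame(metadata)
  labs <- attr(d, "Labels")
  if (!is.null(labs) && all(labs %in% rownames(metadata)))
    metadata <- metadata[labs, , drop = FALSE]
  for (tm in terms) {
    if (length(unique(metadata[[tm]])) < 2)
      stop("constant term column: ", tm)
  }
  f <- stats::as.formula(paste("d ~", paste(terms, collapse = " + ")))
  res <- with_seed(seed, vegan::adonis2(
    f, data = metadata, permutations = permutations,
    by = if (mode == "sequential") "terms" else "margin"))
  out <- data.frame(term = rownames(res), df = res$Df, R2 = res$R2,
                    F = res$F, p = res$`Pr(>F)`, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  out
}

#' Multivariate dispersion test
#'
#' Distances of samples to their group centroid in PCoA space (negative
#' eigenvalue axes contribute negatively to squared distances), with a
#' permutation F-test for homogeneity of dispersion.
#'
#' @param d a `dist`.
#' @param group factor of group labels.
#' @param permutations permutation count.
#' @param seed integer RNG seed.
#' @return list with `distances` (per sample), `F`, `p`.
#' @export
dispersion_test <- function(d, group, permutations = 999, seed = 1) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop("need >= 2 groups")
  if (any(table(group) < 2)) stop("singleton group")
  bd <- vegan::betadisper(d, group)
  pt <- with_seed(seed, vegan::permutest(bd, permutations = permutations))
  list(distances = bd$distances, F = pt$tab$F[1],
       p = pt$tab$`Pr(>F)`[1])
}

#' Mantel test between two distance matrices
#'
#' @param d1,d2 `dist` objects over the same samples.
#' @param method correlation type (default `"pearson"`).
#' @param permutations permutation count (default 999).
#' @param seed integer RNG seed.
#' @return list with `r` and `p`.
#' @export
mantel_test <- function(d1, d2, method = "pearson", permutations = 999,
                        seed = 1) {
  if (attr(stats::as.dist(d1), "Size") != attr(stats::as.dist(d2), "Size"))
    stop("distance matrices differ in size")
  res <- with_seed(seed, vegan::mantel(d1, d2, method = method,
                                       permutations = permutations))
  list(r = unname(res$statistic), p = res$signif)
}

#' Replicate similarity test
#'
#' Converts distances to similarities (1 - d), splits sample pairs into
#' within-replicate-group and between-sample sets, and applies a one-sided
#' Welch t test of within > between.
#'
#' @param d a `dist`.
#' @param groups replicate-group labels aligned with the samples of `d`.
#' @return list with `mean_within`, `mean_between`, `p`.
#' @export
replicate_similarity_test <- function(d, groups) {
  m <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) stop("groups must match samples")
  if (length(unique(groups)) < 2 || !any(duplicated(groups)))
    stop("degenerate replicate structure")
  idx <- which(upper.tri(m), arr.ind = TRUE)
  sim <- 1 - m[idx]
  same <- groups[idx[, 1]] == groups[idx[, 2]]
  mw <- mean(sim[same]); mb <- mean(sim[!same])
  p <- if (stats::var(sim[same]) + stats::var(sim[!same]) <
           .Machine$double.eps * 100) {
    # degenerate constant similarities: decide by the means alone
    if (mw > mb) 0 else if (mw < mb) 1 else 0.5
  } else {
    stats::t.test(sim[same], sim[!same], alternative = "greater",
                  var.equal = FALSE)$p.value
  }
  list(mean_within = mw, mean_between = mb, p = p)
}

#' Per-ASV occurrence-frequency entropy across groups
#'
#' For each ASV, its occurrence frequency in each group is normalized to sum
#' to 1 and the Shannon entropy (bits) of that distribution is reported. An
#' entropy of 0 means the ASV is confined to one group; log2(K) means equal
#' prevalence everywhere.
#'
#' @param table an [asv_table].
#' @param groups group labels partitioning the samples.
#' @return data frame with one row per ASV: per-group frequencies and
#'   `entropy` (NA for ASVs observed nowhere).
#' @export
occurrence_entropy <- function(table, groups) {
  groups <- as.factor(groups)
  if (length(groups) != nrow(table$counts)) stop("groups must match samples")
  pres <- table$counts > 0
  freq <- vapply(levels(groups), function(g)
    colMeans(pres[groups == g, , drop = FALSE]), numeric(ncol(pres)))
  freq <- matrix(freq, nrow = ncol(pres),
                 dimnames = list(colnames(pres), levels(groups)))
  tot <- rowSums(freq)
  rel <- freq / ifelse(tot > 0, tot, NA)
  ent <- apply(rel, 1, function(p) {
    p <- p[!is.na(p) & p > 0]
    if (!length(p)) return(NA_real_)
    -sum(p * log2(p))
  })
  out <- data.frame(asv_id = asv_ids(table), rel, entropy = ent,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out
}
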