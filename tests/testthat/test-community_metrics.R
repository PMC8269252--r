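star_tree <- function(tips, bl = 1) {
  tr <- ape::stree(length(tips), type = "star")
  tr$tip.label <- tips
  tr$edge.length <- rep(bl, nrow(tr$edge))
  tr
}

test_that("rarefaction subsamples exactly and reproducibly", {
  tab <- tiny_table(n = 4, p = 6, lambda = 400, seed = 12)
  r1 <- rarefy(tab, depth = 500, seed = 3)
  r2 <- rarefy(tab, depth = 500, seed = 3)
  expect_identical(r1$counts, r2$counts)
  expect_true(all(rowSums(r1$counts) == 500))
  expect_true(all(r1$counts <= tab$counts[sample_ids(r1), ]))

  # a sample already at depth is unchanged
  tab2 <- tiny_table(n = 2, p = 3, seed = 5)
  tab2$counts[1, ] <- c(400L, 300L, 300L)
  r3 <- rarefy(tab2, depth = 1000, seed = 1)
  expect_identical(unname(r3$counts["s1", ]), c(400L, 300L, 300L))
  expect_true("s2" %in% attr(r3, "dropped"))

  # expected per-ASV count = depth * proportion (hypergeometric mean)
  tab3 <- tiny_table(n = 1, p = 4, seed = 31)
  tab3$counts[1, ] <- c(5000L, 3000L, 1500L, 500L)
  draws <- vapply(1:200, function(i)
    rarefy(tab3, depth = 1000, seed = i)$counts[1, ], numeric(4))
  expected <- 1000 * tab3$counts[1, ] / 10000
  se <- sqrt(1000 * (tab3$counts[1, ] / 10000) *
               (1 - tab3$counts[1, ] / 10000)) / sqrt(200)
  expect_true(all(abs(rowMeans(draws) - expected) < 4 * se))
  expect_error(rarefy(tab3, depth = 0), "positive")
})

test_that("shannon and Faith's PD hit their closed forms", {
  x <- c(a = 5L, b = 5L, c = 5L, d = 5L)
  expect_equal(unname(shannon(x)), 2)                   # log2(4) bits
  expect_equal(unname(shannon(c(a = 9L, b = 0L))), 0)   # single taxon
  expect_error(shannon(c(a = 0L, b = 0L)), "all-zero")

  tr <- generate_tree(16, seed = 2)
  full <- setNames(rep(1L, 16), tr$tip.label)
  expect_equal(faith_pd(full, tr), sum(tr$edge.length))  # all leaves observed
  # single taxon: its root path length
  one <- setNames(c(1L, rep(0L, 15)), tr$tip.label)
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(faith_pd(one, tr), depths[1])
  # cross-check against an established implementation
  skip_if_not_installed("picante")
  tab <- tiny_table(n = 5, p = 16, seed = 77)
  colnames(tab$counts) <- tr$tip.label
  ours <- faith_pd(tab, tr)
  theirs <- picante::pd(tab$counts, tr, include.root = TRUE)$PD
  expect_equal(unname(ours), theirs, tolerance = 1e-10)
})

test_that("distance metrics satisfy their identities", {
  tr <- star_tree(sprintf("asv%d", 1:6))
  tab <- tiny_table(n = 4, p = 6, seed = 21)
  tab$counts[2, ] <- tab$counts[1, ]                      # duplicate sample
  tab$counts[3, ] <- c(3L, 8L, 1L, 0L, 0L, 0L)            # disjoint from s4
  tab$counts[4, ] <- c(0L, 0L, 0L, 5L, 2L, 9L)
  for (m in c("bray_curtis", "jaccard", "unweighted_unifrac",
              "weighted_unifrac_raw", "weighted_unifrac_normalized",
              "generalized_unifrac")) {
    d <- as.matrix(distance_matrix(tab, m, tree = tr))
    expect_equal(unname(d["s1", "s2"]), 0, tolerance = 1e-12,
                 label = paste(m, "identical samples"))
    expect_true(isSymmetric(d))
  }
  dj <- as.matrix(distance_matrix(tab, "jaccard"))
  du <- as.matrix(distance_matrix(tab, "unweighted_unifrac", tree = tr))
  expect_equal(unname(dj["s3", "s4"]), 1)   # disjoint sets on a star tree
  expect_equal(unname(du["s3", "s4"]), 1)
  expect_error(distance_matrix(tab, "unweighted_unifrac"), "tree")
})

test_that("generalized UniFrac at alpha 1 equals weighted-normalized", {
  set.seed(33)
  tr <- generate_tree(20, seed = 4)
  counts <- matrix(rpois(12 * 20, 15), 12, 20,
                   dimnames = list(sprintf("s%d", 1:12), tr$tip.label))
  counts[1, 1:10] <- 0L   # some structural zeros
  meta <- data.frame(sample_id = rownames(counts), sample_type = "concrete",
                     series = "none", months = 0, temperature = 0,
                     replicate = "r")
  tab <- asv_table(counts, meta)
  g1 <- as.matrix(distance_matrix(tab, "generalized_unifrac", tr, alpha = 1))
  wn <- as.matrix(distance_matrix(tab, "weighted_unifrac_normalized", tr))
  pairs <- which(upper.tri(g1), arr.ind = TRUE)
  expect_lt(max(abs(g1[pairs] - wn[pairs])), 1e-12)
  expect_gte(nrow(pairs), 50)

  # adding identical counts to both samples never increases the distance
  tab2 <- tab
  tab2$counts <- tab$counts + matrix(rep(counts[2, ], each = 12), 12, 20)
  g_before <- as.matrix(distance_matrix(tab, "generalized_unifrac", tr))
  g_after <- as.matrix(distance_matrix(tab2, "generalized_unifrac", tr))
  expect_true(all(g_after[upper.tri(g_after)] <=
                  g_before[upper.tri(g_before)] + 1e-9))

  # cross-check unweighted UniFrac against phyloseq
  skip_if_not_installed("phyloseq")
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(counts, taxa_are_rows = FALSE), ape::as.phylo(tr))
  theirs <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  ours <- as.matrix(distance_matrix(tab, "unweighted_unifrac", tr))
  expect_equal(ours[rownames(theirs), colnames(theirs)], theirs,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("PCoA reproduces known geometry", {
  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa_ordination(d3)
  pos <- p3$eigenvalues[p3$eigenvalues > 1e-9]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  # points on a line: a single positive eigenvalue recovers the line
  x <- c(0, 1, 3, 7, 12)
  dl <- as.matrix(dist(x)); dimnames(dl) <- list(letters[1:5], letters[1:5])
  pl <- pcoa_ordination(dl)
  expect_lt(sum(abs(pl$eigenvalues[-1])), 1e-9)
  expect_equal(as.matrix(dist(pl$coordinates[, 1])), dl, tolerance = 1e-9,
               ignore_attr = TRUE)

  # Euclidean input: embedded distances reproduce d
  set.seed(2)
  y <- matrix(rnorm(20), 10, 2)
  de <- as.matrix(dist(y)); dimnames(de) <- list(letters[1:10], letters[1:10])
  pe <- pcoa_ordination(de, k = 9)
  expect_equal(as.matrix(dist(pe$coordinates)), de, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(pcoa_ordination(dist(1:2)), "at least 3")
})

test_that("PERMANOVA separates planted groups and partitions variance", {
  set.seed(6)
  g <- rep(c("a", "b"), each = 10)
  y <- matrix(rnorm(20 * 4), 20, 4) + ifelse(g == "a", 0, 8)
  d <- dist(y)
  attr(d, "Labels") <- sprintf("s%d", 1:20)
  meta <- data.frame(grp = g, cov = rnorm(20),
                     row.names = sprintf("s%d", 1:20))
  res <- permanova(d, meta, c("cov", "grp"), "sequential",
                   permutations = 199, seed = 3)
  expect_equal(res$p[res$term == "grp"], 1 / 200, tolerance = 1e-12)
  expect_equal(sum(res$R2[res$term != "Total"]), 1, tolerance = 1e-9)
  # single-term model: sequential and marginal agree
  r1 <- permanova(d, meta, "grp", "sequential", 99, seed = 4)
  r2 <- permanova(d, meta, "grp", "marginal", 99, seed = 4)
  expect_equal(r1$F[1], r2$F[1])
  expect_equal(r1$p[1], r2$p[1])
  expect_error(permanova(d, transform(meta, k = 1), "k", "sequential"),
               "constant term")
})

test_that("dispersion, Mantel and replicate-similarity behave at their anchors", {
  set.seed(9)
  # zero-dispersion group vs dispersed group
  pts <- rbind(matrix(0, 6, 2), matrix(rnorm(12, sd = 3), 6, 2))
  pts[1:6, ] <- pts[1:6, ] + matrix(rnorm(12, sd = 1e-3), 6, 2)
  d <- dist(pts)
  g <- rep(c("tight", "loose"), each = 6)
  res <- dispersion_test(d, g, permutations = 199, seed = 2)
  expect_lt(res$p, 0.05)
  expect_error(dispersion_test(d, rep(c("a", "b", "c", "c"), c(1, 1, 5, 5))),
               "singleton")

  d1 <- dist(matrix(rnorm(30), 10, 3))
  expect_equal(mantel_test(d1, d1, permutations = 99, seed = 1)$r, 1,
               tolerance = 1e-12)
  expect_equal(mantel_test(d1, 0.3 + 2 * d1, permutations = 99, seed = 1)$r, 1,
               tolerance = 1e-12)

  # replicate similarity: within 0.9, between 0.1
  m <- matrix(0.9, 6, 6)
  m[1:3, 1:3] <- 0.1; m[4:6, 4:6] <- 0.1
  diag(m) <- 0
  dimnames(m) <- list(sprintf("s%d", 1:6), sprintf("s%d", 1:6))
  rs <- replicate_similarity_test(as.dist(m), rep(c("g1", "g2"), each = 3))
  expect_equal(rs$mean_within, 0.9)
  expect_equal(rs$mean_between, 0.1)
  expect_lt(rs$p, 1e-6)
})

test_that("occurrence entropy matches hand arithmetic", {
  counts <- rbind(g1a = c(5L, 1L, 2L), g1b = c(3L, 2L, 1L),
                  g2a = c(0L, 4L, 1L), g2b = c(0L, 2L, 0L),
                  g3a = c(0L, 0L, 1L), g3b = c(0L, 0L, 0L))
  colnames(counts) <- c("only1", "in12", "spread")
  meta <- data.frame(sample_id = rownames(counts), sample_type = "concrete",
                     series = "none", months = 0, temperature = 0,
                     replicate = "r")
  tab <- asv_table(counts, meta)
  groups <- rep(c("g1", "g2", "g3"), each = 2)
  res <- occurrence_entropy(tab, groups)
  e <- setNames(res$entropy, res$asv_id)
  expect_equal(e[["only1"]], 0)                    # confined to one group
  expect_equal(e[["in12"]], 1)                     # 50/50 over two groups
  # spread: freqs (1, 0.5, 0.5) -> normalized (0.5, 0.25, 0.25) -> 1.5 bits
  expect_equal(e[["spread"]], 1.5)
  # 4 equal groups -> 2 bits
  tab2 <- tiny_table(n = 8, p = 1, lambda = 9, seed = 13)
  tab2$counts[] <- 1L
  res2 <- occurrence_entropy(tab2, rep(1:4, each = 2))
  expect_equal(res2$entropy, 2)
  # absent ASV -> NA
  tab3 <- tab; tab3$counts[, "only1"] <- 0L
  expect_true(is.na(occurrence_entropy(tab3, groups)$entropy[1]))
})

test_that("distances are invariant to sample relabeling", {
  tr <- generate_tree(10, seed = 8)
  tab <- tiny_table(n = 5, p = 10, seed = 41)
  colnames(tab$counts) <- tr$tip.label
  perm <- c(3, 1, 5, 2, 4)
  tabp <- asv_subset(tab, samples = sample_ids(tab)[perm])
  for (m in c("bray_curtis", "generalized_unifrac")) {
    d0 <- as.matrix(distance_matrix(tab, m, tree = tr))
    dp <- as.matrix(distance_matrix(tabp, m, tree = tr))
    expect_equal(dp[rownames(d0), colnames(d0)], d0, tolerance = 1e-12)
  }
})
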