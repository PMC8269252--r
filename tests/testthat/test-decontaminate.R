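# a small network fixture whose edges are set by hand
hand_network <- function(ids, edges, metric = "sparcc", threshold = 0.35) {
  sc <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  diag(sc) <- 1
  for (e in edges) sc[e[[1]], e[[2]]] <- sc[e[[2]], e[[1]]] <- as.numeric(e[[3]])
  mask <- abs(sc) > threshold
  diag(mask) <- FALSE
  structure(list(metric = metric, scores = sc, p = NULL, mask = mask,
                 ids = ids), class = "correlation_network")
}

test_that("prevalence test matches exact hypergeometric tails and boundaries", {
  counts <- matrix(0L, 93, 3, dimnames = list(
    c(sprintf("n%d", 1:3), sprintf("c%d", 1:90)), c("negonly", "absent", "everywhere")))
  counts[1:3, "negonly"] <- 10L
  counts[, "everywhere"] <- 5L
  counts[4:93, "absent"] <- 2L
  meta <- data.frame(sample_id = rownames(counts),
                     sample_type = c(rep("negative_control", 3), rep("concrete", 90)),
                     series = "none", months = 0, temperature = 1, replicate = "r")
  tab <- asv_table(counts, meta)
  res <- prevalence_test(tab)
  r <- setNames(res$p, res$asv_id)
  # 3/3 negatives, 0/90 samples: one-sided Fisher p = 1/choose(93,3)
  expect_equal(r[["negonly"]], 1 / choose(93, 3), tolerance = 1e-12)
  expect_true(res$flagged[res$asv_id == "negonly"])
  # 0/3 negatives: no evidence in the contaminant direction
  expect_equal(r[["absent"]], 1)
  # equal prevalence everywhere: p = 1
  expect_equal(r[["everywhere"]], 1)
  expect_false(any(res$flagged[res$asv_id != "negonly"]))
  expect_error(prevalence_test(asv_subset(tab, samples = sprintf("c%d", 1:90))),
               "negative controls")
})

test_that("negative_only applies the strict zero rule", {
  st <- default_study()
  found <- negative_only(st$table)
  # all planted negative-only reagent ASVs are recovered...
  expect_true(all(st$truth$negative_only %in% found))
  # ...and nothing genuinely observed in a real sample is returned
  neg <- st$table$metadata$sample_type == "negative_control"
  expect_true(all(colSums(st$table$counts[!neg, found, drop = FALSE]) == 0))
  # every returned ASV is a planted contaminant, never a true taxon
  expect_true(all(st$truth$labels[found] != "true_community"))

  # single read in one concrete sample disqualifies
  tab <- st$table
  one <- st$truth$negative_only[1]
  tab$counts[which(!neg)[1], one] <- 1L
  expect_false(one %in% negative_only(tab))
})

test_that("core cluster and expansion follow the printed rules exactly", {
  ids <- c(sprintf("neg%d", 1:3), "cand", "far")
  # neg1-neg2, neg1-neg3 strongly positive; neg2-neg3 positive
  net <- hand_network(ids, list(
    list("neg1", "neg2", 0.8), list("neg1", "neg3", 0.7),
    list("neg2", "neg3", 0.6), list("cand", "neg1", 0.5),
    list("cand", "neg2", 0.45), list("far", "neg1", -0.6)))
  rules <- decontam_rules()
  core <- core_reagent_cluster(list(sparcc = net), sprintf("neg%d", 1:3), rules)
  expect_setequal(core$sparcc, c("neg1", "neg2", "neg3"))

  # a member with only negative masked edges is excluded
  net2 <- hand_network(ids, list(
    list("neg1", "neg2", 0.8), list("neg1", "neg3", -0.7),
    list("neg2", "neg3", -0.6)))
  core2 <- core_reagent_cluster(list(sparcc = net2), sprintf("neg%d", 1:3), rules)
  expect_false("neg3" %in% core2$sparcc)

  expect_warning(core_reagent_cluster(list(sparcc = net), "neg1", rules),
                 "fewer than 2")

  # reagent expansion boundary: sparcc needs n_pos > 10, strictly
  seeds <- sprintf("s%02d", 1:12)
  edges10 <- lapply(seeds[1:10], function(s) list("cand", s, 0.5))
  edges11 <- lapply(seeds[1:11], function(s) list("cand", s, 0.5))
  net10 <- hand_network(c(seeds, "cand"), edges10)
  net11 <- hand_network(c(seeds, "cand"), edges11)
  expect_false("cand" %in% expand_from_seeds(list(sparcc = net10), seeds,
                                             "reagent", rules))
  expect_true("cand" %in% expand_from_seeds(list(sparcc = net11), seeds,
                                            "reagent", rules))
  # but mean must also clear 0.25: strong negatives drag the mean below it
  seeds <- sprintf("s%02d", 1:14)
  edges_low <- c(lapply(seeds[1:11], function(s) list("cand", s, 0.4)),
                 lapply(seeds[12:14], function(s) list("cand", s, -0.9)))
  net_low <- hand_network(c(seeds, "cand"), edges_low)
  s <- neighborhood_stats(net_low, seeds, "cand")
  expect_true(s$mean_score < 0.25 && s$n_pos > 10)
  expect_false("cand" %in% expand_from_seeds(list(sparcc = net_low), seeds,
                                             "reagent", rules))
  expect_error(expand_from_seeds(list(sparcc = net10), character(0), "reagent"),
               "non-empty")
  expect_error(expand_from_seeds(list(sparcc = net10), seeds, "bogus"))
})

test_that("lab seeds use strict >99% global identity", {
  ref <- random_seqs(1, 420, seed = 31)
  names(ref) <- "strain1"
  exact <- ref[[1]]
  five <- exact; four <- exact
  set.seed(8)
  pos <- sample(420, 9)
  sub <- function(s, at) {
    v <- strsplit(s, "")[[1]]
    for (p in at) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  recs <- c(copy = exact, mut5 = sub(exact, pos[1:5]), mut4 = sub(exact, pos[1:4]))
  hits <- lab_seeds(recs, ref)
  expect_true("copy" %in% hits)   # identity 1.0
  expect_false("mut5" %in% hits)  # 1 - 5/420 = 0.988 < 0.99
  expect_true("mut4" %in% hits)   # 1 - 4/420 = 0.9905 > 0.99
  expect_warning(none <- lab_seeds(recs, character(0)), "empty lab reference")
  expect_length(none, 0)
})

test_that("edit propagation is single-pass with deterministic tie-breaks", {
  seqs <- c(conA = "AAAAAAAA", conB = "CCCCCCCC",
            v1 = "AAAAAAAT",          # distance 1 from conA
            far = "GGGGGGGG",         # distance 8 from everything
            mid = "AAAAAATT")         # distance 1 from v1, 2 from conA
  em <- utils::adist(seqs)
  dimnames(em) <- list(names(seqs), names(seqs))
  res <- propagate_edit_neighbors(c("conA", "conB"), em, max_dist = 1)
  expect_equal(res$asv_id, "v1")
  expect_equal(res$parent, "conA")
  # distance-2 ASV is retained under single-pass semantics
  expect_false("mid" %in% res$asv_id)
  # transitive mode reaches it through v1
  res_t <- propagate_edit_neighbors(c("conA", "conB"), em, max_dist = 1,
                                    transitive = TRUE)
  expect_setequal(res_t$asv_id, c("v1", "mid"))
  # equidistant tie goes to the lexicographically smaller parent
  seqs2 <- c(a_con = "AAAA", b_con = "AAAT", v = "AAAG")
  em2 <- utils::adist(seqs2); dimnames(em2) <- list(names(seqs2), names(seqs2))
  res2 <- propagate_edit_neighbors(c("a_con", "b_con"), em2, 1)
  expect_equal(res2$parent[res2$asv_id == "v"], "a_con")
})

test_that("full decontamination recovers planted contaminants", {
  st <- default_study()
  res <- default_decontam()
  truth <- st$truth$labels
  contam_truth <- names(truth)[truth != "true_community"]
  called <- res$calls$asv_id[res$calls$verdict == "contaminant"]
  expect_gte(mean(contam_truth %in% called), 0.90)
  true_ids <- names(truth)[truth == "true_community"]
  expect_lte(mean(true_ids %in% called), 0.10)
  # every planted single-edit variant is flagged
  expect_true(all(names(st$truth$edit_parent) %in% called))
  # every negatives-only ASV is flagged
  expect_true(all(st$truth$negative_only %in% called))
  # clean table is an exact sub-matrix of the input
  kept <- asv_ids(res$clean_table)
  expect_identical(res$clean_table$counts, st$table$counts[, kept])
  # retained calls carry no category or methods
  ret <- res$calls[res$calls$verdict == "retained", ]
  expect_true(all(ret$category == "" & ret$flagged_by == ""))
  # report accounting is consistent
  expect_equal(res$report$n_contaminant + res$report$n_retained,
               res$report$n_input)
})

test_that("vacuous rules flag nothing and first-stage-wins sets category", {
  st <- default_study()
  rules <- decontam_rules(prevalence_threshold = 0)
  never <- function(s) FALSE
  for (stage in c("core", "reagent", "lab", "secondary"))
    rules[[stage]] <- list(sparcc = never, rho = never)
  rules$lab_identity <- 1.5
  # drop negatives so the strict negative-only rule cannot fire either
  neg <- st$table$metadata$sample_type == "negative_control"
  keep_asvs <- asv_ids(st$table)[colSums(st$table$counts[!neg, , drop = FALSE]) > 0]
  tab <- asv_subset(st$table, asvs = keep_asvs)
  tab$counts[neg, ] <- 0L
  tab$counts[which(neg), keep_asvs[1]] <- 1L  # keep negatives non-empty
  nets <- list(sparcc = sparcc(tab, permutations = 0, seed = 5),
               rho = proportionality_rho(tab))
  # the single surviving negative-control read leaves <2 negative ASVs, so
  # the core stage warns and returns empty — expected here
  res <- suppressWarnings(run_decontamination(tab, st$sequences[keep_asvs],
                                              nets, st$lab_reference, rules))
  expect_equal(res$report$n_contaminant, 0)
  expect_identical(res$clean_table$counts, tab$counts)

  # first-stage precedence: an ASV flagged by prevalence keeps that category
  # even when later correlation stages also hit it
  full <- default_decontam()
  both <- full$calls[full$calls$category == "prevalence" &
                     grepl("sparcc|rho", full$calls$flagged_by), ]
  if (nrow(both)) {
    expect_true(all(grepl("decontam_prevalence", both$flagged_by)))
    expect_true(all(both$stage == 1))
  }
})
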