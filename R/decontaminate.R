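#' Decision thresholds of the contaminant classifier
#'
#' All rule inequalities are strict. The defaults encode the published working
#' point of the classifier: a prevalence p-value cutoff of 0.33; a core
#' reagent cluster among negative-control ASVs (SparCC: net positive edges
#' > 0 and mean correlation > 0.3; rho: net positive edges > 0); expansion
#' from the reagent core (SparCC: > 10 positive edges and mean > 0.25; rho:
#' net positive > 0); lab-strain identity > 0.99; expansion from lab seeds
#' (SparCC: > 1 positive edge and mean > 0.3; rho: > 0 positive edges); a
#' secondary screen of everything remaining against the full contaminant list
#' (SparCC: mean > 0.3 and > 5 positive edges; rho: mean > 0.3 and > 1
#' positive edge); and edit-distance propagation at distance 1.
#'
#' @param prevalence_threshold p-value cutoff for the prevalence test.
#' @param lab_identity minimum global-alignment identity to a lab strain.
#' @param edit_distance_max propagation radius in edits.
#' @return A `decontam_rules` list; pass to [run_decontamination()].
#' @export
decontam_rules <- function(prevalence_threshold = 0.33, lab_identity = 0.99,
                           edit_distance_max = 1) {
  structure(list(
    prevalence_threshold = prevalence_threshold,
    core = list(
      sparcc = function(s) (s$n_pos - s$n_neg) > 0 && s$mean_score > 0.3,
      rho    = function(s) (s$n_pos - s$n_neg) > 0),
    reagent = list(
      sparcc = function(s) s$n_pos > 10 && s$mean_score > 0.25,
      rho    = function(s) (s$n_pos - s$n_neg) > 0),
    lab = list(
      sparcc = function(s) s$n_pos > 1 && s$mean_score > 0.3,
      rho    = function(s) s$n_pos > 0),
    secondary = list(
      sparcc = function(s) s$mean_score > 0.3 && s$n_pos > 5,
      rho    = function(s) s$mean_score > 0.3 && s$n_pos > 1),
    lab_identity = lab_identity,
    edit_distance_max = edit_distance_max), class = "decontam_rules")
}

#' Prevalence test for contaminant enrichment in negative controls
#'
#' Per ASV, a 2 x 2 presence/absence table (negative vs. real samples) is
#' tested one-sided for presence enrichment in negatives: Fisher's exact test
#' when any expected cell is below 5, otherwise a chi-square test without
#' continuity correction. An ASV is flagged when p <= threshold; the lenient
#' default cutoff of 0.33 reflects that in very-low-biomass data the prior
#' odds of contamination are high.
#'
#' @param table an [asv_table].
#' @param is_negative logical vector over samples, or NULL to use
#'   `sample_type == "negative_control"`.
#' @param threshold decision boundary on the p-value.
#' @return data frame with `asv_id`, `p`, `flagged`.
#' @export
prevalence_test <- function(table, is_negative = NULL, threshold = 0.33) {
  if (is.null(is_negative))
    is_negative <- table$metadata$sample_type == "negative_control"
  if (!any(is_negative)) stop("prevalence test undefined without negative controls")
  if (all(is_negative)) stop("prevalence test needs non-negative samples")
  pres <- table$counts > 0
  n_neg <- sum(is_negative); n_smp <- sum(!is_negative)
  p <- vapply(seq_len(ncol(pres)), function(j) {
    a <- sum(pres[is_negative, j])        # present in negatives
    c_ <- sum(pres[!is_negative, j])      # present in samples
    x <- rbind(c(a, n_neg - a), c(c_, n_smp - c_))
    expected <- outer(rowSums(x), colSums(x)) / sum(x)
    if (any(expected < 5)) {
      stats::fisher.test(x, alternative = "greater")$p.value
    } else {
      prop_neg <- a / n_neg; prop_smp <- c_ / n_smp
      stat <- suppressWarnings(stats::chisq.test(x, correct = FALSE)$statistic)
      if (is.na(stat)) 1 else
        stats::pnorm(sign(prop_neg - prop_smp) * sqrt(stat), lower.tail = FALSE)
    }
  }, numeric(1))
  data.frame(asv_id = asv_ids(table), p = p, flagged = p <= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' ASVs found only in negative controls
#'
#' Strict rule: zero counts in every real sample and at least one read in a
#' negative control. Such ASVs are reagent contaminants by definition.
#'
#' @param table an [asv_table].
#' @return character vector of ASV ids.
#' @export
negative_only <- function(table) {
  neg <- table$metadata$sample_type == "negative_control"
  ids <- asv_ids(table)
  in_neg <- colSums(table$counts[neg, , drop = FALSE]) > 0
  in_smp <- colSums(table$counts[!neg, , drop = FALSE]) > 0
  ids[in_neg & !in_smp]
}

#' Core cluster of intercorrelated reagent contaminants
#'
#' Among the ASVs observed in negative controls, each metric independently
#' selects members whose edges to the other negative-control ASVs satisfy its
#' core rule (more strong positive than strong negative edges; for SparCC
#' additionally a mean correlation above 0.3).
#'
#' @param networks named list of `correlation_network`s (`sparcc`, `rho`).
#' @param neg_asvs ASV ids observed in negative controls.
#' @param rules a [decontam_rules()] object.
#' @return named list of character vectors, one per metric.
#' @export
core_reagent_cluster <- function(networks, neg_asvs, rules = decontam_rules()) {
  if (length(neg_asvs) < 2) {
    warning("fewer than 2 negative-control ASVs; empty reagent core")
    return(lapply(networks, function(x) character(0)))
  }
  lapply(stats::setNames(names(networks), names(networks)), function(m) {
    rule <- rules$core[[m]]
    keep <- vapply(neg_asvs, function(a) {
      s <- neighborhood_stats(networks[[m]], setdiff(neg_asvs, a), a)
      isTRUE(rule(s))
    }, logical(1))
    neg_asvs[keep]
  })
}

#' Expand a contaminant set through the correlation networks
#'
#' Every non-seed ASV whose edges to the seed set satisfy a metric's rule for
#' the given rule set (reagent, lab, or secondary) is flagged; the result is
#' the union over metrics, with per-metric attribution attached.
#'
#' @param networks named list of `correlation_network`s.
#' @param seeds character vector of seed contaminant ids.
#' @param rule_set `"reagent"`, `"lab"` or `"secondary"`.
#' @param rules a [decontam_rules()] object.
#' @return character vector of newly flagged ids, with attribute
#'   `by_metric` (named list).
#' @export
expand_from_seeds <- function(networks, seeds,
                              rule_set = c("reagent", "lab", "secondary"),
                              rules = decontam_rules()) {
  rule_set <- match.arg(rule_set)
  if (!length(seeds)) stop("seed set must be non-empty")
  by_metric <- lapply(stats::setNames(names(networks), names(networks)),
                      function(m) {
    net <- networks[[m]]
    rule <- rules[[rule_set]][[m]]
    cands <- setdiff(net$ids, seeds)
    keep <- vapply(cands, function(a) {
      isTRUE(rule(neighborhood_stats(net, seeds, a)))
    }, logical(1))
    cands[keep]
  })
  out <- unique(unlist(by_metric, use.names = FALSE)) %||% character(0)
  attr(out, "by_metric") <- by_metric
  out
}

#' ASVs matching laboratory reference strains
#'
#' Identity is computed as 1 - Levenshtein distance / max(sequence lengths),
#' a global-alignment identity; an ASV is a lab seed when its best identity to
#' any reference strain strictly exceeds `min_identity`.
#'
#' @param records named character vector of ASV sequences.
#' @param lab_reference named character vector of lab strain sequences.
#' @param min_identity identity cutoff (default 0.99).
#' @return character vector of flagged ASV ids.
#' @export
lab_seeds <- function(records, lab_reference, min_identity = 0.99) {
  if (!length(lab_reference)) {
    warning("empty lab reference; no lab seeds")
    return(character(0))
  }
  d <- utils::adist(records, lab_reference)
  len <- outer(nchar(records), nchar(lab_reference), pmax)
  identity <- 1 - d / len
  names(records)[apply(identity, 1, max) > min_identity]
}

#' Propagate contaminant status to single-edit neighbors
#'
#' A single pass over the pre-propagation contaminant set: every retained ASV
#' within `max_dist` edits of an identified contaminant is itself flagged,
#' inheriting its closest match's category (ties by smallest distance, then
#' lexicographically smallest parent id).
#'
#' @param contaminants character vector of contaminant ids.
#' @param edit_matrix symmetric edit-distance matrix covering all ASVs.
#' @param max_dist propagation radius (default 1).
#' @param transitive if TRUE, iterate to closure instead of a single pass.
#' @return data frame with `asv_id`, `parent`, `distance`.
#' @export
propagate_edit_neighbors <- function(contaminants, edit_matrix, max_dist = 1,
                                     transitive = FALSE) {
  all_ids <- rownames(edit_matrix)
  found <- data.frame(asv_id = character(0), parent = character(0),
                      distance = integer(0), stringsAsFactors = FALSE)
  frontier <- intersect(contaminants, all_ids)
  repeat {
    retained <- setdiff(all_ids, c(contaminants, found$asv_id))
    if (!length(retained) || !length(frontier)) break
    d <- edit_matrix[retained, frontier, drop = FALSE]
    hit <- which(apply(d, 1, min) <= max_dist)
    if (!length(hit)) break
    newly <- lapply(names(hit), function(a) {
      row <- stats::setNames(d[a, ], colnames(d))
      dmin <- min(row)
      parent <- sort(colnames(d)[row == dmin])[1]
      data.frame(asv_id = a, parent = parent, distance = as.integer(dmin),
                 stringsAsFactors = FALSE)
    })
    newly <- do.call(rbind, newly)
    found <- rbind(found, newly)
    if (!transitive) break
    frontier <- newly$asv_id
  }
  found
}

#' Run the full multi-stage decontamination pipeline
#'
#' Stages are applied in order: (1) prevalence test against negative
#' controls; (2) reagent contaminants — core cluster among negative-control
#' ASVs, correlation expansion from that core, and the strict negatives-only
#' rule; (3) lab contaminants — reference-strain identity seeds and
#' correlation expansion; (4) a secondary correlation screen of all remaining
#' ASVs against the accumulated contaminant list; (5) edit-distance
#' propagation. An ASV's category is its first flagging stage; `flagged_by`
#' accumulates every method that hit it across stages.
#'
#' @param table an [asv_table] (must include negative controls).
#' @param records named character vector of ASV sequences.
#' @param networks named list of `correlation_network`s (`sparcc`, `rho`);
#'   computed from `table` if NULL.
#' @param lab_reference named character vector of lab strain sequences.
#' @param rules a [decontam_rules()] object.
#' @param seed RNG seed used when networks must be computed.
#' @return list with `calls` (data frame), `clean_table` (an [asv_table]
#'   containing only retained ASVs, counts untouched), and `report`.
#' @export
run_decontamination <- function(table, records, networks = NULL,
                                lab_reference = character(0),
                                rules = decontam_rules(), seed = 1) {
  ids <- asv_ids(table)
  if (is.null(networks)) {
    networks <- list(sparcc = sparcc(table, seed = derive_seed(seed, 1)),
                     rho = proportionality_rho(table))
  }
  category <- stats::setNames(rep(NA_character_, length(ids)), ids)
  flagged_by <- stats::setNames(vector("list", length(ids)), ids)
  parent <- stats::setNames(rep(NA_character_, length(ids)), ids)
  note <- function(asvs, cat, methods) {
    asvs <- intersect(asvs, ids)
    first <- asvs[is.na(category[asvs])]
    category[first] <<- cat
    for (a in asvs) flagged_by[[a]] <<- union(flagged_by[[a]], methods)
  }

  # stage 1: prevalence
  prev <- prevalence_test(table, threshold = rules$prevalence_threshold)
  note(prev$asv_id[prev$flagged], "prevalence", "decontam_prevalence")

  # stage 2: reagent
  neg <- table$metadata$sample_type == "negative_control"
  neg_asvs <- ids[colSums(table$counts[neg, , drop = FALSE]) > 0]
  core <- core_reagent_cluster(networks, neg_asvs, rules)
  for (m in names(core)) note(core[[m]], "reagent_core", m)
  core_all <- unique(unlist(core, use.names = FALSE))
  if (length(core_all)) {
    exp_r <- expand_from_seeds(networks, core_all, "reagent", rules)
    for (m in names(attr(exp_r, "by_metric")))
      note(attr(exp_r, "by_metric")[[m]], "reagent_expanded", m)
  }
  note(negative_only(table), "negative_only", "negative_only")

  # stage 3: lab
  labs <- intersect(lab_seeds(records, lab_reference, rules$lab_identity), ids)
  note(labs, "lab_seed", "blast_identity")
  if (length(labs)) {
    exp_l <- expand_from_seeds(networks, labs, "lab", rules)
    for (m in names(attr(exp_l, "by_metric")))
      note(attr(exp_l, "by_metric")[[m]], "lab_expanded", m)
  }

  # stage 4: secondary screen against the master list so far
  master <- ids[!is.na(category)]
  if (length(master)) {
    exp_s <- expand_from_seeds(networks, master, "secondary", rules)
    for (m in names(attr(exp_s, "by_metric")))
      note(attr(exp_s, "by_metric")[[m]], "secondary", m)
  }

  # stage 5: edit-distance propagation
  em <- edit_distances(records[ids])
  prop <- propagate_edit_neighbors(ids[!is.na(category)], em,
                                   rules$edit_distance_max)
  if (nrow(prop)) {
    for (k in seq_len(nrow(prop))) {
      a <- prop$asv_id[k]; pa <- prop$parent[k]
      category[a] <- "edit_neighbor"
      parent[a] <- pa
      flagged_by[[a]] <- union(flagged_by[[pa]], "edit_distance")
    }
  }

  verdict <- ifelse(is.na(category), "retained", "contaminant")
  stage_of <- c(prevalence = 1L, reagent_core = 2L, reagent_expanded = 2L,
                negative_only = 2L, lab_seed = 3L, lab_expanded = 3L,
                secondary = 4L, edit_neighbor = 5L)
  calls <- data.frame(
    asv_id = ids, verdict = verdict,
    category = ifelse(is.na(category), "", category),
    flagged_by = vapply(flagged_by, function(x)
      paste(sort(x %||% character(0)), collapse = ","), character(1)),
    parent = ifelse(is.na(parent), "", parent),
    p_prevalence = prev$p,
    stage = ifelse(is.na(category), NA_integer_, stage_of[category]),
    row.names = NULL, stringsAsFactors = FALSE)

  clean <- asv_subset(table, asvs = ids[verdict == "retained"])
  methods_used <- sort(unique(unlist(flagged_by, use.names = FALSE)))
  overlap <- table(vapply(flagged_by[verdict == "contaminant"], function(x)
    paste(sort(x), collapse = "+"), character(1)))
  report <- list(
    n_input = length(ids),
    n_contaminant = sum(verdict == "contaminant"),
    n_retained = sum(verdict == "retained"),
    by_category = as.list(table(calls$category[calls$verdict == "contaminant"])),
    methods_used = methods_used,
    method_overlap = as.list(overlap))
  list(calls = calls, clean_table = clean, report = report)
}

#' Write contaminant calls as TSV
#'
#' @param calls the `calls` data frame from [run_decontamination()].
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
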