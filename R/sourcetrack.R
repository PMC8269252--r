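#' Parameters of the Gibbs source-tracking sampler
#'
#' `alpha1` smooths the fixed taxon distributions of the known sources and
#' `alpha2` the adaptively estimated distribution of the Unknown source
#' (defaults 0.01 and 1). `tau` is the flat Dirichlet pseudo-count on mixing
#' proportions. Sources are pooled by summing replicates per source type and
#' rarefied to `source_depth` (default 8000); sinks are rarefied to
#' `sink_depth` (default 635).
#'
#' @param alpha1,alpha2,tau smoothing pseudo-counts.
#' @param restarts independent chains (default 10).
#' @param burn_in sweeps discarded per chain (default 100).
#' @param draws retained draws per chain (default 25).
#' @param thinning sweeps between retained draws (default 10).
#' @param source_depth,sink_depth rarefaction depths.
#' @param seed integer RNG seed.
#' @return A `sourcetrack_params` list.
#' @export
sourcetrack_params <- function(alpha1 = 0.01, alpha2 = 1, tau = 1,
                               restarts = 10, burn_in = 100, draws = 25,
                               thinning = 10, source_depth = 8000,
                               sink_depth = 635, seed = 1) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, tau = tau, restarts = restarts,
            burn_in = burn_in, draws = draws, thinning = thinning,
            source_depth = source_depth, sink_depth = sink_depth, seed = seed)
  if (any(unlist(p[c("alpha1", "alpha2", "tau")]) <= 0))
    stop("alpha1, alpha2 and tau must be positive")
  if (any(unlist(p[c("restarts", "burn_in", "draws", "thinning",
                     "source_depth", "sink_depth")]) < 1))
    stop("chain and depth parameters must be >= 1")
  structure(p, class = "sourcetrack_params")
}

rarefy_vector <- function(x, depth) {
  reads <- rep.int(seq_along(x), x)
  keep <- sample(reads, depth)
  out <- tabulate(keep, nbins = length(x))
  names(out) <- names(x)
  out
}

# Pool replicate samples per source type (row sums) and rarefy each pooled
# source. `sources_by` names the metadata column holding the source type.
pool_sources <- function(table, sources_by = "sample_type",
                         exclude = c("concrete", "negative_control")) {
  type <- table$metadata[[sources_by]]
  keep <- !type %in% exclude
  pooled <- rowsum(table$counts[keep, , drop = FALSE], type[keep])
  pooled
}

#' Estimate source mixing proportions for sink samples
#'
#' A collapsed Gibbs sampler assigns each sink read to one of the known
#' sources or to an Unknown source: known-source taxon distributions are
#' fixed from the rarefied source table (pseudo-count `alpha1`), while the
#' Unknown source's distribution is learned from its currently assigned
#' reads (pseudo-count `alpha2`). Reported proportions are means over all
#' retained draws of all restarts, with posterior standard deviations.
#'
#' @param sources matrix of pooled source counts (source types x ASVs), or an
#'   [asv_table] whose non-concrete, non-negative samples are pooled by
#'   `sample_type`.
#' @param sinks matrix of sink counts (samples x ASVs), or an [asv_table]
#'   whose concrete samples are used.
#' @param params a [sourcetrack_params()].
#' @return A `source_estimate`: list with `proportions` (sinks x
#'   sources+Unknown), `sd` (same shape) and `skipped` (sink ids below the
#'   rarefaction depth).
#' @export
sourcetrack <- function(sources, sinks, params = sourcetrack_params()) {
  if (inherits(sources, "asv_table")) sources <- pool_sources(sources)
  if (inherits(sinks, "asv_table")) {
    idx <- sinks$metadata$sample_type == "concrete"
    sinks <- sinks$counts[idx, , drop = FALSE]
  }
  if (is.null(dim(sinks))) sinks <- matrix(sinks, nrow = 1,
                                           dimnames = list("sink", names(sinks)))
  if (!nrow(sources)) stop("no sources")
  common <- intersect(colnames(sources), colnames(sinks))
  if (!length(common)) stop("sources and sinks share no ASVs")
  sources <- sources[, common, drop = FALSE]
  sinks <- sinks[, common, drop = FALSE]
  src_names <- rownames(sources)

  with_seed(params$seed, {
    src <- t(vapply(seq_len(nrow(sources)), function(v) {
      tot <- sum(sources[v, ])
      if (tot < params$source_depth) {
        warning("source ", src_names[v], " below source_depth; using all ",
                tot, " reads")
        as.integer(sources[v, ])
      } else rarefy_vector(sources[v, ], params$source_depth)
    }, integer(ncol(sources))))
    rownames(src) <- src_names

    skipped <- character(0)
    est <- matrix(NA_real_, nrow(sinks), nrow(src) + 1,
                  dimnames = list(rownames(sinks), c(src_names, "Unknown")))
    sds <- est
    for (s in seq_len(nrow(sinks))) {
      tot <- sum(sinks[s, ])
      if (tot < params$sink_depth) {
        skipped <- c(skipped, rownames(sinks)[s])
        next
      }
      sink_r <- rarefy_vector(sinks[s, ], params$sink_depth)
      reads <- rep.int(seq_along(sink_r) - 1L, sink_r)
      drawsm <- gibbs_sourcetrack(reads, src, params$alpha1, params$alpha2,
                                  params$tau, params$restarts, params$burn_in,
                                  params$draws, params$thinning)
      est[s, ] <- colMeans(drawsm)
      sds[s, ] <- apply(drawsm, 2, stats::sd)
    }
    structure(list(proportions = est, sd = sds, skipped = skipped,
                   params = params), class = "source_estimate")
  })
}

#' @export
print.source_estimate <- function(x, ...) {
  cat("source_estimate:", nrow(x$proportions), "sink(s) x",
      ncol(x$proportions), "sources (incl. Unknown)\n")
  print(round(x$proportions, 3))
  invisible(x)
}

#' Leave-one-out source validation
#'
#' Each source type in turn is treated as the sink against the remaining
#' sources plus Unknown, exposing cross-attribution between similar sources.
#'
#' @param sources matrix of pooled source counts (source types x ASVs) or an
#'   [asv_table] (pooled by `sample_type`).
#' @param params a [sourcetrack_params()].
#' @return square attribution matrix (rows: held-out sinks; columns: sources
#'   + Unknown); rows sum to 1, the held-out source's own column is NA.
#' @export
leave_one_out <- function(sources, params = sourcetrack_params()) {
  if (inherits(sources, "asv_table")) sources <- pool_sources(sources)
  if (nrow(sources) < 2) stop("leave-one-out needs >= 2 source types")
  nm <- rownames(sources)
  out <- matrix(NA_real_, nrow(sources), nrow(sources) + 1,
                dimnames = list(nm, c(nm, "Unknown")))
  for (v in seq_len(nrow(sources))) {
    p <- params
    p$seed <- derive_seed(params$seed, v)
    res <- sourcetrack(sources[-v, , drop = FALSE],
                       sources[v, , drop = FALSE], p)
    out[v, colnames(res$proportions)] <- res$proportions[1, ]
  }
  out
}

#' Benchmark recovery of known mixing proportions
#'
#' Compares estimated sink proportions against the true mixing weights of a
#' synthetic study and reports per-source and mean absolute error.
#'
#' @param estimate a `source_estimate`.
#' @param truth_weights named numeric vector of true proportions (must cover
#'   the estimate's source columns; names matched, remainder = Unknown).
#' @return list with `per_source` absolute errors (averaged over sinks) and
#'   `mean_absolute_error`.
#' @export
recover_mixtures_benchmark <- function(estimate, truth_weights) {
  props <- estimate$proportions
  props <- props[!rownames(props) %in% estimate$skipped, , drop = FALSE]
  cols <- colnames(props)
  truth <- stats::setNames(numeric(length(cols)), cols)
  truth[names(truth_weights)[names(truth_weights) %in% cols]] <-
    truth_weights[names(truth_weights) %in% cols]
  truth["Unknown"] <- 1 - sum(truth[setdiff(cols, "Unknown")])
  err <- abs(sweep(props, 2, truth))
  list(per_source = colMeans(err), mean_absolute_error = mean(colMeans(err)),
       truth = truth)
}

#' Write a source estimate as TSV
#'
#' One row per sink: proportions for each source and Unknown, then posterior
#' standard deviation columns.
#'
#' @param estimate a `source_estimate`.
#' @param path output path.
#' @export
write_source_estimate <- function(estimate, path) {
  sd_cols <- estimate$sd
  colnames(sd_cols) <- paste0(colnames(sd_cols), "_sd")
  df <- data.frame(sink = rownames(estimate$proportions),
                   estimate$proportions, sd_cols, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
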