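#' Default pipeline configuration
#'
#' A single auditable surface for every stage of the end-to-end workflow:
#' input paths (or in-memory objects), stage toggles, and per-stage parameter
#' blocks. One global seed expands deterministically into per-stage seeds.
#'
#' @param table,metadata,sequences,tree,lab_reference input paths (TSV,
#'   TSV, FASTA, Newick, FASTA) or the corresponding in-memory objects.
#' @param outdir output directory for stage artifacts.
#' @param seed global integer seed.
#' @param stages named logical vector toggling `filter`, `cooccur`,
#'   `decontam`, `diversity`, `indicators`, `sourcetrack`.
#' @param min_len short-ASV length cutoff (nt).
#' @param min_reads low-depth sample cutoff (NULL = 5% of median depth).
#' @param sparcc_permutations,rarefaction_depth,permanova_permutations,
#'   indicator_permutations,interval_permutations stage parameters.
#' @param unifrac_alpha generalized-UniFrac exponent.
#' @param rules a [decontam_rules()] object.
#' @param sourcetrack a [sourcetrack_params()] object (its seed is derived
#'   from the global seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(table = NULL, metadata = NULL, sequences = NULL,
                            tree = NULL, lab_reference = NULL,
                            outdir = tempfile("concretome_run_"), seed = 1,
                            stages = c(filter = TRUE, cooccur = TRUE,
                                       decontam = TRUE, diversity = TRUE,
                                       indicators = TRUE, sourcetrack = TRUE),
                            min_len = 400, min_reads = NULL,
                            sparcc_permutations = 1000,
                            rarefaction_depth = 1000,
                            permanova_permutations = 999,
                            indicator_permutations = 1000,
                            interval_permutations = 1000,
                            unifrac_alpha = 0.5,
                            rules = decontam_rules(),
                            sourcetrack = sourcetrack_params()) {
  structure(list(table = table, metadata = metadata, sequences = sequences,
                 tree = tree, lab_reference = lab_reference, outdir = outdir,
                 seed = seed, stages = stages, min_len = min_len,
                 min_reads = min_reads,
                 sparcc_permutations = sparcc_permutations,
                 rarefaction_depth = rarefaction_depth,
                 permanova_permutations = permanova_permutations,
                 indicator_permutations = indicator_permutations,
                 interval_permutations = interval_permutations,
                 unifrac_alpha = unifrac_alpha, rules = rules,
                 sourcetrack = sourcetrack), class = "pipeline_config")
}

resolve_input <- function(x, reader) {
  if (is.null(x) || !is.character(x) || length(x) != 1) return(x)
  reader(x)
}

#' Run the end-to-end analysis pipeline
#'
#' Stage order mirrors the analysis workflow: table hygiene (length-variant
#' merging, short-ASV filter, low-depth sample removal), co-occurrence
#' networks, decontamination, diversity / ordination / PERMANOVA /
#' replicate-similarity, bioindicator detection, and source tracking. Every
#' stage writes TSV/JSON artifacts into `config$outdir`, and the run is fully
#' deterministic given the global seed. Any stage failure halts with the
#' stage name.
#'
#' @param config a [pipeline_config()].
#' @return list of per-stage results plus a `summary`, invisibly writes
#'   artifacts to `config$outdir`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  on_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- list()
  stages <- config$stages

  table <- if (inherits(config$table, "asv_table")) config$table
           else if (!is.null(config$table))
             read_table(config$table, config$metadata)
  sequences <- resolve_input(config$sequences, read_fasta)
  tree <- resolve_input(config$tree, ape::read.tree)
  lab_reference <- resolve_input(config$lab_reference, read_fasta) %||%
    character(0)
  if (is.null(table) && any(stages)) stop("pipeline requires an input table")

  if (isTRUE(stages["filter"])) {
    out$filter <- on_stage("filter", {
      mv <- merge_length_variants(table, sequences)
      fs <- filter_short_asvs(mv$table, mv$records, config$min_len)
      min_reads <- config$min_reads %||%
        (0.05 * stats::median(rowSums(fs$table$counts)))
      ld <- drop_low_depth_samples(fs$table, min_reads)
      table <- ld$table
      sequences <- mv$records[asv_ids(table)]
      list(merge_map = mv$merge_map, short_dropped = fs$dropped,
           low_depth_dropped = ld$dropped)
    })
    write_table(table, file.path(config$outdir, "filtered_table.tsv"),
                file.path(config$outdir, "filtered_metadata.tsv"))
  }

  networks <- NULL
  if (isTRUE(stages["cooccur"])) {
    out$networks <- on_stage("cooccur", {
      networks <- list(
        sparcc = sparcc(table, permutations = config$sparcc_permutations,
                        seed = derive_seed(config$seed, 1)),
        rho = proportionality_rho(table))
      write_network(networks$sparcc, file.path(config$outdir, "sparcc_edges.tsv"))
      write_network(networks$rho, file.path(config$outdir, "rho_edges.tsv"))
      networks
    })
    networks <- out$networks
  }

  decontam <- NULL
  if (isTRUE(stages["decontam"])) {
    out$decontam <- on_stage("decontam", {
      run_decontamination(table, sequences, networks, lab_reference,
                          config$rules, seed = derive_seed(config$seed, 2))
    })
    decontam <- out$decontam
    write_calls(decontam$calls, file.path(config$outdir, "contaminant_calls.tsv"))
    jsonlite::write_json(decontam$report,
                         file.path(config$outdir, "decontam_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  work <- if (!is.null(decontam)) decontam$clean_table else table

  if (isTRUE(stages["diversity"])) {
    out$diversity <- on_stage("diversity", {
      if (is.null(tree)) stop("diversity stage requires a Newick tree")
      conc <- asv_subset(work, samples =
        sample_ids(work)[work$metadata$sample_type == "concrete"])
      conc <- asv_subset(conc,
        asvs = asv_ids(conc)[colSums(conc$counts) > 0])
      rt <- rarefy(conc, config$rarefaction_depth,
                   seed = derive_seed(config$seed, 3))
      alpha <- data.frame(
        sample_id = sample_ids(rt),
        shannon = shannon(rt),
        faith_pd = faith_pd(rt, tree),
        months = rt$metadata$months,
        temperature = rt$metadata$temperature,
        series = rt$metadata$series)
      utils::write.table(alpha, file.path(config$outdir, "alpha_diversity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      d <- distance_matrix(rt, "generalized_unifrac", tree,
                           alpha = config$unifrac_alpha)
      ord <- pcoa_ordination(d)
      perm_seq <- permanova(d, rt$metadata, c("temperature", "months", "series"),
                            "sequential", config$permanova_permutations,
                            seed = derive_seed(config$seed, 4))
      perm_marg <- permanova(d, rt$metadata, c("temperature", "months", "series"),
                             "marginal", config$permanova_permutations,
                             seed = derive_seed(config$seed, 4))
      disp <- dispersion_test(d, rt$metadata$series,
                              config$permanova_permutations,
                              seed = derive_seed(config$seed, 5))
      repsim <- replicate_similarity_test(
        d, interaction(rt$metadata$series, rt$metadata$months))
      utils::write.table(
        data.frame(sample = labels(d), as.matrix(d), check.names = FALSE),
        file.path(config$outdir, "gunifrac_distance.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(rbind(perm_seq, perm_marg),
        file.path(config$outdir, "permanova.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      list(alpha = alpha, distance = d, pcoa = ord,
           permanova_sequential = perm_seq, permanova_marginal = perm_marg,
           dispersion = disp, replicate_similarity = repsim)
    })
  }

  if (isTRUE(stages["indicators"])) {
    out$indicators <- on_stage("indicators", {
      conc <- asv_subset(work, samples =
        sample_ids(work)[work$metadata$sample_type == "concrete"])
      iv <- indval_g(conc, conc$metadata$series,
                     permutations = config$indicator_permutations,
                     seed = derive_seed(config$seed, 6))
      lg <- presence_logistic(conc)
      intervals <- interval_differential(
        conc, permutations = config$interval_permutations,
        seed = derive_seed(config$seed, 8))
      utils::write.table(iv, file.path(config$outdir, "indval.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(intervals, file.path(config$outdir, "intervals.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(indval = iv, logistic = lg, intervals = intervals)
    })
  }

  if (isTRUE(stages["sourcetrack"])) {
    out$sourcetrack <- on_stage("sourcetrack", {
      stp <- config$sourcetrack
      stp$seed <- derive_seed(config$seed, 9)
      conc <- work$metadata$sample_type == "concrete"
      first_last <- work$metadata$months %in%
        range(work$metadata$months[conc])
      sinks <- work$counts[conc & first_last, , drop = FALSE]
      est <- sourcetrack(work, sinks, stp)
      write_source_estimate(est, file.path(config$outdir, "source_mixing.tsv"))
      est
    })
  }

  out$summary <- list(
    n_samples = nrow(table$counts), n_asvs = ncol(table$counts),
    n_contaminants = if (!is.null(decontam)) decontam$report$n_contaminant,
    stages_run = names(stages)[stages])
  jsonlite::write_json(out$summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
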