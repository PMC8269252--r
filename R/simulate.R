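#' Configuration for a synthetic longitudinal concrete study
#'
#' Defines the study design the generator emulates: two series of concrete
#' cylinders (one prone to the alkali-silica reaction, one mitigated) sampled
#' at 15 time points in triplicate, plus triplicate libraries of each sequenced
#' precursor material (gravel, sand, cement powder, fly ash) and triplicate
#' negative-control extractions. Mixing water contributes to the community but
#' is never sequenced, so its share is unobservable and counts toward the
#' "unknown" source downstream.
#'
#' @param n_timepoints,n_series,n_replicates concrete design dimensions
#'   (defaults 15 x 2 x 3 = 90 samples).
#' @param n_negatives number of negative-control libraries (default 3).
#' @param n_precursor_replicates replicates per sequenced precursor material
#'   (default 3; materials are gravel, sand, cement, fly_ash).
#' @param n_true_asvs number of genuine community ASVs.
#' @param n_reagent_contaminants,n_lab_contaminants,n_edit_variants planted
#'   contaminant counts; edit variants differ from a parent contaminant by
#'   exactly one substitution.
#' @param source_weights named list (one vector per series) of mixing weights
#'   over gravel, sand, cement, fly_ash, water, unknown; each sums to 1.
#' @param diversity_decay_rate per-month proportional loss of expected
#'   richness (default 0.03, erasing roughly two thirds of taxa over the
#'   21-month series).
#' @param seasonal_amplitude dimensionless richness gain per 10 degrees C of
#'   temperature anomaly (default 0.1).
#' @param library_size_log_mean,library_size_log_sd log-normal library-size
#'   parameters (defaults give a mean depth near 50,000 reads).
#' @param contaminant_load_fraction expected contaminant share of a concrete
#'   library (default 0.85, the regime where only ~15% of reads are genuine).
#' @param negative_only_fraction fraction of reagent contaminants confined to
#'   negative controls (default 0.2).
#' @param sequence_length ASV sequence length in nt (default 420).
#' @param n_indicator_taxa true taxa whose presence probability in the
#'   reactive series rises with months (default 5).
#' @param n_seasonal_taxa true taxa with a planted seasonal abundance cycle
#'   (default 5).
#' @param seed integer RNG seed (required at generation time).
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(n_timepoints = 15, n_series = 2, n_replicates = 3,
                              n_negatives = 3, n_precursor_replicates = 3,
                              n_true_asvs = 150, n_reagent_contaminants = 30,
                              n_lab_contaminants = 20, n_edit_variants = 10,
                              source_weights = NULL,
                              diversity_decay_rate = 0.03,
                              seasonal_amplitude = 0.1,
                              library_size_log_mean = log(5e4),
                              library_size_log_sd = 0.3,
                              contaminant_load_fraction = 0.85,
                              negative_only_fraction = 0.2,
                              sequence_length = 420,
                              n_indicator_taxa = 5, n_seasonal_taxa = 5,
                              seed = NULL) {
  if (is.null(source_weights)) {
    source_weights <- list(
      reactive  = c(gravel = 0.32, sand = 0.05, cement = 0.14, fly_ash = 0.07,
                    water = 0.07, unknown = 0.35),
      mitigated = c(gravel = 0.25, sand = 0.05, cement = 0.20, fly_ash = 0.12,
                    water = 0.07, unknown = 0.31))
  }
  cfg <- list(n_timepoints = n_timepoints, n_series = n_series,
              n_replicates = n_replicates, n_negatives = n_negatives,
              n_precursor_replicates = n_precursor_replicates,
              n_true_asvs = n_true_asvs,
              n_reagent_contaminants = n_reagent_contaminants,
              n_lab_contaminants = n_lab_contaminants,
              n_edit_variants = n_edit_variants,
              source_weights = source_weights,
              diversity_decay_rate = diversity_decay_rate,
              seasonal_amplitude = seasonal_amplitude,
              library_size_log_mean = library_size_log_mean,
              library_size_log_sd = library_size_log_sd,
              contaminant_load_fraction = contaminant_load_fraction,
              negative_only_fraction = negative_only_fraction,
              sequence_length = sequence_length,
              n_indicator_taxa = n_indicator_taxa,
              n_seasonal_taxa = n_seasonal_taxa, seed = seed)
  counts <- cfg[c("n_timepoints", "n_series", "n_replicates", "n_negatives",
                  "n_precursor_replicates", "n_true_asvs",
                  "n_reagent_contaminants", "n_lab_contaminants")]
  if (any(unlist(counts) < 1)) stop("all design counts must be >= 1")
  if (n_edit_variants < 0) stop("n_edit_variants must be >= 0")
  for (w in source_weights) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stop("source_weights must be non-negative and sum to 1")
  }
  if (contaminant_load_fraction < 0 || contaminant_load_fraction >= 1)
    stop("contaminant_load_fraction must be in [0, 1)")
  if (n_reagent_contaminants + n_lab_contaminants > n_true_asvs)
    stop("contaminant counts exceed n_true_asvs; truth labels would be ill-posed")
  class(cfg) <- "simulation_config"
  cfg
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

substitute_base <- function(seq, n_sub) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample(length(s), n_sub)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  stats::setNames(g / sum(g), names(alpha))
}

# Day-of-year and sinusoidal temperature for a given months-since-pour vector.
# Pour assumed at day-of-year 121 (early May); annual temperature cycle peaks
# in late July (day ~205).
season_covariates <- function(months, temp_mean = 13, temp_amp = 12,
                              temp_noise_sd = 1) {
  doy <- (121 + months * 365.25 / 12) %% 365.25
  temp <- temp_mean + temp_amp * cos(2 * pi * (doy - 205) / 365.25) +
    stats::rnorm(length(months), 0, temp_noise_sd)
  list(day_of_year = doy, temperature = temp)
}

#' Generate a synthetic study with complete ground truth
#'
#' Draws a full study the analysis stages can be validated against: precursor
#' sources with partially disjoint Dirichlet base profiles, concrete samples as
#' Dirichlet-multinomial draws from the source-weighted mixture, richness that
#' declines with months and rises with temperature, reagent contaminants
#' present in every negative control (a configurable subset found nowhere
#' else), lab contaminants sharing a log-normal batch factor (half of them
#' copied at >99% identity from the lab reference strains), and single
#' substitution edit variants of contaminants. The returned truth labels every
#' ASV and records mixture weights, indicator taxa and seasonal parameters.
#'
#' @param config a [simulation_config()] with a non-NULL seed.
#' @return list with `table` ([asv_table]), `sequences` (named character),
#'   `tree` (`phylo`), `lab_reference` (named character), and `truth`.
#' @export
generate_study <- function(config = simulation_config(seed = 1)) {
  if (is.null(config$seed)) stop("config$seed is required")
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  n_true <- cfg$n_true_asvs
  n_rea <- cfg$n_reagent_contaminants
  n_lab <- cfg$n_lab_contaminants
  n_var <- cfg$n_edit_variants
  true_ids <- sprintf("ASV_T%03d", seq_len(n_true))
  rea_ids <- sprintf("ASV_R%03d", seq_len(n_rea))
  lab_ids <- sprintf("ASV_L%03d", seq_len(n_lab))
  var_ids <- if (n_var) sprintf("ASV_V%03d", seq_len(n_var)) else character(0)

  sources <- c("gravel", "sand", "cement", "fly_ash", "water", "unknown")
  sequenced_sources <- c("gravel", "sand", "cement", "fly_ash")

  # --- source base profiles over partially disjoint subsets of true taxa ----
  home <- sample(sources, n_true, replace = TRUE)
  base_profiles <- sapply(sources, function(s) {
    support <- home == s
    # each source also borrows ~15% of foreign taxa at low weight
    borrow <- !support & stats::runif(n_true) < 0.15
    alpha <- numeric(n_true)
    alpha[support] <- 0.8
    alpha[borrow] <- 0.1
    if (!any(alpha > 0)) alpha[sample(n_true, 3)] <- 0.8
    p <- numeric(n_true)
    idx <- alpha > 0
    p[idx] <- rdirichlet1(alpha[idx])
    p
  })
  rownames(base_profiles) <- true_ids

  # --- contaminant profiles ------------------------------------------------
  rea_profile <- rdirichlet1(rep(0.8, n_rea))
  names(rea_profile) <- rea_ids
  n_negonly <- round(cfg$negative_only_fraction * n_rea)
  negonly_ids <- if (n_negonly) rea_ids[seq_len(n_negonly)] else character(0)
  lab_profile <- rdirichlet1(rep(0.8, n_lab))
  names(lab_profile) <- lab_ids

  # edit variants: parent among contaminants, small relative load
  var_parent <- if (n_var)
    sample(c(rea_ids, lab_ids), n_var, replace = n_var > n_rea + n_lab)
  else character(0)
  names(var_parent) <- var_ids

  # --- sequences -----------------------------------------------------------
  L <- cfg$sequence_length
  seqs <- stats::setNames(random_dna(n_true + n_rea, L), c(true_ids, rea_ids))
  n_strains <- max(5, ceiling(n_lab / 4))
  lab_reference <- stats::setNames(random_dna(n_strains, L),
                                   sprintf("lab_strain_%02d", seq_len(n_strains)))
  # half the lab contaminants are near-identical copies of reference strains
  n_seeded <- ceiling(n_lab / 2)
  lab_seeded_ids <- lab_ids[seq_len(n_seeded)]
  for (i in seq_len(n_lab)) {
    if (i <= n_seeded) {
      ref <- lab_reference[[sample(n_strains, 1)]]
      seqs[lab_ids[i]] <- substitute_base(ref, sample(0:2, 1))
    } else {
      seqs[lab_ids[i]] <- random_dna(1, L)
    }
  }
  for (v in var_ids) seqs[v] <- substitute_base(seqs[[var_parent[v]]], 1)

  # --- design grid ---------------------------------------------------------
  months_grid <- seq(0, 21, length.out = cfg$n_timepoints)
  series_names <- c("reactive", "mitigated")[seq_len(cfg$n_series)]
  meta <- list(); rows <- list()
  all_ids <- c(true_ids, rea_ids, lab_ids, var_ids)
  n_asv <- length(all_ids)

  # persistence order: taxa drop out in a fixed order as richness declines
  persistence <- stats::setNames(sample(n_true), true_ids)

  # planted temporal structure
  indicator_ids <- sample(true_ids, min(cfg$n_indicator_taxa, n_true))
  seasonal_ids <- sample(setdiff(true_ids, indicator_ids),
                         min(cfg$n_seasonal_taxa, n_true))
  seasonal_peak <- stats::setNames(
    sample(seq_len(365), length(seasonal_ids), replace = TRUE), seasonal_ids)
  indicator_slope <- 0.35   # logistic slope per month for reactive presence
  indicator_mid <- 10       # months at which presence probability is 0.5

  # Contaminant mixture for one library. Shared log-normal batch factors make
  # each contaminant block strongly mutually correlated across samples.
  # Negative controls see only the reagent block (plus its edit variants),
  # including the negative-only reagent ASVs; real samples see both blocks but
  # never the negative-only subset.
  draw_contaminant_mix <- function(negative = FALSE) {
    rea_batch <- stats::rlnorm(1, 0, 0.8)
    lab_batch <- stats::rlnorm(1, 0, 0.8)
    rea_w <- rea_profile
    if (!negative) rea_w[negonly_ids] <- 0
    w <- rea_w * rea_batch
    if (!negative) w <- c(w, lab_profile * lab_batch)
    for (v in var_ids) {
      pw <- w[var_parent[v]]
      if (!is.na(pw) && pw > 0) w[v] <- 0.05 * pw
    }
    w / sum(w)
  }

  add_sample <- function(id, type, series, months, temperature, replicate,
                         true_mix, contam_share) {
    negative <- type == "negative_control"
    p <- numeric(n_asv); names(p) <- all_ids
    if (!is.null(true_mix) && sum(true_mix) > 0) {
      over <- rdirichlet1(true_mix[true_mix > 0] * 50)  # Dirichlet overdispersion
      p[names(over)] <- over * (1 - contam_share)
    } else contam_share <- 1
    if (contam_share > 0) {
      cm <- draw_contaminant_mix(negative)
      p[names(cm)] <- p[names(cm)] + cm * contam_share
    }
    size <- round(stats::rlnorm(1, cfg$library_size_log_mean,
                                cfg$library_size_log_sd))
    if (negative) {
      # every reagent contaminant observed in every negative library, while
      # keeping the column sum equal to the drawn library size
      counts <- stats::rmultinom(1, size - length(rea_ids), p)[, 1]
      counts[rea_ids] <- counts[rea_ids] + 1L
    } else {
      counts <- stats::rmultinom(1, size, p)[, 1]
    }
    rows[[id]] <<- counts
    meta[[id]] <<- data.frame(sample_id = id, sample_type = type,
                              series = series, months = months,
                              temperature = temperature, replicate = replicate,
                              stringsAsFactors = FALSE)
  }

  # --- concrete samples ----------------------------------------------------
  for (s in series_names) {
    w <- cfg$source_weights[[s]]
    for (ti in seq_along(months_grid)) {
      m <- months_grid[ti]
      cov <- season_covariates(m)
      for (r in seq_len(cfg$n_replicates)) {
        temp <- cov$temperature + stats::rnorm(1, 0, 0.3)
        mix <- as.vector(base_profiles %*% w[sources])
        names(mix) <- true_ids
        # richness declines with months, rises with temperature anomaly
        frac <- 1 - cfg$diversity_decay_rate * m +
          cfg$seasonal_amplitude * (temp - 13) / 10
        frac <- min(1, max(0.15, frac))
        active <- persistence <= max(2, round(frac * n_true))
        mix[!active] <- 0
        # indicator taxa: presence probability in the reactive series rises
        # with months (logistic); near-absent in the mitigated series
        for (a in indicator_ids) {
          pr <- if (s == "reactive")
            stats::plogis(indicator_slope * (m - indicator_mid)) else 0.03
          mix[a] <- if (stats::runif(1) < pr) max(mix[a], 0.004) else 0
        }
        for (a in seasonal_ids) {
          doy <- cov$day_of_year
          season_f <- exp(0.9 * cos(2 * pi * (doy - seasonal_peak[a]) / 365.25))
          mix[a] <- mix[a] * season_f
        }
        if (sum(mix) > 0) mix <- mix / sum(mix)
        id <- sprintf("C_%s_t%02d_r%d", substr(s, 1, 3), ti, r)
        add_sample(id, "concrete", s, m, temp, sprintf("t%02d_r%d", ti, r),
                   mix, cfg$contaminant_load_fraction)
      }
    }
  }

  # --- precursor samples ---------------------------------------------------
  cov0 <- season_covariates(0)
  for (src in sequenced_sources) {
    for (r in seq_len(cfg$n_precursor_replicates)) {
      mix <- base_profiles[, src]
      names(mix) <- true_ids
      id <- sprintf("P_%s_r%d", src, r)
      add_sample(id, src, "none", 0, cov0$temperature, sprintf("r%d", r),
                 mix, min(0.3, cfg$contaminant_load_fraction))
    }
  }

  # --- negative controls ---------------------------------------------------
  for (r in seq_len(cfg$n_negatives)) {
    id <- sprintf("NEG_r%d", r)
    add_sample(id, "negative_control", "none", 0, cov0$temperature,
               sprintf("r%d", r), NULL, 1)
  }

  counts <- do.call(rbind, rows)
  metadata <- do.call(rbind, meta)
  # drop ASVs never observed anywhere (truth kept only for observed ASVs)
  observed <- colnames(counts)[colSums(counts) > 0]
  counts <- counts[, observed, drop = FALSE]
  table <- asv_table(counts, metadata)

  labels <- stats::setNames(rep("true_community", n_asv), all_ids)
  labels[rea_ids] <- "reagent_contaminant"
  labels[lab_ids] <- "lab_contaminant"
  labels[var_ids] <- "edit_variant"
  labels <- labels[observed]

  # observable mixture truth: water is unsequenced, so it joins "unknown"
  mixing <- lapply(cfg$source_weights, function(w) {
    obs <- w[sequenced_sources]
    c(obs, Unknown = unname(w["water"] + w["unknown"]))
  })

  truth <- list(
    labels = labels,
    edit_parent = var_parent[intersect(var_ids, observed)],
    negative_only = intersect(negonly_ids, observed),
    lab_seeded = intersect(lab_seeded_ids, observed),
    mixing = mixing,
    indicator_taxa = intersect(indicator_ids, observed),
    indicator_params = list(slope = indicator_slope, midpoint = indicator_mid),
    seasonal_taxa = intersect(seasonal_ids, observed),
    seasonal_peak = seasonal_peak[intersect(seasonal_ids, observed)],
    diversity_decay_rate = cfg$diversity_decay_rate)

  tree <- generate_tree(length(observed), seed = derive_seed(cfg$seed, 7),
                        labels = observed)

  list(table = table, sequences = seqs[observed], tree = tree,
       lab_reference = lab_reference, truth = truth)
}

#' Generate a random rooted phylogeny over ASV leaves
#'
#' Random binary topology with exponential branch lengths; a stand-in for a
#' reference-placement tree, sufficient for Faith's PD and the UniFrac family.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed integer RNG seed.
#' @param labels optional leaf names (default `ASV_1..n`).
#' @return An [ape::rtree()]-style `phylo` object, rooted, with branch lengths.
#' @export
generate_tree <- function(n_leaves, seed, labels = NULL) {
  if (n_leaves < 2) stop("n_leaves must be >= 2")
  with_seed(seed, {
    tr <- ape::rtree(n_leaves, rooted = TRUE, br = function(n) stats::rexp(n, 10))
    tr$tip.label <- labels %||% sprintf("ASV_%d", seq_len(n_leaves))
    tr
  })
}

#' Write all artifacts of a synthetic study to a directory
#'
#' Emits the count table (TSV, `#ASV_ID` header), metadata (`#SampleID`),
#' ASV and lab-reference FASTA files, the Newick tree, and the ground truth
#' as JSON.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(study$table, file.path(dir, "table.tsv"),
              file.path(dir, "metadata.tsv"))
  write_fasta(study$sequences, file.path(dir, "asv_sequences.fasta"))
  write_fasta(study$lab_reference, file.path(dir, "lab_reference.fasta"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  truth <- study$truth
  truth$labels <- as.list(truth$labels)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
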