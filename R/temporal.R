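#' Group-equalized indicator value analysis (IndVal.g)
#'
#' For each taxon and each combination of up to `max_order` groups, the
#' statistic is sqrt(A * B): A (specificity) is the sum of per-group mean
#' abundances inside the combination divided by the sum across all groups —
#' the group-size-equalized form, so unbalanced designs do not bias A — and B
#' (sensitivity) is the fraction of combination samples in which the taxon
#' occurs. The full set of all groups is not a valid combination. Significance
#' is by permutation of group labels, using each taxon's best combination;
#' Benjamini-Hochberg adjusted p-values are reported alongside raw ones.
#'
#' @param counts samples x taxa matrix (or [asv_table]) already agglomerated
#'   to the taxon level of interest.
#' @param groups group labels over samples.
#' @param max_order largest combination size (default 1).
#' @param permutations label permutations (default 1000).
#' @param min_obs,min_samples taxa must have strictly more than `min_obs`
#'   total observations in strictly more than `min_samples` samples.
#' @param seed integer RNG seed.
#' @return data frame: taxon, combination, A, B, stat, p, p_adj.
#' @export
indval_g <- function(counts, groups, max_order = 1, permutations = 1000,
                     min_obs = 5, min_samples = 5, seed = 1) {
  if (inherits(counts, "asv_table")) counts <- counts$counts
  groups <- as.factor(groups)
  K <- nlevels(groups)
  if (K < 2) stop("need >= 2 groups")
  if (max_order > K) stop("max_order exceeds the number of groups")
  keep <- colSums(counts) > min_obs & colSums(counts > 0) > min_samples
  counts <- counts[, keep, drop = FALSE]
  if (!ncol(counts)) return(data.frame())

  combos <- list()
  for (k in seq_len(max_order)) {
    cc <- utils::combn(levels(groups), k, simplify = FALSE)
    combos <- c(combos, Filter(function(x) length(x) < K, cc))
  }
  combo_names <- vapply(combos, paste, character(1), collapse = "+")

  eval_all <- function(g) {
    gsize <- as.vector(table(g))
    gmeans <- rowsum(counts, g) / gsize           # K x taxa
    gpres <- rowsum((counts > 0) + 0, g)
    total_mean <- colSums(gmeans)
    A <- do.call(rbind, lapply(combos, function(cb)
      colSums(gmeans[cb, , drop = FALSE]) / total_mean))
    B <- do.call(rbind, lapply(combos, function(cb)
      colSums(gpres[cb, , drop = FALSE]) /
        sum(gsize[match(cb, levels(groups))])))
    sqrt(A * B)  # combos x taxa
  }

  with_seed(seed, {
    obs <- eval_all(groups)
    best_idx <- apply(obs, 2, which.max)
    best_stat <- obs[cbind(best_idx, seq_along(best_idx))]
    exceed <- numeric(length(best_stat))
    for (b in seq_len(permutations)) {
      perm <- eval_all(sample(groups))
      exceed <- exceed + (apply(perm, 2, max) >= best_stat)
    }
    p <- perm_p(exceed, permutations)
    gmeans <- rowsum(counts, groups) / as.vector(table(groups))
    A_best <- vapply(seq_along(best_idx), function(j) {
      cb <- combos[[best_idx[j]]]
      sum(gmeans[cb, j]) / sum(gmeans[, j])
    }, numeric(1))
    B_best <- vapply(seq_along(best_idx), function(j) {
      cb <- combos[[best_idx[j]]]
      idx <- groups %in% cb
      mean(counts[idx, j] > 0)
    }, numeric(1))
    data.frame(taxon = colnames(counts),
               combination = combo_names[best_idx],
               A = A_best, B = B_best, stat = best_stat, p = p,
               p_adj = stats::p.adjust(p, "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Presence/absence logistic regression with a series-by-time interaction
#'
#' Fits presence ~ series * scale(months) per taxon and reports the
#' interaction log-odds with its two-sided Wald p-value. Non-convergence or
#' separation is reported per taxon, not fatal.
#'
#' @param table an [asv_table]; only samples of the two series are used.
#' @param series,months covariates (default from metadata columns).
#' @param min_samples taxa must be present in at least this many samples.
#' @return data frame: taxon, interaction, se, p, converged.
#' @export
presence_logistic <- function(table, series = NULL, months = NULL,
                              min_samples = 5) {
  counts <- table$counts
  series <- series %||% table$metadata$series
  months <- months %||% table$metadata$months
  use <- series %in% setdiff(unique(series), "none")
  counts <- counts[use, , drop = FALSE]
  series <- factor(series[use])
  if (nlevels(series) < 2) stop("both series must be present")
  sm <- as.numeric(scale(months[use]))
  keep <- colSums(counts > 0) >= min_samples
  counts <- counts[, keep, drop = FALSE]
  rows <- lapply(colnames(counts), function(a) {
    y <- as.integer(counts[, a] > 0)
    if (length(unique(y)) < 2)
      return(data.frame(taxon = a, interaction = NA_real_, se = NA_real_,
                        p = NA_real_, converged = FALSE))
    fit <- suppressWarnings(stats::glm(y ~ series * sm, family = stats::binomial()))
    cf <- summary(fit)$coefficients
    ix <- grep(":", rownames(cf))
    conv <- fit$converged && all(abs(cf[, "Estimate"]) < 20)
    data.frame(taxon = a, interaction = cf[ix, "Estimate"],
               se = cf[ix, "Std. Error"], p = cf[ix, "Pr(>|z|)"],
               converged = conv, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Time intervals of differential abundance between two groups
#'
#' Per taxon, relative abundances are fitted per group with a least-squares
#' B-spline over months; the fitted difference curve, evaluated at the
#' observed time points, is segmented into maximal runs of constant sign
#' (candidate intervals) scored by the summed |difference| over the run. The
#' null permutes group labels within time points and records the maximal
#' interval area; p-values are Laplace-corrected exceedance probabilities.
#'
#' @param table an [asv_table] restricted to the two groups.
#' @param time numeric time (months) per sample.
#' @param group two-level factor per sample.
#' @param spline_df B-spline degrees of freedom (default 4).
#' @param permutations within-time label permutations (default 1000).
#' @param seed integer RNG seed.
#' @param min_prevalence taxa observed in fewer samples are skipped.
#' @return data frame: taxon, t_start, t_end, area, p, reaches_end.
#' @export
interval_differential <- function(table, time = NULL, group = NULL,
                                  spline_df = 4, permutations = 1000,
                                  seed = 1, min_prevalence = 5) {
  counts <- if (inherits(table, "asv_table")) table$counts else table
  meta <- if (inherits(table, "asv_table")) table$metadata else NULL
  time <- time %||% meta$months
  group <- as.factor(group %||% meta$series)
  if (nlevels(droplevels(group)) != 2) stop("exactly two groups required")
  tpts <- sort(unique(time))
  if (length(tpts) < spline_df + 1)
    stop("fewer distinct time points than spline_df + 1")
  rel <- counts / rowSums(counts)
  keep <- colSums(counts > 0) >= min_prevalence
  rel <- rel[, keep, drop = FALSE]
  basis <- splines::bs(time, df = spline_df, intercept = TRUE)
  basis_at <- splines::bs(tpts, knots = attr(basis, "knots"),
                          degree = attr(basis, "degree"), intercept = TRUE,
                          Boundary.knots = attr(basis, "Boundary.knots"))
  g1 <- group == levels(droplevels(group))[1]

  fit_diff <- function(y, gmask) {
    c1 <- stats::lm.fit(basis[gmask, , drop = FALSE], y[gmask])$coefficients
    c2 <- stats::lm.fit(basis[!gmask, , drop = FALSE], y[!gmask])$coefficients
    c1[is.na(c1)] <- 0; c2[is.na(c2)] <- 0
    as.vector(basis_at %*% (c1 - c2))
  }
  runs_of_sign <- function(dd) {
    sgn <- sign(dd)
    r <- rle(sgn)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values != 0
    data.frame(start = starts[keep], end = ends[keep])
  }
  max_area <- function(dd) {
    rr <- runs_of_sign(dd)
    if (!nrow(rr)) return(list(area = 0, start = NA, end = NA))
    areas <- vapply(seq_len(nrow(rr)), function(k)
      sum(abs(dd[rr$start[k]:rr$end[k]])), numeric(1))
    k <- which.max(areas)
    list(area = areas[k], start = rr$start[k], end = rr$end[k])
  }

  with_seed(seed, {
    # within-time-point permutation scheme shared by all taxa
    perm_orders <- lapply(seq_len(permutations), function(b) {
      idx <- seq_along(time)
      for (tp in tpts) {
        at <- which(time == tp)
        idx[at] <- at[sample(length(at))]
      }
      idx
    })
    rows <- lapply(colnames(rel), function(a) {
      y <- rel[, a]
      ob <- max_area(fit_diff(y, g1))
      if (is.na(ob$start))
        return(data.frame(taxon = a, t_start = NA_real_, t_end = NA_real_,
                          area = 0, p = 1, reaches_end = FALSE))
      exceed <- 0
      for (idx in perm_orders) {
        pa <- max_area(fit_diff(y, g1[idx]))$area
        if (pa >= ob$area) exceed <- exceed + 1
      }
      data.frame(taxon = a, t_start = tpts[ob$start], t_end = tpts[ob$end],
                 area = ob$area, p = perm_p(exceed, permutations),
                 reaches_end = ob$end == length(tpts),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Seasonal and long-term trend decomposition of one abundance series
#'
#' Hellinger-transforms the response (square root of relative abundance) and
#' fits ordinary least squares on an intercept, `n_harmonics` annual sin/cos
#' pairs of day-of-year, and a linear months term. Reports the months slope,
#' R-squared, an F-test for the joint seasonal block, and the peak day of
#' year of the fitted seasonal component (grid argmax).
#'
#' @param abundance relative abundances (one taxon across samples).
#' @param day_of_year day of year per sample (1..366).
#' @param months months since start per sample.
#' @param n_harmonics annual harmonics (default 2, matching a cyclic cubic
#'   spline with 4 knots in effective degrees of freedom).
#' @return list: coefficients, months_slope, months_p, r_squared,
#'   seasonal_p, peak_day.
#' @export
seasonal_trend <- function(abundance, day_of_year, months, n_harmonics = 2) {
  n <- length(abundance)
  if (n < 2 * n_harmonics + 2) stop("too few observations")
  y <- sqrt(pmax(abundance, 0))
  H <- do.call(cbind, lapply(seq_len(n_harmonics), function(k)
    cbind(sin(2 * pi * k * day_of_year / 365.25),
          cos(2 * pi * k * day_of_year / 365.25))))
  colnames(H) <- paste0(rep(c("sin", "cos"), n_harmonics),
                        rep(seq_len(n_harmonics), each = 2))
  X <- data.frame(H, months = months)
  if (qr(cbind(1, as.matrix(X)))$rank < ncol(X) + 1)
    stop("collinear design (e.g. all samples share a day of year)")
  full <- stats::lm(y ~ ., data = X)
  reduced <- stats::lm(y ~ months, data = X)
  an <- stats::anova(reduced, full)
  cf <- summary(full)$coefficients
  grid <- seq(1, 366, by = 0.25)
  Hg <- do.call(cbind, lapply(seq_len(n_harmonics), function(k)
    cbind(sin(2 * pi * k * grid / 365.25), cos(2 * pi * k * grid / 365.25))))
  seasonal_curve <- as.vector(Hg %*% stats::coef(full)[colnames(H)])
  list(coefficients = stats::coef(full),
       months_slope = unname(cf["months", "Estimate"]),
       months_se = unname(cf["months", "Std. Error"]),
       months_p = unname(cf["months", "Pr(>|t|)"]),
       r_squared = summary(full)$r.squared,
       seasonal_p = an$`Pr(>F)`[2],
       peak_day = grid[which.max(seasonal_curve)])
}
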