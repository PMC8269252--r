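---
title: "Methods: decontamination and longitudinal analysis of low-biomass 16S data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decontamination and longitudinal analysis of low-biomass 16S data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Concrete is an alkaline, saline, oligotrophic habitat whose microbial
community is seeded by precursor materials and reshaped over years of
weathering. DNA yields from such samples are nanogram-scale, so a sequencing
library can carry more reagent and laboratory DNA than genuine signal.
Worse, amplicon counts are *compositional*: only relative abundances
survive sequencing, so naive correlations between taxa are confounded by the
shared denominator. `concretome` implements an analysis chain built around
these two constraints, and a synthetic-study generator that supplies ground
truth for validating every stage.

This vignette records the models, the tunable parameters, and the design
decisions taken where the methodology left genuine choices open.

# Co-occurrence inference on compositional counts

## SparCC

`sparcc()` estimates correlations of *basis* (absolute) abundances from
log-ratio variances. For fractions $f_i$ the variation matrix is
$t_{ij} = \mathrm{var}\,\log(f_i/f_j)$. Writing $\omega_i$ for the basis
log-variance of taxon $i$ and assuming correlations are sparse (so their sum
is negligible), row sums of $t$ satisfy a linear system
$\sum_j t_{ij} \approx (D-2)\,\omega_i + \sum_j \omega_j$, solved directly;
then $\rho_{ij} = (\omega_i + \omega_j - t_{ij}) / (2\sqrt{\omega_i\omega_j})$,
clipped to $[-1, 1]$. Because a single strongly correlated pair violates the
sparsity assumption most, the most correlated pair above
`exclusion_threshold` (default 0.1) is removed from the system and the solve
repeated, up to `exclusion_rounds` (default 10) times; these two defaults
are the original algorithm's published values. Fraction uncertainty is
handled by averaging `iterations` = 50 posterior Dirichlet(counts + 1) draws.
`iterations = 0` switches to plug-in fractions without smoothing, which makes
algebraic identities exact (proportional counts give $t \equiv 0$,
$\rho \equiv 1$) and is what the unit tests use for oracle comparisons
against a hand-built 4-taxon linear solve.

Significance: each ASV's counts are shuffled across samples independently;
an edge is significant when $|\rho| > 0.35$ and the Laplace-corrected
two-sided exceedance $p = (1+k)/(1+B) < 0.05$ at $B = 1000$ permutations.
**Numerical choice:** the permutation replicates are scored with the
point-estimate fractions $(c+1)/(\text{total}+D)$ and no exclusion rounds,
rather than re-running the full 50-draw estimate per permutation. The null
replicates therefore carry slightly more sampling noise than the observed
statistic, which inflates the null spread and makes the test mildly
conservative — the safe direction for a screen that feeds a contaminant
classifier — at roughly 2% of the cost.

## Proportionality rho

`proportionality_rho()` computes $\rho_{ij} = 1 - \mathrm{var}(a_i - a_j) /
(\mathrm{var}\,a_i + \mathrm{var}\,a_j)$ on the centered-log-ratio transform
of counts + pseudocount (default 1). Significance is by fixed cutoffs only
($\rho > 0.65$ or $\rho < -0.5$), the published FDR-controlling working
point; no permutations are attached. An ASV with zero clr variance has
undefined rho; its pairs are set to 0, left unmasked, and reported by
warning.

## Support metrics

Pairwise chi-square tests (`pairwise_chisq()`) use the standard Monte-Carlo
simulated p-value with both margins fixed; the operation is provided for
completeness but feeds no default decision rule. Edit distances use
unit-cost Levenshtein (via base R's C implementation, verified in tests
against a textbook recursion).

# The contaminant classifier

`run_decontamination()` applies five stages in order; an ASV's *category* is
its first flagging stage, while `flagged_by` accumulates every method that
hit it, so alternative accounting can be reconstructed from the calls table.

1. **Prevalence.** Per ASV, a 2×2 presence table (negative controls vs. real
   samples), tested one-sided for enrichment in negatives — Fisher's exact
   test when any expected cell is below 5, else chi-square without
   continuity correction — flagged at $p \le 0.33$. The lenient threshold
   reflects the high prior odds of contamination in very-low-biomass
   libraries.
2. **Reagent.** Among ASVs observed in negative controls, each metric
   independently selects a *core* of mutually correlated members (net
   positive significant edges > 0; SparCC additionally mean correlation
   > 0.3), then expands through the network (SparCC: > 10 positive edges and
   mean > 0.25; rho: net positive > 0). ASVs found *only* in negatives are
   reagent contaminants by definition.
3. **Lab.** ASVs whose global-alignment identity (1 − Levenshtein /
   max length) to any lab reference strain strictly exceeds 0.99 seed the
   lab set; expansion uses SparCC > 1 positive edge and mean > 0.3, rho > 0
   positive edges.
4. **Secondary screen.** Everything still retained is screened against the
   full master list (SparCC: mean > 0.3 and > 5 positive edges; rho: mean
   > 0.3 and > 1).
5. **Edit propagation.** Retained ASVs within one edit of an identified
   contaminant inherit contaminant status (category `edit_neighbor` with the
   parent recorded), accounting for residual sequencing error.

Design decisions worth recording:

* All rule inequalities are strict, matching their printed ">" forms.
* The "mean correlation" in every rule averages the *raw* scores to the
  whole focus set, not only the significant edges: restricting to masked
  edges (which already exceed 0.35 in absolute value) would make a 0.3 mean
  cutoff nearly vacuous.
* Edit propagation is a single pass over the pre-propagation contaminant
  set; neighbors-of-neighbors are not flagged. A transitive mode exists
  behind a flag. Ties (a variant equidistant from two contaminants) resolve
  to the smallest distance, then the lexicographically smallest parent id —
  deterministic and auditable.
* The union-over-metrics semantics is kept over the two implemented metrics
  (SparCC, rho). A graphical-lasso third metric would slot into the same
  rule table but is out of scope; the classifier's structure — independent
  metrics voting by union — does not depend on it.
* Precedence when an ASV satisfies several categories is narrative-order
  (first stage wins); since `flagged_by` accumulates everything, no
  information is lost to this choice.

# Community metrics

Rarefaction subsamples each library without replacement to a fixed depth
(default 1,000 reads), dropping and reporting under-depth samples rather
than erroring. Shannon diversity defaults to base 2 (bits); the base is a
flag because effect sizes in the literature rarely pin it. Faith's PD is the
sum of branch lengths on the union of root-to-leaf paths of observed taxa —
implemented directly on the `phylo` edge table so that the single-taxon case
(its root path) and the all-taxa case (the whole tree length) hold exactly,
and cross-checked in tests against an established implementation.

The UniFrac family is computed from per-branch descendant mass: for samples
$A, B$ and branch $i$ with length $b_i$ carrying proportions $p_{iA},
p_{iB}$, generalized UniFrac is
$$ d^{(\alpha)} = \frac{\sum_i b_i\,(p_{iA}+p_{iB})^\alpha\,
   \left|\frac{p_{iA}-p_{iB}}{p_{iA}+p_{iB}}\right|}
   {\sum_i b_i\,(p_{iA}+p_{iB})^\alpha}, $$
with branches absent from both samples excluded. At $\alpha = 1$ this
coincides with normalized weighted UniFrac (asserted numerically to 1e-12 in
the tests); $\alpha = 0.5$ (the default) balances emphasis between rare and
abundant lineages. Unweighted UniFrac uses branch presence only. Trees must
be rooted; eigenvalue corrections (Cailliez/Lingoes) are deliberately not
applied in PCoA — negative eigenvalues are reported as-is.

PERMANOVA, dispersion (betadisper-style), and Mantel tests delegate to vegan
(`adonis2`, `betadisper`/`permutest`, `mantel`) behind the package's
interface: free permutation of sample rows, 999 permutations by default,
sequential (Type-I) and marginal modes. The replicate-similarity check
converts distances to similarities ($1-d$) and applies a one-sided Welch
t-test of within-replicate vs. between-sample similarity; when both sets are
exactly constant the test is degenerate and the decision falls back to
comparing the means directly.

# Temporal inference

**IndVal.g.** For a combination $C$ of groups, specificity
$A_C = \sum_{k \in C} m_k / \sum_k m_k$ uses per-group *means* $m_k$, so a
group's sample count does not bias its share (at 10-vs-90 imbalance with
identical per-sample abundance, $A = 0.5$ rather than 0.1/0.9); sensitivity
$B_C$ is the fraction of combination samples with presence; the statistic is
$\sqrt{A_C B_C}$, maximized over combinations up to `max_order` (the full
group set excluded), with label-permutation p-values on the best
combination and Benjamini–Hochberg adjustment reported alongside raw p.
Taxa need strictly more than 5 observations in strictly more than 5 samples.

**Presence logistic.** Per taxon, `glm(presence ~ series * scale(months),
binomial)`; the interaction coefficient and Wald p are reported;
non-convergence and separation (|coefficient| > 20) are reported per taxon,
not fatal.

**Differential-abundance intervals.** The smoothing-spline ANOVA idea —
"which time interval shows a group difference, with permutation
significance" — is implemented as a fully specified construction: per-group
least-squares B-spline fits (df = 4) of relative abundance over months, a
difference curve evaluated at the observed time points, maximal runs of
constant sign as candidate intervals scored by summed |difference|, and a
null that permutes group labels *within* time points and records the maximal
permuted interval area. A fitted cubic rises ahead of a sharp step, so a
detected interval typically begins one inter-knot span before a planted
onset while still covering it; the tests assert coverage, not knot-exact
onset. Relative abundance (per-sample proportions) is the default response
scale, configurable, since the original tooling does not pin it.

**Seasonal + trend decomposition.** Responses are Hellinger-transformed
(square root of relative abundance) and fitted by OLS on an intercept, two
annual sin/cos harmonic pairs of day-of-year, and a linear months term. Two
harmonics match the effective degrees of freedom of a cyclic cubic spline
with four knots while staying closed-form. The seasonal block is tested
jointly by F-test; the peak day of year is the grid argmax of the fitted
seasonal component (¼-day grid).

# Source tracking

`sourcetrack()` is a collapsed Gibbs sampler over per-read source
assignments $z_i \in \{1..V, \text{Unknown}\}$:
$$ P(z_i = v \mid \cdot) \propto \phi_v(t_i) \cdot (n_v^{-i} + \tau), $$
where for known sources $\phi_v(t) = (m_{vt} + \alpha_1) / (m_{v\cdot} +
\alpha_1 T)$ with $m$ fixed from the rarefied source table, and for the
Unknown source $\phi_u(t) = (c_{ut}^{-i} + \alpha_2) / (c_{u\cdot}^{-i} +
\alpha_2 T)$ with $c$ counted from its currently assigned reads. Defaults:
$\alpha_1 = 0.01$, $\alpha_2 = 1$, sources pooled by summation and rarefied
to 8,000 reads, sinks to 635. The chain parameters (flat mixing prior
$\tau = 1$, 10 restarts, 100 burn-in sweeps, 25 draws at thinning 10) are
the original source-tracking tool's conventions, all configurable; only the
smoothing parameters and depths are pinned by the published configuration.
The inner loop is compiled (Rcpp) and draws its randomness from R's RNG, so
a seed makes the whole chain reproducible. Sinks below the rarefaction depth
are skipped and reported. Leave-one-out validation treats each pooled source
in turn as a sink against the remainder.

# The synthetic-study generator

`generate_study()` emulates the study design the analysis assumes: 15 time
points × 2 series (reactive vs. ASR-mitigated) × 3 replicates of concrete,
plus triplicate libraries of the four sequenced precursor materials and
triplicate negative controls — 105 samples. Mixing water is part of every
source-weight vector but is never emitted as samples (it was never
sequenced), so its share is unobservable and folds into the Unknown
component of the source-tracking ground truth.

Mechanisms, each matching what the corresponding analysis stage exploits:

* Source communities are Dirichlet profiles over partially disjoint taxon
  subsets (each source "owns" its home taxa and borrows ~15% of foreign ones
  at low weight). Concrete samples are Dirichlet-multinomial draws
  (concentration 50) from the series' source-weighted mixture — the standard
  overdispersed model for amplicon counts.
* Expected richness declines linearly with months (default 3%/month) and
  rises with temperature anomaly (default 10% per 10 °C); taxa drop out in a
  fixed persistence order so the decline is nested, as in real longitudinal
  thinning. The temperature covariate is an annual sinusoid peaking in late
  July with 1 °C noise.
* Reagent and lab contaminants each share a log-normal batch factor
  (σ = 0.8) that induces the strong mutual positive correlation the
  classifier's network stages rely on. Reagent contaminants appear in every
  negative-control library by construction (library sizes still sum
  exactly); a configurable fraction (default 0.2) is negative-control-only.
  Half of the lab contaminants are copies of lab reference strains at ≤ 2
  substitutions (> 99% identity — the BLAST-seed route), half share only the
  batch factor (the correlation-expansion route).
* Edit variants differ from a parent contaminant by exactly one substitution
  and ride at 5% of the parent's weight.
* Indicator taxa have a presence probability in the reactive series rising
  logistically with months (slope 0.35/month, midpoint month 10) against a
  3% background in the mitigated series; seasonal taxa carry a log-scale
  annual cycle with a known peak day.
* The contaminant load fraction of a concrete library defaults to 0.85 — the
  regime in which only ~15% of reads are genuine, which is what makes this
  class of study hard. The true value in any real study is unknown; this is
  a working point, not a claim.

What the generator does **not** emulate: sequencing error profiles and
chimeras (edit variants stand in for the residual error that matters
downstream), taxonomy, real phylogenetic signal (the tree is a random
rooted topology with exponential branch lengths — sufficient for PD/UniFrac
mechanics but carrying no ecological structure), cross-batch designs, or
spatial structure within a cylinder. Passing tests therefore demonstrate
that each method recovers the structure it is designed for at realistic
noise levels — not that real concrete data will be as clean.

# Problem sizes and determinism

The default synthetic study (105 samples, ~210 ASVs, mean depth 5 × 10⁴) is
sized so a full decontamination run — including SparCC with 1,000
permutations — completes in about a minute on one CPU; the test suite and
the acceptance script use it plus smaller purpose-built fixtures (e.g.
50 taxa × 200 samples for SparCC block recovery, 200 replicates at 199
permutations for PERMANOVA calibration, five seeds for source-tracking
recovery). Every stochastic function takes an explicit seed and restores the
caller's RNG state; the pipeline derives per-stage seeds from one global
seed, and a rerun with the same configuration is byte-identical — asserted
by hashing every artifact.

# Known limitations

* The SparCC permutation null's point-estimate shortcut (above) trades a
  little power for a large constant factor; with very few samples (< ~20)
  the conservatism grows.
* The prevalence test is a plain one-sided 2×2 test; batch-aware prevalence
  testing and the frequency-based method (unreliable at very low biomass)
  are intentionally absent.
* Interval detection reports coverage-style intervals from a df-4 spline;
  sharp features narrower than the inter-knot spacing blur accordingly.
* `merge_length_variants()` defines a length variant as exact substring
  containment, which coincides with 100%-identity-over-overlap clustering
  for same-locus amplicons but will not merge sequences that differ anywhere
  in their overlap. The pipeline merges variants before the length filter,
  following the natural narrative order of table hygiene.
* Source tracking assumes sources are observed at the same locus and depth
  scale as sinks; systematically missing sources load onto Unknown, which is
  the honest but irreducible failure mode of the model class.
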