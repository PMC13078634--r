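---
title: "Methods: cell-state matching and proliferation statistics for tunicate heart growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-state matching and proliferation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ulheart packages the computational procedures used to study post-larval
heart growth in *Ciona robusta*: how a line of undifferentiated
cardiomyocyte progenitors (the "UL") is identified in single-cell
transcriptomes after removing contaminating blood cells, and how its
proliferative behavior is quantified from EdU labeling, drug/CRISPR
perturbation trials, and amplicon sequencing. This vignette explains each
model, its assumptions, the tunable parameters, and the choices made where
the underlying procedures left the design open.

```{r setup, eval = FALSE}
library(ulheart)
```

## Single-cell preprocessing and clustering

The ladder from raw counts to cluster labels is the standard droplet
workflow:

1. **QC** — cells detecting fewer than `min_genes` genes are removed
   (`qc_filter()`; 400 for the dense heart dataset, >200 for the sparser
   circulating-cell reference).
2. **Normalization** — counts are scaled per cell to a target sum of
   10^4 and transformed with ln(1 + x) (`normalize_log()`). After the
   transform, `expm1()` of each cell's values sums back to the target
   exactly (to floating tolerance), which the tests assert.
3. **Covariate regression** — per gene, OLS residuals on per-cell
   technical covariates (`regress_covariates()`). Which covariates count
   as "technical" is an open choice; the pipeline default is the per-cell
   total count, and any per-cell data frame is accepted. Rank-deficient
   covariates are an error rather than a silent drop.
4. **Scaling** — genes are centered and scaled to unit variance, then
   values above `clip_max = 10` are truncated (`scale_clip()`). Two
   decisions are documented and configurable: the SD denominator is the
   population n (`ddof = 0`), and zero-variance genes map to all zeros
   rather than being dropped, so matrix geometry is stable.
5. **HVG selection** — mean-binned dispersion ranking
   (`select_hvg()`): dispersion var/mean on de-logged values, z-scored
   within 20 mean-expression bins. Ties break by gene id so the list is
   deterministic. Default `n_top = 2000`.
6. **PCA** — a truncated Lanczos solver (irlba) on the scaled matrix
   (`run_pca()`); when most of the spectrum is requested (beyond a third
   of the smaller dimension) the dense SVD is used instead, since
   truncated solvers are only advantageous — and only reliable — far from
   full rank. Component signs are fixed by making the largest loading
   positive, so results are reproducible across runs.
7. **Component count** — `choose_n_pcs()` formalizes "read the knee of
   the log variance-ratio curve" as the largest discrete second difference
   of ln(variance ratio): the index where the curve flattens fastest. All
   components before the flattening are kept, bounded to
   `[min_pcs, max_pcs]`, and an explicit override always wins. With fewer
   than four components everything is kept.
8. **Louvain clustering** — a kNN graph (`n_neighbors = 15`, Euclidean
   distance in PC space) with shared-nearest-neighbor Jaccard edge
   weights (pruned below 1/15), partitioned by Louvain
   (`cluster_cells()`). The SNN weighting keeps coherent states together
   at moderate resolutions; plain unweighted kNN graphs fragment even
   clearly separated groups under the modularity objective. The
   main-clustering resolution default is 1.0 (the source procedure states
   none); sub-clustering uses 0.83, the one stated value.
9. **Sub-clustering** — `subcluster()` re-runs Louvain on one cluster's
   cells using the *parent* PCA rows, never recomputing PCA, so the
   sub-structure is resolved in the parent's coordinate system. The tests
   verify this by garbling every other row of the embedding and checking
   the result is unchanged.

A single pipeline seed fans out to per-stage seeds through a documented
hash of the stage name, so any stage can be re-run in isolation with the
same randomness.

## Contaminant-cluster elimination

Dissected hearts carry blood cells. The elimination procedure correlates
cluster centroids between the heart (query) and a circulating-cell
(reference) dataset:

- `cluster_profiles()` computes, per cluster, the mean **log-normalized
  (pre-scaling)** expression over the HVG set — following the wording of
  the procedure being reproduced; scaled-value centroids are possible by
  passing a scaled matrix's values, but the default and tested path is
  log-stage. The HVG set used for matching is the intersection of the two
  datasets' HVG lists.
- `profile_correlation()` computes Pearson r for every cluster pair
  (Spearman by flag). Pearson is the natural reading of an unqualified
  "correlation" on centroids.
- `assign_contaminants()` applies the decision ladder with
  `match_config()`: a query cluster whose best correlation reaches the
  threshold (default 0.5) is a contaminant, unless vetoed; a best
  correlation within `band = 0.01` *below* the threshold is flagged
  `needs_review` (codifying the manual rescue of a 0.494 pairing against
  a 0.5 cutoff); and the **abundance veto** retains query clusters whose
  matching reference cluster is too small to plausibly explain them
  (codifying the case of a reference state at 0.17% abundance matching
  query clusters totalling 12.1% — a 71-fold discrepancy against the
  default 10-fold limit). Manual overrides are applied last and recorded
  in the decision table.

One subtlety: the veto compares a reference cluster's abundance with the
summed abundance of all query clusters whose *best match* it is,
regardless of whether each match clears the current threshold. Summing
only above-threshold matches would make the veto depend on the threshold
in a way that can *grow* the contaminant set as the threshold rises;
under the best-match definition, raising the threshold can only shrink
the contaminant set, which is asserted as a property test.

`calibrate_threshold()` reproduces the threshold-selection procedure:
cluster and profile each reference replicate independently, correlate
across replicates, and pick the largest grid value (default grid 0.10 to
0.90 by 0.05) at which every cluster of each replicate still has a
cross-replicate match in both directions — i.e., all states present in
both replicates are still recognized as shared. The acceptance rule in
the original account is qualitative; this grid rule is one explicit
formalization, and the full curve is returned so a different cut can be
audited.

## Marker genes

`rank_markers()` runs a one-vs-rest two-sided Wilcoxon rank-sum test per
gene per cluster with Benjamini–Hochberg correction within each cluster's
gene list (the underlying procedure names no correction; BH is the
field's default and is configurable by post-processing the returned p
values). Small untied samples use the exact null, larger or tied samples
the normal approximation with continuity correction. `panel_zscores()`
z-scores per-cluster means across *all* clusters (population SD), so
masking a display to one cluster never changes the values.
`top_expressed()` reports per-cluster mean-expression rankings with a
specificity score (mean inside / mean outside; `Inf` for
cluster-exclusive genes) to support the manual curation the original
analysis applied; the curation itself is out of algorithmic scope.

## EdU proliferation and division rate

`proliferation_index()` is the percent of EdU+ nuclei in a compartment.
`edu_count_distribution()` tallies animals by their EdU+ cell count into
0/1/2/3+ bins. `division_rate()` implements the pulse/chase estimator:

rate = (mean chase count / mean pulse count) / (chase_hours / 24),

with animals at zero excluded from both arms, per the estimator's stated
rule. At the standard 36-hour chase the divisor is 1.5 and a value of 1
means one division per day.

The synthetic generator (`generate_edu_dataset()`) labels each of an
animal's progenitor cells independently during the pulse. For the chase
arm the default growth model is **multiplicative label propagation**: the
number of EdU+ nuclei per initially labeled cell is Poisson with mean
rate × t/24, which is exactly the model under which the ratio estimator
above is unbiased (before zero-truncation) for any rate. An additive
clone-growth option (`growth = "linear_plus_one"`, clone size
1 + rate × t/24, nuclei never lost) is provided for sensitivity
analysis; under it the estimator carries a constant offset of 24/t, which
is worth knowing when interpreting rates estimated from real pulse/chase
counts. Zero-exclusion truncation biases the estimator upward when
labeled counts are small; the recovery experiments therefore use
compartments with roughly ten labeled cells per animal (200 cells at 5%
labeling), where the truncation term is negligible. With the sparse
labeling regime of a 30-minute pulse (mostly 0–1 labeled cells) the
estimator is substantially truncation-biased — a limitation of the
estimator itself, not of the implementation.

`normalize_ul_counts()` divides every animal's count by its trial's
control **mean** (the well-defined reading of "normalized to control per
trial"); a single-reference-animal mode exists for exact replication of
the alternative reading.

## The hypothesis-testing ladder

- `shapiro_gate()` / `two_group_test()`: a Shapiro–Wilk gate (on pooled
  within-group-centered residuals, α = 0.05) chooses between a Student t
  test (equal variances) and a Mann–Whitney U test, followed by
  Bonferroni correction `min(1, m·p)`.
- `fisher_exact_2x2()`: two-sided by the point-probability rule (summing
  hypergeometric probabilities no larger than the observed table's), the
  same definition the original analysis' software used. A zero margin
  returns p = 1 with a warning.
- `paired_t()`: t on differences; zero-variance differences are flagged
  degenerate rather than producing a misleading statistic.
- `exceedance_permutation_test()`: the bespoke test. Per trial, the
  exceedance proportion is the fraction of animals at or above the
  trial's control mean + 1 control SD (sample SD, closed inequality —
  both documented choices); the statistic T averages the
  treatment-minus-control difference of these proportions over trials.
  Labels are permuted **within** each trial, recomputing the control
  summary per permutation, preserving trial structure; a pooled
  permutation mode exists for sensitivity analysis. When the total number
  of within-trial arrangements is at most 10^6 the null is enumerated
  exhaustively (per-trial contribution vectors combined by outer sums)
  and the p-value is exact; otherwise Monte-Carlo permutations with the
  add-one rule p = (1 + #{T* ≥ T})/(1 + n_perm), so p is never zero. The
  default alternative is one-sided (the planted claim is directional);
  two-sided compares |T*| against |T|.

## Amplicon indel analysis

Unique-read tables are partitioned by a prevalent naturally occurring
IN/DEL (`classify_natural_indel()`) using either a pre-annotated flag
column or an explicit signature (type, offset, length) matched against
the edit table — making a manual filtering step machine-checkable.
Mutagenesis incidence (`mutagenesis_incidence()`) is the fraction of
remaining reads with at least one edit inside the locus window (default
60 bp around the PAM). Both statistics are multiplicity-weighted by
default with a unique-reads mode (weight 1), since the original counts
are phrased per unique read; the tests compute both.
`deletion_offsets()` summarizes frameshift-deletion start positions
(frameshift = length not divisible by 3) as signed offsets from the
PAM-proximal base, negative upstream — a stated convention, since none
was given.

## What the synthetic data emulate — and what they do not

`generate_sc_pair()` draws per-state × per-gene negative-binomial counts
(independent gamma mean profiles per state, so distinct states correlate
weakly while shared states reuse identical profiles and correlate
strongly). Reference replicates differ only by sampling noise unless a
multiplicative log-normal batch factor is requested. Rare states can be
planted by passing per-state cell counts. The generator does **not**
model ambient RNA, doublets, batch-specific library chemistry, or
continuous differentiation trajectories, so a passing contaminant-recovery
test shows the decision machinery is correct on well-separated states —
not that 0.5 is the right threshold for any particular real dataset; the
replicate-calibration function exists precisely because that threshold
must be re-derived per dataset. Trial counts are rounded truncated
normals with either an additive shift or a planted exceeder fraction;
read sets store annotations (flags and offsets) rather than nucleotide
strings, since every downstream computation consumes annotations.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately small instances: dataset
pairs of roughly 500 query cells × 300 genes across 6 states (20 seeded
replicates), 1000 null replications of 20 trials × 10 animals at 200
permutations each, 10 replicate EdU datasets of 200 animals per rate, and
read sets of 1,500–5,000 unique reads. These sizes keep every stochastic
check well-powered (binomial/Monte-Carlo error comfortably inside each
asserted tolerance) while the whole suite runs in minutes. Floating
tolerances follow the contracts: 1e-6 relative for normalization sums,
1e-8 for orthogonality and centering, 1e-12 for closed-form and
enumeration-oracle agreement.

## Known limitations

- Louvain community detection is seed-sensitive on ambiguous graphs;
  labels are deterministic given the seed but not across seeds.
- The division-rate estimator's zero-exclusion rule makes it upward
  biased under sparse labeling (see above).
- `calibrate_threshold()` assumes the replicates genuinely share all
  states; replicates with disjoint rare states force the threshold down.
- The exact exceedance enumeration grows as a product of per-trial
  binomial coefficients; beyond 10^6 arrangements the Monte-Carlo path is
  used and p-values carry simulation error of order 1/sqrt(n_perm).
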