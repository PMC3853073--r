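---
title: "Multivariate random-forest regression for GWAS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate random-forest regression for GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvrforest)
```

## The problem

Genome-wide association studies increasingly measure quantitative traits
that are high-dimensional by nature — voxel-wise brain-atrophy slopes,
gene-expression panels, shape coordinates.  With `N` unrelated samples
genotyped at `P` biallelic SNPs (additive coding: the genotype is the count
of minor alleles, 0/1/2) and a `Q`-dimensional real-valued trait per
sample, often with `N` far below both `P` and `Q`, single-SNP regression
discards the joint structure of the trait and the joint effects of loci.
`mvrforest` fits an ensemble of multivariate regression trees to such data
and returns three things at once:

* a **SNP ranking** by information-gain importance, for prioritising
  candidate loci;
* an **out-of-bag (OOB) prediction error**, an internally cross-validated
  measure of how predictable the trait is from the genotypes;
* a **genetic proximity matrix**, the fraction of trees in which two
  samples co-occur in a leaf, whose complement is a genetic distance that
  can be compared directly with phenotypic distances.

## The model

Each of `Ntree` trees is grown on a bootstrap multiset of the `N` samples.
At every node `j` holding sample multiset `D(j)`, a fresh random subset of
`Mtry` candidate SNPs is drawn without replacement, and every allowable
binary split of every candidate is scored by the reduction in the node sum
of squares

$$\phi(j) = SS(j) - SS(j)_l - SS(j)_r,$$

where, under the **standard criterion**,

$$SS(j) = \sum_{i \in D(j)} (y_i - \bar y(j))^\top V^{-1}(j)\,
  (y_i - \bar y(j)),$$

with `V(j)` either the identity or a diagonal matrix of per-trait variances
estimated at the node.  Daughters are scored under the parent's `V`, which
keeps `phi(j) >= 0`; after the split is fixed, the daughters re-estimate
their own covariance.  A full `Q x Q` covariance is deliberately not
offered: with `N` in the hundreds and `Q` as large or larger, the estimate
is singular, so the diagonal family is the honest parametrization.

Under the **distance-based criterion**, the same quantity (for identity
`V`) is evaluated from the matrix of squared pairwise phenotype distances,

$$SS(j) = \frac{1}{2 N(j)} \sum_{i \in D(j)} \sum_{l \in D(j)}
  d_E^2(y_i, y_l),$$

with bootstrap duplicates counted with multiplicity — this multiplicity
convention is exactly what makes the two criteria agree on a bootstrap
sample.  Because the `N x N` distance matrix is precomputed once, the
per-split cost no longer involves `Q` at all, which is the point when `Q`
reaches tens of thousands.  A *standardized* Euclidean variant divides
each trait by its whole-sample standard deviation before computing
distances; it corresponds to a diagonal covariance estimated once at the
root, not per node, so it is the distance-side analogue — not an exact
twin — of the standard criterion's diagonal option.  The package verifies
the identity/Euclidean equivalence both numerically (relative tolerance
`1e-10` on random node multisets) and structurally (forests grown from
shared per-tree seeds are identical across criteria).

**Allowable splits.**  With additive coding, a split is an ordinal
threshold: left branch `genotype <= t`, `t` in `{0, 1}`.  When a node has
no heterozygotes the two thresholds induce the same partition and only
`t = 0` is kept.  Ties between equal-gain splits go to the lowest SNP
index, then the lowest threshold, so trees are reproducible.  Growth stops
when a node is smaller than `min_node_size` (5 for univariate, 20 for
multivariate traits — small leaves are meaningless when a leaf must
estimate a `Q`-vector) or when no strictly positive gain exists; trees are
never pruned.

## The map/shuffle/reduce contract

Forests parallelise trivially because trees are independent.  The engine
mirrors a map/reduce design: *map* tasks each hold the full data set and
grow a batch of trees, emitting three keyed streams — per-sample OOB
predictions, per-SNP split gains, and per-tree leaf assignments (the
sparse encoding of co-leaf pairs); the *shuffle* groups values by key; the
*reduce* step aggregates each stream into the OOB error, the importance
table and the proximity matrix.  Every tree's random stream is derived
from `(master_seed, tree_id)` with a splitmix64 generator, and reduction
always proceeds in tree-id order, so the result is bit-identical whatever
`n_workers` is — a property the test suite asserts exactly, and the reason
a failed batch can simply be re-run.

Two conventions here were genuinely open:

* **OOB error for multivariate traits.**  The per-sample error is
  `(1/Q) ||y_i - \hat y_i||^2`, the squared error averaged per trait, so
  univariate and multivariate runs live on comparable scales; the overall
  error averages over samples that were OOB at least once.
* **Proximity counting population.**  By default all `N` samples are
  routed down every tree and co-leaf pairs are counted against `Ntree`
  (the classical convention); an OOB-only mode (pairs counted only in
  trees where both samples are OOB, against the number of such trees) is
  available via `mvrf_config(proximity = "oob")`.  Neither is asserted to
  be the only defensible choice.

## SNP ranking and the gene-rank permutation test

Importance is the sum of `phi(j)` over every split a SNP wins, across all
trees; ties in the resulting ranking receive average ranks.  Stability of
the ranking is monitored by growing the forest in blocks (500 trees in
genome-wide runs) and computing the Jaccard agreement of consecutive
cumulative top-`k` sets ([stability_curve()]); a forest is large enough
when the curve plateaus near 1.

SNPs map to genes when they fall within the gene body extended by 10 kb on
both sides (inclusive boundary; BED intervals are 0-based half-open, SNP
positions 1-based, conversion internal).  A gene's score is the mean rank
of its SNPs, and its significance comes from jointly permuting the rank
vector across all `P` SNPs — one shared permutation stream for all genes,
which is equivalent in distribution per gene and far cheaper than per-gene
streams.  P-values use add-one smoothing, `(1 + hits)/(1 + n_perm)`, so
they are never zero, and the discovery list is controlled by
Benjamini–Hochberg FDR at 10% — the standard reading of "controlling the
false discovery rate" where no specific procedure is named.

## Proximity analyses

Genetic distance is `1 - proximity`.  Classical (Torgerson) scaling
embeds it: double-centre `-D^2/2`, take the top eigenpairs; negative
eigenvalues — expected, since forest distances are not exactly Euclidean —
are truncated to zero and their share of the spectrum recorded on the
result.  Association between genetic and phenotypic distance matrices is
tested with a one-sided Mantel permutation test (upper-triangle Pearson
correlation; rows and columns of the second matrix permuted together),
delegated to `vegan::mantel` and checked in the tests against an
exhaustive enumeration of all `4!` permutations at `N = 4`.

Severity analysis embeds the phenotypic distances in 3 dimensions (2 for
visualisation and clustering, matching how such plots are drawn), cuts a
Ward-linkage dendrogram into four clusters C1–C4 ordered along the
dominant axis (an optional reference marker, e.g. healthy controls, fixes
the orientation), and scores each sample by (a) the Euclidean distance to
the C1 centroid and (b) the scalar projection on the C1-to-C4 axis.  These
are regressed on two mutation burdens: the count of top-1000-ranked SNPs
at which the sample carries any minor allele, and the count of retained
*mutation patterns* — unordered pairs of (SNP, state) items with state 1
or 2 over distinct top-100 SNPs (pairs of items, consistent with roughly
`C(200, 2)` candidates before filtering; higher-order patterns are out of
scope).  A pattern is retained when its overall frequency reaches 0.05 and
it is significantly more frequent in C4 than overall, by a one-sided
proportion z-test at the 5% nominal level with no multiplicity correction
(the analysis is exploratory screening, and only a nominal level is
specified); the frequency gate is computed over all samples.  Retention is
monotone in both the frequency gate and the level, which the tests assert.

## The simulator

`simulation_config()` describes the validation conditions used throughout:
`N = 253`, `P = 1000`, `Q = 100`, five causal SNPs among those with minor
allele frequency at least 0.2, additive effects calibrated so the genetic
component explains about 8% of the phenotypic variance of the affected
traits.  Choices the design left open, fixed once here:

* **Non-causal MAFs** are uniform on 0.1–0.5, the range that survives the
  MAF ≥ 0.1 quality-control filter typical of such cohorts.
* **Noise covariance** defaults to exchangeable with correlation 0.3.
  Real high-dimensional endophenotypes (neighbouring voxels, co-regulated
  transcripts) are substantially correlated; an identity default would
  make the multivariate problem an average of `Q` independent univariate
  ones.  Identity and user-supplied matrices remain available.
* **Effect structure**: each causal SNP affects a random 20% of traits
  with equal magnitude and random sign.
* **Calibration** solves, by a monotone root search, for the scalar `m`
  with `mean_q[ m^2 g_q / (m^2 g_q + sigma_q^2) ] = target` over affected
  traits, where `g_q` is the realized variance of the genetic component —
  for independent SNPs this reduces to the closed-form additive variance
  `sum_c beta_cq^2 2\,\mathrm{MAF}_c(1-\mathrm{MAF}_c)`.  The target is a
  share of *total* variance, so the multiplier grows slightly faster than
  `sqrt(target)`; the defining identity itself is what the tests check.
* An optional **LD mode** (`ld_rho`) thresholds genotypes from two latent
  AR(1) haplotype signals, giving decaying correlation between adjacent
  SNPs.  It is a caricature of linkage disequilibrium — no recombination
  maps, no allele-frequency/LD coupling — and defaults to off.

What passing simulation-based tests shows, and what it does not: the
generator produces independent (or AR-correlated) SNPs, Gaussian noise and
homogeneous samples.  Real cohorts add population structure, genotyping
error, heavy-tailed phenotypes and LD blocks with realistic topology; good
behaviour here demonstrates correctness of the machinery, not performance
guarantees on any particular cohort.

## Numerical choices and degenerate inputs

* Variances in the diagonal parametrization (and in trait
  standardization) are floored at `1e-8`, so constant traits cannot
  produce infinite weights.
* Split gains must be strictly positive to be accepted; exact zero gains
  (identical daughter means) terminate growth rather than split
  arbitrarily.
* Gain comparisons carry a tolerance of `1e-9` times the node sum of
  squares: a challenger split must beat the incumbent by that margin, and
  an accepted split must clear it.  Distinct SNPs can induce the very same
  sample partition (and two formulas for the same quantity differ in their
  last floating-point digits), so without the tolerance the winning split
  would be decided by rounding noise; with it, exact ties always resolve
  to the lowest SNP index and threshold, identically under both split
  criteria.
* Missing genotypes must be imputed before growth; the built-in
  [impute_missing()] uses the per-SNP modal genotype with ties broken
  towards the smaller value.  Model-based imputation is a pre-processing
  concern outside this package's scope.
* The Hardy–Weinberg filter threshold is `5e-7`; QC filters use strict
  inequalities and attribute each removal to the first failing filter in
  the order call rate, HWE, MAF.
* `Mtry` above `P` is clamped with a warning; a forest where no sample
  was ever OOB (tiny `Ntree`) is an error with guidance rather than a
  silent `NaN`.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script run the simulation designs at
the sizes stated above (`N = 253`, `P = 1000`, `Q = 100`, `Ntree = 200`,
`Mtry = 333` for the criterion comparison over 100 data sets; 20 runs at a
0.4 variance-explained target for causal-SNP recovery; 10 data sets for
the calibration check), with smaller configurations for structural and
permutation checks.  `Ntree = 200` with `Mtry = P/3` is the package's
default operating point for data of this size: rankings are stable block
to block and the OOB error has converged well within it.  The genome-wide
settings discussed alongside the stability curve (tens of thousands of
trees, top-5000 Jaccard monitoring) scale the same machinery up without
changing any of its logic.

## Known limitations

* Binary ordinal splits only; no multi-way splits, no classification
  mode, no pruning.
* The covariance family is identity/diagonal; genuinely unstructured
  covariances would need `N >> Q`.
* The distance criterion materialises an `N x N` matrix; at very large
  `N` (tens of thousands) that matrix, not `Q`, becomes the constraint.
* Proximities from small forests are coarse (`1/Ntree` resolution);
  downstream MDS and Mantel analyses inherit that granularity.
* The gene-rank null treats SNP ranks as exchangeable; strong LD between
  SNPs mapped to the same gene makes the test conservative rather than
  anti-conservative, but it is still a null of convenience.
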