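---
title: "Enterosignature discovery by consensus NMF: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enterosignature discovery by consensus NMF: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

An *enterosignature* (ES) is a latent, co-occurring microbial subcommunity
learned from a non-negative abundance matrix. Given a samples-by-features
table `V` — MAG (metagenome-assembled genome) counts for the taxonomic
layer, KEGG Orthology (KO) aggregates for the functional layer — the
package factorises

$$ V \approx W H, \qquad W \ge 0,\; H \ge 0, $$

where `W` (samples × k) carries per-sample signature loadings and `H`
(k × features) carries per-signature feature profiles. The factorisation
minimises the generalised Kullback–Leibler divergence
$D(V\,\|\,WH) = \sum_{ij} V_{ij}\log\frac{V_{ij}}{(WH)_{ij}} - V_{ij} +
(WH)_{ij}$ by the classical multiplicative updates (the Brunet
formulation). The updates guarantee a non-increasing objective, which the
implementation records per iteration and the test-suite audits.

Key modelling assumptions:

* **Additivity.** Community profiles are non-negative mixtures of
  subcommunity profiles; this is what makes factors readable as
  assemblages rather than contrasts.
* **Mixed membership.** A sample expresses several signatures at once;
  discrete "dominant-signature" labels are derived only for descriptive
  composition summaries (argmax of the W row, ties broken to the lowest
  index and flagged).
* **Compositionality.** `V` is total-sum scaled (TSS) before
  factorisation, so library size is removed and rows are proportions.
  Rarefaction is deliberately not offered: TSS achieves the same
  library-size normalisation without discarding reads.

### Scale identifiability

`WH` is invariant to rescaling a factor in `H` and inversely in `W`. The
package fixes the scale by renormalising each row of `H` to sum 1 and
letting `W` absorb the factor scale (the product is unchanged to within
1e-10). Loadings are then comparable across samples, which downstream
"loading" semantics require.

## Rank selection

For each candidate rank (default grid 2–8, 10 runs per rank) the package
computes five quality metrics from the multi-run consensus matrix `C`
(`C[i,j]` = fraction of runs in which samples i and j share a dominant
signature):

* cophenetic correlation of `1 - C` against its average-linkage
  dendrogram;
* mean silhouette width of the consensus clustering cut at k;
* residual sum of squares (minimised);
* dispersion `mean(4 (C - 1/2)^2)`;
* explained variance `1 - rss / sum(V^2)`.

Each metric votes for all ranks within a relative tolerance of its
optimum (10% for taxonomic, 5% for functional matrices); the rank with
the most votes wins, ties going to the larger rank to preserve
ecological resolution. Two choices were genuinely open and are worth
recording:

* **Orientation.** rss is minimised, the other four maximised. For a
  maximised metric with a non-positive optimum (possible for
  silhouette), the relative rule is ill-defined, so acceptability falls
  back to absolute distance `|m - opt| <= tol * |opt|`.
* **Raw versus rescaled metrics.** Tolerances are applied to raw metric
  values, not to per-metric rescalings; raw values are what the voting
  rule quotes.

On clean synthetic data the cophenetic correlation tends to accept the
whole grid and rss/evar plateau above the true rank, so the decisive
votes usually come from silhouette and dispersion — the same qualitative
pattern reported for real gut metagenomes, where no rank wins all five
metrics and ties between adjacent ranks are resolved upward.

### What "convergence" means

A run stops when the relative decrease of the objective over a
10-iteration window falls below `tol` (default 1e-6) or at `max_iter`
(default 2000). In multi-run consensus, a run is *failed* only if its
objective trace is non-finite or increases beyond numerical slack
(1e-10 relative to the initial objective — near an exact factorisation
the divergence underflows to zero and fluctuates at rounding level).
Runs that stop at `max_iter` with a clean trace are retained and counted
separately: above the true rank the updates drift slowly and rarely meet
the window criterion, yet their factors are perfectly usable, and
discarding them would abort the survey.

## Stability validation

`subsample_stability()` refits the NMF on random 80% subsamples (100
iterations by default, 5 best-of inner runs per refit), extracts the top
30 features per factor with the same ranking rule used for reporting,
and matches factors to the full-data reference by Hungarian-optimal
Jaccard similarity. Subsampling is stratified by line and timepoint when
metadata are supplied so no design cell empties. Feature persistence is
the fraction of pooled reference top features recovered (in their
matched factor) in at least 80% of iterations — pooled, not
per-signature, matching how the fraction is usually quoted.

The Hungarian assignment is a direct O(k³) shortest-augmenting-path
implementation; tests verify it against exhaustive permutation for
k ≤ 5.

## Feature ranking within signatures

`specificity(s, j) = H[s,j] / Σ_s' H[s',j]` and
`enrichment = k × specificity`, so an exclusively loaded feature at
k = 8 scores enrichment 8.000 and specificity 1.0. Within each
signature, when the coefficient of variation of (nonzero) enrichment is
below 0.5 the profile is effectively flat and features are ranked by the
z-score of their loading; otherwise by fold-enrichment. The CV is
computed over features with nonzero enrichment because a zero-inflated
CV is undefined at mean 0.

## Loading normalisation and association models

Statistical testing operates on a two-step normalisation of `W`:
TMM scale factors (edgeR's doubly trimmed log-ratios, trim 0.3 on
M-values and 0.05 on A-values, reference = sample whose upper-quartile
loading is closest to the mean upper quartile) remove composition bias
in total loading, then a centred log-ratio transform
(`x → ln x − mean(ln x)` per sample, pseudocount = half the smallest
positive scaled value) maps the compositional loadings to an
unconstrained space whose rows sum to zero. The pseudocount rule is a
sensitivity knob: offsetting by the minimum instead changes little in
the tests here but is not exposed as a default.

Two mixed models are fitted by REML with a random animal intercept and
sum-to-zero factor coding:

1. per signature, `loading ~ timepoint * line + (1 | animal)`;
2. per phenotype × signature,
   `P ~ loading * timepoint * line + (1 | animal)` with all two- and
   three-way interactions retained as a pre-specified plan.

Type-III F tests use Satterthwaite denominator degrees of freedom
(lmerTest). A singular fit (animal variance estimated at zero) is valid
and only flagged; models whose optimiser actually fails are excluded
from inference. p-values are Benjamini–Hochberg adjusted across
signatures within each effect, and marginal-mean contrasts (balanced
factor weights; line difference per timepoint, temporal changes within
line) are adjusted within each signature-by-family group. Cohen's d
between lines is reported per timepoint with a noncentral-t 95%
interval, computed on the same normalised scale as the models.

## Cross-layer integration

Taxonomic and functional decompositions are integrated three ways:
Spearman correlation between all pairs of T-ES and F-ES score vectors
(two-sided p-values kept for annotation); between-line centroid
distances in W space per timepoint with a permutation test on
`Δ = d(last) − d(first)`; and per-timepoint PERMANOVA of line on
Euclidean distances among W rows.

Permutation choices that were open:

* **Exchangeability unit.** The trend test permutes line labels at the
  *animal* level — all of an animal's samples move together — because
  repeated measures within animal are dependent under the
  random-intercept design. Sample-level permutation is available as an
  option.
* **Sidedness and ties.** The trend p compares magnitudes —
  `|Δ_null| >= |Δ_obs|` with the +1 correction, ties counted — while
  the sign of the observed Δ is reported separately as the direction
  (divergence/convergence). Conditioning the tail on the observed sign
  instead would halve the p-values and break uniformity under the null;
  the magnitude form is exchangeability-valid. The PERMANOVA p counts only
  permuted pseudo-F values strictly greater than the observed one
  (+1 correction): under a continuous null, ties have probability zero,
  and a perfectly separating grouping then attains the 1/(n_perm + 1)
  floor rather than being diluted by permutations that merely reproduce
  the same partition.
* **Distance space.** Centroids and PERMANOVA operate on raw
  (TSS-scale) W rows, since the quantities are defined "in W-matrix
  space"; CLR space is a parameter away.

## The synthetic cohort

The generator is first-class, tested code: it defines the conditions
under which every downstream property is demonstrated.

* **Design**: 13 + 12 animals in two lines (TOL/SEN), three timepoints
  (d4, d8, d14), one sample dropped uniformly at random (75 → 74), all
  configurable.
* **Latent structure**: sample memberships from a symmetric
  Dirichlet(0.3) — samples mostly dominated by one subcommunity with a
  real mixture tail; signature profiles sparse (70% zeros) with
  log-normal(0, 2.5) magnitudes. These two defaults were calibrated so
  the simulated count matrix reproduces the ~38% zero fraction reported
  for strain-resolved MAG tables at the default depth of 1e5 reads per
  sample; the realised sparsity varies by seed (roughly 20–40%
  depending on how many features fall below detection).
* **Noise**: multinomial sampling at fixed depth, optionally
  Dirichlet-multinomial overdispersed (concentration `p / φ`), the
  standard overdispersed count model for metagenomic data.
* **Functional layer**: a guild-structured MAG→KO map (shared core
  block plus per-guild blocks, per-MAG dropout) emulating functional
  redundancy, so the KO matrix is a linear aggregate of the MAG matrix
  exactly as in real annotation pipelines.
* **Phenotypes**: linear couplings `P = μ + Wβ + offsets + ε`, matching
  the association model's own premise.
* **Group effects**: additive shifts on the membership simplex,
  renormalised, so planted effects keep W interpretable.

What the generator does *not* emulate: phylogenetic correlation among
features, sequencing-depth variation across samples, batch effects,
zero-inflation beyond the multinomial sampling process, and non-linear
phenotype couplings. Passing tests therefore demonstrate correctness of
the machinery and recoverability under the stated noise model — not that
real cohorts of this size will yield equally stable factorisations.

## Problem sizes used in the tests

The packaged checks run the full study geometry where it matters — 20
cohorts of 74 samples × 300 features for rank and factor recovery, 100
subsample iterations for stability, 500 replicates for mixed-model
calibration, 200 for effect-size coverage and permutation validity —
and small geometries (6–24 samples, 60–150 features, short rank grids)
for the per-operation contracts, keeping the default suite comfortably
below typical CI budgets on a single core.

## Known limitations

* KL-divergence NMF only; no Frobenius, sparse or orthogonal variants,
  and no topic models.
* Rank selection inherits the plateau behaviour of rss/evar above the
  true rank; the deciding metrics are consensus-based, so heavily
  overlapping subcommunities at low depth can still produce upward
  ties.
* The mixed models assume a single random intercept; no serial
  correlation structures or Kenward–Roger degrees of freedom.
* Cohen's d is computed on normalised loadings; on raw loadings the
  magnitudes differ.
* The KO layer is a deterministic aggregate of the MAG layer in the
  generator, so cross-layer correlations in synthetic data are stronger
  than typical real ones.
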