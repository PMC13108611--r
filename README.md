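# enterosig

Enterosignature discovery from microbiome abundance matrices via
consensus non-negative matrix factorization.

## The problem

Longitudinal microbiome studies — here, the gut metagenomes of lactating
sows from heat-tolerant (TOL) and heat-sensitive (SEN) genetic lines
sampled across a heat-stress challenge — are usually summarised by
taxon-level abundances or diversity indices, which miss the *ecological
structure* of the community: groups of organisms that rise and fall
together. An **enterosignature (ES)** is a latent, co-occurring
subcommunity learned directly from the data. Each sample is a
non-negative mixture of signatures, so communities are described as
blends of ecological signals rather than being forced into discrete
types.

`enterosig` implements the full analysis as a tested R package, for
microbiome researchers who want the method on their own sample-by-MAG or
sample-by-KO tables, exercised end-to-end on synthetic cohorts with
planted ground truth.

## The method

Given a non-negative samples x features matrix *V* (total-sum scaled),
find *W* (samples x k, signature loadings) and *H* (k x features,
signature profiles) minimising the generalised Kullback-Leibler
divergence

> D(V ‖ WH) = Σᵢⱼ [ Vᵢⱼ log(Vᵢⱼ/(WH)ᵢⱼ) − Vᵢⱼ + (WH)ᵢⱼ ]

by Brunet-style multiplicative updates. Around that core:

* **Rank selection** — multi-run consensus per candidate rank (default
  2–8, 10 runs each); five quality metrics (cophenetic correlation,
  silhouette, RSS, dispersion, explained variance) each vote for all
  ranks within 10% (taxonomic) or 5% (functional) of their optimum; most
  votes wins, ties go to the larger rank.
* **Stability** — 100 refits on 80% subsamples, factors matched to the
  reference by Hungarian-optimal Jaccard similarity of top-30 feature
  sets, plus pooled feature persistence.
* **Signature characterisation** — enrichment (= k x specificity),
  specificity, adaptive feature ranking (z-score vs fold-enrichment by
  coefficient of variation), dominant-signature composition summaries,
  Shannon diversity/evenness of loadings.
* **Association** — TMM + CLR normalisation of loadings, then
  linear mixed models (`loading ~ timepoint * line + (1 | animal)`, and
  phenotype models with the loading as covariate and all interactions)
  with type-III Satterthwaite F tests, Benjamini-Hochberg FDR,
  estimated-marginal-mean contrasts and Cohen's d with noncentral-t
  confidence intervals.
* **Integration** — Spearman correlation between taxonomic and
  functional signature scores, between-line centroid-distance trend
  tests with animal-level permutation, and per-timepoint PERMANOVA.
* **Synthetic cohorts** — a first-class generator planting
  mixed-membership ground truth (Dirichlet memberships, sparse
  heavy-tailed profiles, multinomial or Dirichlet-multinomial counts,
  guild-structured MAG→KO maps, linearly coupled phenotypes) so every
  claim above is testable.

## Worked example

```r
library(enterosig)

# a synthetic cohort with 4 planted subcommunities: 25 animals (13 TOL /
# 12 SEN), 3 timepoints, 74 usable samples, 300 MAG features, depth 1e5
co <- simulate_cohort(seed = 1)
V  <- tss_normalize(filter_features(co$mag))

metrics <- nmf_rank_survey(V, ranks = 2:8, n_runs = 10, seed = 1)
(sel <- select_rank(metrics, tolerance = 0.10))
#> Rank selection (tolerance 0.1): chosen k = 4
#> # A tibble: 7 × 2
#>    rank votes
#>   <int> <int>
#> 1     2     0
#> 2     3     1
#> 3     4     5
#> 4     5     3
#> 5     6     3
#> 6     7     3
#> 7     8     3

fit <- nmf_multirun(V, sel$chosen_k, n_runs = 30, seed = 1)$best
match_factors(fit$H, co$truth$H_true[, colnames(fit$H)])
#> # A tibble: 4 × 3
#>     ref   est cosine
#>   <int> <int>  <dbl>
#> 1     1     4  1.000
#> 2     2     3  1.000
#> 3     3     1  1.000
#> 4     4     2  1.000
```

The survey chose the planted rank (4) with a full house of five metric
votes, and the fitted signature profiles match the planted ones (up to
the expected factor permutation) with cosine similarity ≈ 1: on clean
data at this depth the decomposition is essentially exact. Downstream,

```r
clr   <- normalize_loadings(fit)                   # TMM + CLR, rows sum to 0
assoc <- fit_signature_models(clr, co$metadata)    # mixed models + contrasts
head(tidy(assoc), 3)
#> # A tibble: 3 × 8
#>   signature effect         F_value df_num df_den      p p_adj significance
#>   <chr>     <chr>            <dbl>  <int>  <dbl>  <dbl> <dbl> <chr>
#> 1 ES1       timepoint        0.793      2   45.7 0.459  0.459 ""
#> 2 ES1       line             3.37       1   23.1 0.0795 0.318 ""
#> 3 ES1       timepoint:line   0.516      2   45.7 0.601  0.768 ""
```

gives the per-signature type-III tests (no planted group effects here,
so nothing survives FDR — as it should). `subsample_stability()`,
`signature_scores()`, `composition_by_group()`,
`cross_layer_correlation()`, `centroid_trend_test()` and
`es_permanova()` cover the rest of the workflow, and `run_pipeline()`
chains everything from a single `es_config()` with TSV/JSON artifacts
and a hash manifest for byte-identical replay.

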