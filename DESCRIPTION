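Package: enterosig
Title: Enterosignature Discovery from Microbiome Abundance Matrices via
    Consensus Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes sample-by-feature microbial abundance tables
    (metagenome-assembled genomes or KEGG Orthology profiles) into latent
    co-occurring subcommunities ("enterosignatures") using Brunet
    Kullback-Leibler non-negative matrix factorization with multi-run
    consensus, tolerance-based rank selection over five quality metrics,
    and subsampling stability validation with Hungarian-matched Jaccard
    similarity. Downstream tools characterise signatures (enrichment,
    specificity, ranked top features, dominant-signature composition,
    loading diversity), normalise signature loadings (TMM then centred
    log-ratio), fit longitudinal mixed-effects association models with
    type-III Satterthwaite tests, FDR correction, marginal-mean contrasts
    and Cohen's d effect sizes, and integrate taxonomic with functional
    decompositions through Spearman correlation, centroid-distance
    permutation trend tests and PERMANOVA. A synthetic-cohort generator
    with planted ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    cluster,
    dplyr,
    edgeR,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
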