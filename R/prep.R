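#' Filter low-information features
#'
#' A feature is kept if it is present (strictly positive) in at least
#' `prevalence_min` of samples, or if its mean abundance lies strictly
#' above the `abundance_quantile` quantile of all features' means
#' (computed on the input matrix, linear-interpolation quantiles).  This
#' keeps rare-but-abundant features while removing sparse noise.
#'
#' @param tbl Abundance tibble (`sample_id` + feature columns).
#' @param prevalence_min Minimum presence fraction (inclusive), default 0.20.
#' @param abundance_quantile Quantile of per-feature means used as the
#'   abundance rescue threshold, default 0.75.
#' @return Filtered abundance tibble (a column subset; values unchanged).
#'   The attribute `filter_report` records features before/after and
#'   sparsity before/after.
#' @export
filter_features <- function(tbl, prevalence_min = 0.20,
                            abundance_quantile = 0.75) {
  stopifnot(prevalence_min > 0, prevalence_min <= 1,
            abundance_quantile > 0, abundance_quantile < 1)
  V <- check_nonnegative(as_abundance_matrix(tbl))
  if (nrow(V) == 0 || ncol(V) == 0) stop("empty abundance matrix")
  prevalence <- colMeans(V > 0)
  feat_means <- colMeans(V)
  thresh <- quantile(feat_means, abundance_quantile, names = FALSE)
  keep <- prevalence >= prevalence_min | feat_means > thresh
  if (!any(keep)) {
    stop("all ", ncol(V), " features removed (max prevalence ",
         signif(max(prevalence), 3), ", abundance threshold ",
         signif(thresh, 3), "); relax the filter")
  }
  out <- tbl[c("sample_id", colnames(V)[keep])]
  attr(out, "filter_report") <- list(
    n_features_before = ncol(V), n_features_after = sum(keep),
    sparsity_before = mean(V == 0),
    sparsity_after = mean(V[, keep, drop = FALSE] == 0),
    prevalence_min = prevalence_min, abundance_quantile = abundance_quantile
  )
  out
}

#' Total-sum scaling
#'
#' Divides each sample's abundances by its total, converting raw
#' abundances to within-sample proportions (the standard preprocessing
#' for NMF on microbiome data: keeps non-negativity, removes library-size
#' effects).  All-zero samples are left untouched and reported with a
#' warning.
#'
#' @param tbl Abundance tibble.
#' @return TSS-normalised abundance tibble; every row with a positive
#'   total sums to 1.
#' @export
tss_normalize <- function(tbl) {
  V <- check_nonnegative(as_abundance_matrix(tbl))
  totals <- rowSums(V)
  zero <- totals == 0
  if (any(zero)) {
    warning("all-zero samples left unnormalised: ",
            paste(rownames(V)[zero], collapse = ", "))
    totals[zero] <- 1
  }
  as_abundance_tibble(V / totals)
}

#' Matrix sparsity
#'
#' Fraction of exactly-zero entries in the feature block of an abundance
#' table.
#'
#' @param tbl Abundance tibble.
#' @return A single number in \\[0, 1\\].
#' @export
sparsity <- function(tbl) {
  V <- as_abundance_matrix(tbl)
  if (length(V) == 0) stop("empty abundance matrix")
  mean(V == 0)
}
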