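#' Enrichment and specificity of features within signatures
#'
#' For each (signature, feature) pair, `loading` is the H coefficient,
#' `specificity` is the fraction of the feature's total loading carried
#' by that signature (`H[s, j] / sum_s' H[s', j]`), and `enrichment` is
#' the fold over the feature's mean loading across signatures, hence
#' `enrichment = k * specificity` and lies in \\[0, k\\].  Features with
#' zero total loading get specificity and enrichment 0 and are flagged.
#'
#' @param fit An `es_nmf` object, or an H matrix (signatures x features).
#' @return Tibble with columns `signature`, `feature_id`, `loading`,
#'   `enrichment`, `specificity`, `zero_total`.
#' @export
signature_scores <- function(fit) {
  H <- if (inherits(fit, "es_nmf")) fit$H else fit
  stopifnot(is.matrix(H), all(H >= 0))
  if (is.null(rownames(H))) rownames(H) <- paste0("ES", seq_len(nrow(H)))
  if (is.null(colnames(H))) colnames(H) <- paste0("f", seq_len(ncol(H)))
  k <- nrow(H)
  totals <- colSums(H)
  safe <- ifelse(totals > 0, totals, 1)
  spec <- sweep(H, 2, safe, `/`)
  spec[, totals == 0] <- 0
  tibble::as_tibble(spec, rownames = "signature") |>
    tidyr::pivot_longer(-"signature", names_to = "feature_id",
                        values_to = "specificity") |>
    dplyr::mutate(
      loading = as.vector(t(H)),
      enrichment = k * .data$specificity,
      zero_total = rep(totals == 0, times = k)
    ) |>
    dplyr::select("signature", "feature_id", "loading", "enrichment",
                  "specificity", "zero_total")
}

#' Rank and truncate signature features
#'
#' Within each signature the ranking statistic adapts to how variable the
#' enrichment profile is: when the coefficient of variation of the
#' signature's (nonzero) enrichment values is below `cv_threshold`,
#' features are ranked by descending z-score of their loading
#' (standardised across features within the signature); otherwise by
#' descending fold-enrichment.  The top `top_n` features are kept.
#'
#' @param scores Output of [signature_scores()].
#' @param cv_threshold Coefficient-of-variation cutoff choosing the
#'   ranking mode (default 0.5).
#' @param top_n Number of features kept per signature (default 30); a
#'   signature with fewer features keeps all with a warning.
#' @return Tibble like `scores` plus `rank_mode` and `rank`, truncated to
#'   the top `top_n` rows per signature.
#' @export
rank_features <- function(scores, cv_threshold = 0.5, top_n = 30) {
  ranked <- scores |>
    dplyr::group_by(.data$signature) |>
    dplyr::group_modify(function(df, key) {
      enr <- df$enrichment[df$enrichment > 0]
      cv <- if (length(enr) >= 2 && mean(enr) > 0) sd(enr) / mean(enr) else 0
      if (cv < cv_threshold) {
        mu <- mean(df$loading); s <- sd(df$loading)
        stat <- if (is.na(s) || s == 0) rep(0, nrow(df)) else (df$loading - mu) / s
        mode <- "zscore"
      } else {
        stat <- df$enrichment
        mode <- "fold_enrichment"
      }
      df$rank_mode <- mode
      ord <- order(stat, decreasing = TRUE)
      df <- df[ord, ]
      df$rank <- seq_len(nrow(df))
      if (nrow(df) < top_n) {
        warning("signature ", key$signature, " has only ", nrow(df),
                " features (< top_n = ", top_n, ")")
      }
      head(df, top_n)
    }) |>
    dplyr::ungroup()
  ranked
}

top_feature_sets <- function(fit, top_n = 30, cv_threshold = 0.5) {
  ranked <- rank_features(signature_scores(fit), cv_threshold, top_n)
  sets <- split(ranked$feature_id, ranked$signature)
  sets[rownames(if (inherits(fit, "es_nmf")) fit$H else fit)]
}

#' Dominant signature per sample
#'
#' Assigns each sample the signature with the highest loading in its W
#' row (argmax); used for descriptive composition summaries only.  Ties
#' are broken toward the lowest factor index and flagged.
#'
#' @param fit An `es_nmf` object or a W matrix / loading tibble.
#' @return Tibble with `sample_id`, `signature`, `tie`.
#' @export
dominant_signature <- function(fit) {
  W <- if (inherits(fit, "es_nmf")) fit$W else as_abundance_matrix(fit)
  stopifnot(all(W >= 0))
  if (any(rowSums(W) == 0)) stop("all-zero loading rows have no dominant signature")
  idx <- max.col(W, ties.method = "first")
  tie <- vapply(seq_len(nrow(W)), function(i) {
    sum(W[i, ] == max(W[i, ])) > 1
  }, logical(1))
  tibble::tibble(sample_id = rownames(W),
                 signature = colnames(W)[idx],
                 tie = tie)
}

#' Dominant-signature composition by experimental group
#'
#' Within each (line, timepoint) cell, the percentage of samples whose
#' dominant signature is each factor; rows of percentages sum to 100.
#'
#' @param labels Output of [dominant_signature()].
#' @param metadata Cohort metadata with `sample_id`, `line`, `timepoint`.
#' @return Tibble with `line`, `timepoint`, `signature`, `n`, `percent`.
#' @export
composition_by_group <- function(labels, metadata) {
  missing <- setdiff(metadata$sample_id, labels$sample_id)
  if (length(missing) > 0) {
    stop("labels missing for samples: ", paste(head(missing, 5), collapse = ", "))
  }
  dplyr::inner_join(metadata, labels, by = "sample_id") |>
    dplyr::count(.data$line, .data$timepoint, .data$signature, name = "n") |>
    dplyr::group_by(.data$line, .data$timepoint) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Shannon diversity and evenness of signature loadings
#'
#' Per sample, loadings are renormalised to proportions `p_i` and the
#' Shannon diversity `H' = -sum(p_i * ln(p_i))` (natural log, with
#' `0 * ln 0 = 0`) and evenness `H' / ln(k)` are returned.  High evenness
#' means the sample spreads its membership over many signatures.
#'
#' @param fit An `es_nmf` object or a W matrix / loading tibble.
#' @return Tibble with `sample_id`, `shannon`, `evenness`.
#' @export
loading_diversity <- function(fit) {
  W <- if (inherits(fit, "es_nmf")) fit$W else as_abundance_matrix(fit)
  stopifnot(all(W >= 0))
  if (any(rowSums(W) == 0)) stop("all-zero loading rows have undefined diversity")
  P <- W / rowSums(W)
  shannon <- apply(P, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  tibble::tibble(sample_id = rownames(W),
                 shannon = unname(shannon),
                 evenness = unname(shannon) / log(ncol(W)))
}
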