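#' Subsampling stability of a factorisation
#'
#' Quantifies how reproducible the signatures are under resampling: the
#' reference solution is fitted on the full table, then in each of
#' `n_iter` iterations a random `fraction` of the samples is drawn
#' without replacement (stratified by line and timepoint when `metadata`
#' is supplied, preserving design balance), the NMF is refitted, the top
#' `top_n` feature sets per factor are extracted with the same ranking
#' rule as [rank_features()], and matched to the reference sets by
#' Hungarian-optimal Jaccard similarity.  Feature persistence is the
#' fraction of pooled reference top features recovered (in their matched
#' factor) in at least `persistence_threshold` of iterations.
#'
#' Iterations whose refit fails to converge are skipped and counted; more
#' than 20\% skipped is an error.
#'
#' @inheritParams nmf_multirun
#' @param metadata Optional metadata (`sample_id`, `line`, `timepoint`)
#'   for stratified subsampling.
#' @param n_iter Number of subsample iterations (default 100).
#' @param fraction Subsample fraction (default 0.8).
#' @param top_n Top features per factor compared (default 30).
#' @param n_runs Inner best-of runs per refit (default 5).
#' @param persistence_threshold Recovery-fraction cutoff for persistence
#'   (default 0.8).
#' @param reference Optional pre-fitted reference `es_nmf`; by default
#'   the reference is fitted here with the same `n_runs`.
#' @param cv_threshold Passed to the feature-ranking rule.
#' @param iter_seeds Optional integer vector of per-iteration refit seeds
#'   (length `n_iter`); defaults to `seed + 1 .. seed + n_iter`.
#' @return Object of class `es_stability`: `per_signature` (tibble of
#'   mean matched Jaccard), `per_iteration` (long tibble), `mean_jaccard`,
#'   `persistence`, `n_skipped`, `reference`, and parameters.
#' @export
subsample_stability <- function(tbl, k, metadata = NULL, n_iter = 100,
                                fraction = 0.8, top_n = 30, n_runs = 5,
                                persistence_threshold = 0.8,
                                reference = NULL, cv_threshold = 0.5,
                                seed = 12345, max_iter = 2000, tol = 1e-6,
                                iter_seeds = NULL) {
  V <- as_abundance_matrix(tbl)
  n <- nrow(V)
  if (floor(fraction * n) < k + 1) {
    stop("subsample of ", floor(fraction * n), " samples is too small for k = ", k)
  }
  if (is.null(reference)) {
    reference <- nmf_multirun(V, k, n_runs = n_runs, seed = seed,
                              max_iter = max_iter, tol = tol)$best
  }
  ref_sets <- top_feature_sets(reference, top_n, cv_threshold)
  strata <- if (!is.null(metadata)) {
    meta <- metadata[match(rownames(V), metadata$sample_id), ]
    split(seq_len(n), interaction(meta$line, meta$timepoint, drop = TRUE))
  } else {
    list(seq_len(n))
  }

  withr::local_seed(seed)
  iter_rows <- list()
  presence <- list()  # per iteration: named logical over pooled ref features
  pooled <- unlist(lapply(seq_along(ref_sets), function(s) {
    setNames(ref_sets[[s]], rep(s, length(ref_sets[[s]])))
  }))
  n_skipped <- 0
  for (it in seq_len(n_iter)) {
    idx <- sort(unlist(lapply(strata, function(ix) {
      take <- max(1, round(fraction * length(ix)))
      if (length(ix) == 1) ix else sample(ix, take)
    })))
    sub_seed <- if (is.null(iter_seeds)) seed + it else iter_seeds[it]
    sub_fit <- tryCatch(
      nmf_multirun(V[idx, , drop = FALSE], k, n_runs = n_runs,
                   seed = sub_seed, max_iter = max_iter, tol = tol)$best,
      error = function(e) NULL
    )
    if (is.null(sub_fit)) {
      n_skipped <- n_skipped + 1
      next
    }
    sub_sets <- top_feature_sets(sub_fit, top_n, cv_threshold)
    m <- match_signatures(ref_sets, sub_sets)
    iter_rows[[length(iter_rows) + 1]] <- tibble::tibble(
      iteration = it, signature = names(ref_sets), jaccard = m$jaccard
    )
    rec <- logical(length(pooled))
    for (s in seq_along(ref_sets)) {
      matched <- m$sub[m$ref == s]
      in_set <- if (is.na(matched)) character(0) else sub_sets[[matched]]
      sel <- names(pooled) == as.character(s)
      rec[sel] <- pooled[sel] %in% in_set
    }
    presence[[length(presence) + 1]] <- rec
  }
  if (n_skipped > 0.2 * n_iter) {
    stop(n_skipped, " of ", n_iter, " stability refits failed to converge")
  }
  per_iter <- dplyr::bind_rows(iter_rows)
  per_sig <- per_iter |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(mean_jaccard = mean(.data$jaccard), .groups = "drop")
  rec_frac <- if (length(presence) > 0) {
    rowMeans(do.call(cbind, presence))
  } else {
    rep(NA_real_, length(pooled))
  }
  structure(list(
    per_signature = per_sig,
    per_iteration = per_iter,
    mean_jaccard = mean(per_iter$jaccard),
    persistence = mean(rec_frac >= persistence_threshold),
    recovery_fraction = setNames(rec_frac, pooled),
    n_skipped = n_skipped,
    reference = reference,
    params = list(k = k, n_iter = n_iter, fraction = fraction,
                  top_n = top_n, n_runs = n_runs,
                  persistence_threshold = persistence_threshold, seed = seed)
  ), class = "es_stability")
}

#' @exportS3Method base::print
print.es_stability <- function(x, ...) {
  cat("Subsampling stability (", x$params$n_iter, " iterations at ",
      100 * x$params$fraction, "%): mean matched Jaccard ",
      round(x$mean_jaccard, 3), ", persistence ",
      round(100 * x$persistence, 1), "%\n", sep = "")
  print(x$per_signature)
  invisible(x)
}

#' @export
tidy.es_stability <- function(x, ...) x$per_signature

#' @export
glance.es_stability <- function(x, ...) {
  tibble::tibble(mean_jaccard = x$mean_jaccard,
                 persistence = x$persistence,
                 n_iter = x$params$n_iter,
                 n_skipped = x$n_skipped,
                 k = x$params$k)
}
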