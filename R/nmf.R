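#' Brunet NMF with Kullback-Leibler multiplicative updates
#'
#' Factorises a non-negative samples-by-features matrix `V` into
#' `V ~ W %*% H` with `W` (samples x k, signature loadings) and `H`
#' (k x features, signature profiles), minimising the generalised
#' Kullback-Leibler divergence `D(V || WH)` by multiplicative updates
#' (the Brunet formulation).  Factors are initialised from seeded
#' uniform(0, 1) draws scaled to the magnitude of `V`.  After
#' convergence each row of `H` is rescaled to sum 1 and `W` absorbs the
#' scale, leaving the product `W %*% H` unchanged; loadings are then
#' comparable across samples.
#'
#' Iteration stops when the relative decrease of the objective over a
#' `window`-iteration span falls below `tol`, or at `max_iter`.
#'
#' @param tbl Abundance tibble or non-negative numeric matrix (typically
#'   TSS-normalised).
#' @param k Factorisation rank (number of signatures).
#' @param max_iter Maximum number of update iterations.
#' @param tol Relative objective-change tolerance over `window` iterations.
#' @param window Convergence window length in iterations.
#' @param seed Integer seed for the initialisation.
#' @return An object of class `es_nmf`: list with `W`, `H`, `k`,
#'   `objective_trace` (KL divergence per iteration, index 1 = initial),
#'   `n_iter`, `converged`, `seed`.
#' @examples
#' V <- tss_normalize(simulate_cohort(seed = 1)$mag)
#' fit <- nmf_brunet(V, k = 4, seed = 1)
#' glance(fit)
#' @export
nmf_brunet <- function(tbl, k, max_iter = 2000, tol = 1e-6, window = 10,
                       seed = 12345) {
  V <- check_nonnegative(as_abundance_matrix(tbl), "V")
  n <- nrow(V); m <- ncol(V)
  if (k < 1 || k >= min(n, m)) {
    stop("rank k must satisfy 1 <= k < min(n_samples, n_features) = ",
         min(n, m))
  }
  if (any(rowSums(V) == 0)) stop("V has all-zero rows; drop them before NMF")

  withr::local_seed(seed)
  scale0 <- 2 * sqrt(mean(V) / k)
  W0 <- matrix(runif(n * k), n, k) * scale0
  H0 <- matrix(runif(k * m), k, m) * scale0

  res <- .nmf_brunet_cpp(V, W0, H0, as.integer(max_iter), tol,
                         as.integer(window))
  W <- res$W; H <- res$H
  # scale identifiability: H rows sum to 1, W absorbs the scale
  hsum <- rowSums(H)
  hsum[hsum == 0] <- 1
  H <- H / hsum
  W <- sweep(W, 2, hsum, `*`)
  dimnames(W) <- list(rownames(V), paste0("ES", seq_len(k)))
  dimnames(H) <- list(paste0("ES", seq_len(k)), colnames(V))

  structure(list(W = W, H = H, k = k,
                 objective_trace = res$objective_trace,
                 n_iter = res$n_iter, converged = res$converged,
                 seed = seed),
            class = "es_nmf")
}

#' @exportS3Method base::print
print.es_nmf <- function(x, ...) {
  cat("Brunet KL-NMF fit: ", nrow(x$W), " samples x ", ncol(x$H),
      " features, k = ", x$k, "\n", sep = "")
  cat("  final KL divergence ", signif(final_objective(x), 6), " after ",
      x$n_iter, " iterations (", if (x$converged) "converged" else
        "max_iter reached", ")\n", sep = "")
  invisible(x)
}

final_objective <- function(fit) {
  tr <- fit$objective_trace
  tr[length(tr)]
}

#' Tidy and summarise NMF fits
#'
#' `tidy()` returns the factor matrices in long form: `matrix = "W"`
#' rows are (sample_id, signature, loading), `matrix = "H"` rows are
#' (signature, feature_id, loading).  `glance()` returns a one-row fit
#' summary.
#'
#' @param x An `es_nmf` object.
#' @param matrix Which factor to return, `"W"` (default) or `"H"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.es_nmf <- function(x, matrix = c("W", "H"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "W") {
    as_abundance_tibble(x$W) |>
      tidyr::pivot_longer(-"sample_id", names_to = "signature",
                          values_to = "loading")
  } else {
    tibble::as_tibble(x$H, rownames = "signature") |>
      tidyr::pivot_longer(-"signature", names_to = "feature_id",
                          values_to = "loading")
  }
}

#' @rdname tidy.es_nmf
#' @export
glance.es_nmf <- function(x, ...) {
  tibble::tibble(k = x$k, n_iter = x$n_iter, converged = x$converged,
                 kl_divergence = final_objective(x), seed = x$seed)
}

consensus_from_labels <- function(labels_by_run) {
  n <- length(labels_by_run[[1]])
  C <- matrix(0, n, n)
  for (lab in labels_by_run) {
    C <- C + outer(lab, lab, `==`)
  }
  C <- C / length(labels_by_run)
  diag(C) <- 1
  C
}

#' Multi-run NMF with a consensus matrix
#'
#' Repeats [nmf_brunet()] with `n_runs` consecutive seeds, keeps the run
#' with the lowest final objective, and builds the sample consensus
#' matrix: `C[i, j]` is the fraction of runs in which samples i and j
#' share the same dominant signature (argmax of their W rows).  Runs that
#' fail numerically (non-finite or increasing objective) are excluded
#' from best-run selection and consensus and counted; if all runs fail,
#' an error is raised.  Runs stopped at `max_iter` without meeting the
#' tolerance are retained (their factors are valid) and counted in
#' `n_unconverged`.
#'
#' @inheritParams nmf_brunet
#' @param n_runs Number of independent runs (seeds `seed .. seed+n_runs-1`).
#' @return List of class `es_nmf_runs`: `best` (an `es_nmf`), `consensus`
#'   (samples x samples matrix in \\[0, 1\\]), `objectives` (per run),
#'   `n_runs`, `n_failed`.
#' @export
nmf_multirun <- function(tbl, k, n_runs = 10, seed = 12345,
                         max_iter = 2000, tol = 1e-6, window = 10) {
  stopifnot(n_runs >= 1)
  V <- as_abundance_matrix(tbl)
  fits <- lapply(seq_len(n_runs) - 1L, function(off) {
    nmf_brunet(V, k, max_iter = max_iter, tol = tol, window = window,
               seed = seed + off)
  })
  ok <- vapply(fits, function(f) {
    tr <- f$objective_trace
    # slack scaled by the initial objective: near an exact factorisation
    # the divergence underflows to ~0 and fluctuates at rounding level
    all(is.finite(tr)) && all(diff(tr) <= 1e-10 * max(abs(tr[1]), 1))
  }, logical(1))
  if (!any(ok)) stop("all NMF runs failed numerically at k = ", k)
  fits_ok <- fits[ok]
  objectives <- vapply(fits, final_objective, numeric(1))
  best <- fits_ok[[which.min(objectives[ok])]]
  labels <- lapply(fits_ok, function(f) max.col(f$W, ties.method = "first"))
  C <- consensus_from_labels(labels)
  dimnames(C) <- list(rownames(V), rownames(V))
  structure(list(best = best, consensus = C, objectives = objectives,
                 n_runs = n_runs, n_failed = sum(!ok),
                 n_unconverged = sum(!vapply(fits, function(f)
                   isTRUE(f$converged), logical(1))),
                 k = k, seed = seed),
            class = "es_nmf_runs")
}

#' @exportS3Method base::print
print.es_nmf_runs <- function(x, ...) {
  cat("Consensus of ", x$n_runs, " NMF runs at k = ", x$k,
      if (x$n_failed) paste0(" (", x$n_failed, " failed)"), "\n", sep = "")
  print(x$best)
  invisible(x)
}

#' Factorisation quality metrics
#'
#' Computes the five rank-selection metrics for one candidate rank:
#' * `cophenetic`: Pearson correlation between the consensus
#'   dissimilarity `1 - C` and the cophenetic distances of its
#'   average-linkage hierarchical clustering;
#' * `silhouette`: mean silhouette width of the samples under the
#'   consensus clustering cut at `k` clusters, distance `1 - C`
#'   (`NA` with a warning when fewer than 2 clusters are occupied);
#' * `rss`: residual sum of squares `sum((V - WH)^2)`;
#' * `dispersion`: `mean(4 * (C - 0.5)^2)`, 1 for perfectly binary
#'   consensus;
#' * `evar`: explained variance `1 - rss / sum(V^2)`.
#'
#' @param tbl The factorised abundance table (same one passed to
#'   [nmf_multirun()]).
#' @param runs An `es_nmf_runs` object (or pass `model` and `consensus`
#'   explicitly).
#' @param model,consensus Optional explicit best fit and consensus matrix.
#' @return One-row tibble: `rank`, `cophenetic`, `silhouette`, `rss`,
#'   `dispersion`, `evar`.
#' @export
nmf_quality <- function(tbl, runs = NULL, model = runs$best,
                        consensus = runs$consensus) {
  V <- as_abundance_matrix(tbl)
  stopifnot(inherits(model, "es_nmf"),
            nrow(consensus) == nrow(V), nrow(model$W) == nrow(V))
  C <- consensus
  d <- as.dist(1 - C)
  hc <- hclust(d, method = "average")
  coph <- if (sd(d) == 0) {
    NA_real_
  } else {
    cor(d, cophenetic(hc))
  }
  cl <- cutree(hc, k = min(model$k, nrow(C)))
  sil <- if (length(unique(cl)) < 2 || length(unique(cl)) >= nrow(C)) {
    warning("degenerate consensus clustering; silhouette is NA")
    NA_real_
  } else {
    mean(cluster::silhouette(cl, dmatrix = as.matrix(1 - C))[, "sil_width"])
  }
  resid <- V - model$W %*% model$H
  rss <- sum(resid^2)
  tibble::tibble(rank = model$k,
                 cophenetic = coph,
                 silhouette = sil,
                 rss = rss,
                 dispersion = mean(4 * (C - 0.5)^2),
                 evar = 1 - rss / sum(V^2))
}

#' Survey candidate factorisation ranks
#'
#' Runs multi-run consensus NMF over a grid of candidate ranks and
#' collects the five quality metrics per rank; feed the result to
#' [select_rank()].
#'
#' @inheritParams nmf_multirun
#' @param ranks Integer vector of candidate ranks (default 2:8).
#' @param keep_runs Keep the per-rank `es_nmf_runs` objects in the
#'   `runs` attribute (memory-heavy; default FALSE).
#' @return Tibble with one row per rank (class `es_rank_metrics`).
#' @export
nmf_rank_survey <- function(tbl, ranks = 2:8, n_runs = 10, seed = 12345,
                            max_iter = 2000, tol = 1e-6, window = 10,
                            keep_runs = FALSE) {
  stopifnot(length(ranks) >= 1, all(diff(ranks) > 0))
  V <- as_abundance_matrix(tbl)
  all_runs <- lapply(ranks, function(k) {
    nmf_multirun(V, k, n_runs = n_runs, seed = seed + 1000L * k,
                 max_iter = max_iter, tol = tol, window = window)
  })
  metrics <- purrr::map_dfr(all_runs, function(r) nmf_quality(V, r))
  class(metrics) <- c("es_rank_metrics", class(metrics))
  if (keep_runs) attr(metrics, "runs") <- setNames(all_runs, ranks)
  metrics
}
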