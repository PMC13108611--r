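#' Spearman correlation between two signature score sets
#'
#' Pairwise Spearman rank correlations between every taxonomic and every
#' functional signature score vector over the shared samples, with
#' two-sided p-values retained for annotation.  Constant score vectors
#' yield `NA` correlations for their pairs.
#'
#' @param w_tax,w_fun Loading tibbles (`sample_id` + signature columns)
#'   over the same samples.
#' @return Tibble with `t_es`, `f_es`, `rho`, `p`; the full matrices are
#'   in attributes `rho` and `rho_p`.
#' @export
cross_layer_correlation <- function(w_tax, w_fun) {
  Wt <- as_abundance_matrix(w_tax)
  Wf <- as_abundance_matrix(w_fun)
  stopifnot(nrow(Wt) >= 3)
  if (!identical(rownames(Wt), rownames(Wf))) {
    common <- intersect(rownames(Wt), rownames(Wf))
    if (length(common) < 3) stop("fewer than 3 shared samples")
    Wt <- Wt[common, , drop = FALSE]
    Wf <- Wf[common, , drop = FALSE]
  }
  kt <- ncol(Wt); kf <- ncol(Wf)
  rho <- matrix(NA_real_, kt, kf, dimnames = list(colnames(Wt), colnames(Wf)))
  pmat <- rho
  for (i in seq_len(kt)) {
    for (j in seq_len(kf)) {
      if (sd(Wt[, i]) == 0 || sd(Wf[, j]) == 0) next
      ct <- suppressWarnings(
        cor.test(Wt[, i], Wf[, j], method = "spearman", exact = FALSE)
      )
      rho[i, j] <- unname(ct$estimate)
      pmat[i, j] <- ct$p.value
    }
  }
  out <- tibble::as_tibble(rho, rownames = "t_es") |>
    tidyr::pivot_longer(-"t_es", names_to = "f_es", values_to = "rho")
  out$p <- as.vector(t(pmat))
  attr(out, "rho") <- rho
  attr(out, "rho_p") <- pmat
  out
}

line_centroid_delta <- function(W, line, timepoint, tps) {
  lev <- levels(line)
  dists <- vapply(tps, function(tp) {
    c1 <- colMeans(W[line == lev[1] & timepoint == tp, , drop = FALSE])
    c2 <- colMeans(W[line == lev[2] & timepoint == tp, , drop = FALSE])
    sqrt(sum((c1 - c2)^2))
  }, numeric(1))
  list(distances = setNames(dists, as.character(tps)),
       delta = dists[length(dists)] - dists[1])
}

#' Permutation trend test on between-line centroid distances
#'
#' Computes, at each timepoint, the Euclidean distance between the two
#' lines' centroids in signature-loading (W) space, and the change
#' `delta = d(last) - d(first)`.  The null distribution is built by
#' permuting line labels at the animal level (all of an animal's samples
#' move together, respecting the repeated-measures dependence); the
#' p-value counts null deltas whose magnitude reaches the observed
#' magnitude (`|delta_null| >= |delta_obs|`, +1 correction) — a valid
#' uniform-under-the-null test — while the sign of the observed delta is
#' reported as the direction annotation (divergence/convergence).
#' Permutations that empty a line-by-timepoint cell are redrawn and
#' counted.
#'
#' @param loadings Loading tibble (`sample_id` + signature columns).
#' @param metadata Cohort metadata.
#' @param n_perm Number of permutations (default 9999).
#' @param unit Permutation unit: `"animal"` (default) or `"sample"`.
#' @param seed Integer seed.
#' @return List with `distances` (per timepoint), `delta`, `perm_p`,
#'   `direction`, `n_redrawn`.
#' @export
centroid_trend_test <- function(loadings, metadata, n_perm = 9999,
                                unit = c("animal", "sample"), seed = 12345) {
  unit <- match.arg(unit)
  check_metadata(metadata)
  W <- as_abundance_matrix(loadings)
  meta <- metadata[match(rownames(W), metadata$sample_id), ]
  tps <- levels(droplevels(meta$timepoint))
  line <- droplevels(meta$line)
  stopifnot(nlevels(line) == 2, length(tps) >= 2)
  first_last <- c(tps[1], tps[length(tps)])
  for (tp in first_last) {
    if (any(table(line[meta$timepoint == tp]) == 0)) {
      stop("both lines must be present at the first and last timepoints")
    }
  }
  obs <- line_centroid_delta(W, line, meta$timepoint, tps)
  direction <- if (obs$delta >= 0) "divergence" else "convergence"

  animals <- unique(meta$animal_id)
  animal_line <- line[match(animals, meta$animal_id)]
  withr::local_seed(seed)
  n_hit <- 0; n_redrawn <- 0; done <- 0
  while (done < n_perm) {
    if (unit == "animal") {
      perm_line <- setNames(sample(animal_line), animals)
      pl <- perm_line[meta$animal_id]
    } else {
      pl <- sample(line)
    }
    cells <- table(pl, droplevels(meta$timepoint))
    if (any(cells == 0)) { n_redrawn <- n_redrawn + 1; next }
    null_delta <- line_centroid_delta(W, factor(pl, levels = levels(line)),
                                      meta$timepoint, tps)$delta
    if (abs(null_delta) >= abs(obs$delta)) n_hit <- n_hit + 1
    done <- done + 1
  }
  list(distances = obs$distances,
       delta = unname(obs$delta),
       perm_p = (1 + n_hit) / (1 + n_perm),
       direction = direction,
       n_redrawn = n_redrawn)
}

#' PERMANOVA on signature loadings
#'
#' One-factor permutational multivariate analysis of variance on
#' Euclidean distances among loading rows: `R^2` is the between-group
#' fraction of the total sum of squares, the pseudo-F statistic is
#' `(SS_between / (a - 1)) / (SS_within / (n - a))`, and the p-value is
#' obtained by permuting group labels (+1 correction; permuted statistics
#' strictly greater than the observed one count as more extreme, so a
#' perfectly separating grouping attains the `1 / (n_perm + 1)` floor).
#'
#' @param loadings Loading tibble or matrix (samples x signatures).
#' @param groups Factor (or vector) of group labels, one per sample.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @return List with `R2`, `F`, `p`, `n_perm`.
#' @export
es_permanova <- function(loadings, groups, n_perm = 9999, seed = 12345) {
  W <- as_abundance_matrix(loadings)
  groups <- droplevels(as.factor(groups))
  stopifnot(length(groups) == nrow(W))
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("need at least two samples per group")

  ss_decomp <- function(g) {
    centroid <- colMeans(W)
    ss_total <- sum(sweep(W, 2, centroid)^2)
    ss_within <- 0
    for (lev in levels(g)) {
      rows <- W[g == lev, , drop = FALSE]
      ss_within <- ss_within + sum(sweep(rows, 2, colMeans(rows))^2)
    }
    c(total = ss_total, within = ss_within)
  }
  n <- nrow(W); a <- nlevels(groups)
  pseudo_f <- function(g) {
    ss <- ss_decomp(g)
    ((ss["total"] - ss["within"]) / (a - 1)) / (ss["within"] / (n - a))
  }
  ss_obs <- ss_decomp(groups)
  R2 <- unname((ss_obs["total"] - ss_obs["within"]) / ss_obs["total"])
  F_obs <- unname(pseudo_f(groups))

  withr::local_seed(seed)
  n_hit <- 0
  for (b in seq_len(n_perm)) {
    g <- factor(sample(as.character(groups)), levels = levels(groups))
    F_b <- unname(pseudo_f(g))
    # label permutation preserves group sizes; Inf > Inf is FALSE, so an
    # exactly reproduced perfect partition does not count as more extreme
    if (isTRUE(F_b > F_obs)) n_hit <- n_hit + 1
  }
  list(R2 = R2, F = F_obs, p = (1 + n_hit) / (1 + n_perm), n_perm = n_perm)
}
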