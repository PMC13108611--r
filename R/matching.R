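#' Optimal one-to-one assignment (Hungarian algorithm)
#'
#' Solves the linear assignment problem for a square score matrix by the
#' Kuhn-Munkres shortest-augmenting-path algorithm with potentials
#' (O(n^3)).  Used to match factors between factorisation solutions.
#'
#' @param score Square numeric matrix of pairwise scores.
#' @param maximize Maximise total score (default) or minimise.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`.
#' @examples
#' hungarian_assign(matrix(c(0.9, 0.3, 0.2, 0.8), 2, byrow = TRUE))
#' @export
hungarian_assign <- function(score, maximize = TRUE) {
  stopifnot(is.matrix(score), nrow(score) == ncol(score),
            all(is.finite(score)))
  cost <- if (maximize) max(score) - score else score
  n <- nrow(cost)
  if (n == 1) return(1L)
  # columns/rows 0..n, index-shifted by +1; column 0 is the virtual root
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1]] <- j
  assignment
}

#' Jaccard similarity of two feature sets
#'
#' `|a intersect b| / |a union b|`; defined as 1 when both sets are empty.
#'
#' @param a,b Character (or atomic) vectors treated as sets.
#' @return A number in \\[0, 1\\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Match signature feature sets between two solutions
#'
#' Builds the Jaccard similarity matrix between reference and candidate
#' top-feature sets and finds the one-to-one assignment maximising total
#' Jaccard (Hungarian algorithm).  When the two solutions have unequal
#' factor counts, the shorter side is padded with empty sets (Jaccard 0).
#'
#' @param ref_sets,sub_sets Lists of feature-ID vectors, one per factor.
#' @return Tibble with one row per reference factor: `ref`, `sub`
#'   (matched candidate index, `NA` when paired with padding), `jaccard`.
#' @export
match_signatures <- function(ref_sets, sub_sets) {
  stopifnot(length(ref_sets) > 0, length(sub_sets) > 0)
  k_ref <- length(ref_sets); k_sub <- length(sub_sets)
  s <- max(k_ref, k_sub)
  J <- matrix(0, s, s)
  for (i in seq_len(k_ref)) {
    for (j in seq_len(k_sub)) {
      J[i, j] <- jaccard_index(ref_sets[[i]], sub_sets[[j]])
    }
  }
  a <- hungarian_assign(J, maximize = TRUE)
  tibble::tibble(
    ref = seq_len(k_ref),
    sub = ifelse(a[seq_len(k_ref)] <= k_sub, a[seq_len(k_ref)], NA_integer_),
    jaccard = J[cbind(seq_len(k_ref), a[seq_len(k_ref)])]
  )
}

#' Match estimated factors to reference factors by cosine similarity
#'
#' Hungarian matching on row-wise cosine similarity between two factor
#' profile matrices (e.g. estimated H against planted H); used to assess
#' factor recovery up to permutation.
#'
#' @param H_est,H_ref Factor-by-feature matrices with equal column counts.
#' @return Tibble with one row per reference factor: `ref`, `est`,
#'   `cosine`.
#' @export
match_factors <- function(H_est, H_ref) {
  stopifnot(ncol(H_est) == ncol(H_ref))
  k_est <- nrow(H_est); k_ref <- nrow(H_ref)
  s <- max(k_est, k_ref)
  S <- matrix(0, s, s)
  for (i in seq_len(k_ref)) {
    for (j in seq_len(k_est)) {
      S[i, j] <- sum(H_ref[i, ] * H_est[j, ]) /
        (sqrt(sum(H_ref[i, ]^2)) * sqrt(sum(H_est[j, ]^2)))
    }
  }
  a <- hungarian_assign(S, maximize = TRUE)
  tibble::tibble(
    ref = seq_len(k_ref),
    est = ifelse(a[seq_len(k_ref)] <= k_est, a[seq_len(k_ref)], NA_integer_),
    cosine = S[cbind(seq_len(k_ref), a[seq_len(k_ref)])]
  )
}
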