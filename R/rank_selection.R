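#' Consensus tolerance-based rank selection
#'
#' Each quality metric votes for every candidate rank whose value lies
#' within `tolerance` of that metric's optimum: for maximised metrics
#' (cophenetic, silhouette, dispersion, explained variance) rank r is
#' acceptable iff `metric(r) >= (1 - tolerance) * max`; for minimised
#' metrics (residual sum of squares) iff
#' `metric(r) <= (1 + tolerance) * min`.  When a maximised metric's
#' optimum is non-positive the relative rule is ill-defined, so
#' acceptability falls back to absolute distance
#' `|metric(r) - opt| <= tolerance * |opt|`.  The rank accepted by the
#' most metrics wins; ties are broken toward the larger rank when
#' `prefer_higher` (higher ranks preserve ecological resolution).
#' Missing metric values abstain for that rank.
#'
#' @param metrics A rank-metrics tibble from [nmf_rank_survey()] (columns
#'   `rank`, `cophenetic`, `silhouette`, `rss`, `dispersion`, `evar`).
#' @param tolerance Relative tolerance in (0, 1); conventionally 0.10 for
#'   taxonomic and 0.05 for functional matrices.
#' @param prefer_higher Break vote ties toward the larger rank.
#' @return Object of class `es_rank_selection`: list with `chosen_k`,
#'   `votes` (tibble rank/votes), `acceptable` (per metric, the accepted
#'   ranks), `tolerance`.
#' @export
select_rank <- function(metrics, tolerance = 0.10, prefer_higher = TRUE) {
  stopifnot(nrow(metrics) >= 2, tolerance > 0, tolerance < 1,
            all(diff(metrics$rank) > 0))
  maximise <- c("cophenetic", "silhouette", "dispersion", "evar")
  minimise <- "rss"
  ranks <- metrics$rank

  acceptable <- lapply(c(maximise, minimise), function(name) {
    v <- metrics[[name]]
    ok <- !is.na(v)
    if (!any(ok)) return(integer(0))
    if (name %in% minimise) {
      opt <- min(v[ok])
      acc <- ok & v <= (1 + tolerance) * opt
    } else {
      opt <- max(v[ok])
      acc <- if (opt > 0) {
        ok & v >= (1 - tolerance) * opt
      } else {
        ok & abs(v - opt) <= tolerance * abs(opt)
      }
    }
    ranks[acc]
  })
  names(acceptable) <- c(maximise, minimise)

  votes <- vapply(ranks, function(r) {
    sum(vapply(acceptable, function(acc) r %in% acc, logical(1)))
  }, integer(1))
  winners <- ranks[votes == max(votes)]
  chosen <- if (prefer_higher) max(winners) else min(winners)

  structure(list(chosen_k = chosen,
                 votes = tibble::tibble(rank = ranks, votes = votes),
                 acceptable = acceptable,
                 tolerance = tolerance,
                 prefer_higher = prefer_higher),
            class = "es_rank_selection")
}

#' @exportS3Method base::print
print.es_rank_selection <- function(x, ...) {
  cat("Rank selection (tolerance ", x$tolerance, "): chosen k = ",
      x$chosen_k, "\n", sep = "")
  print(x$votes, n = Inf)
  invisible(x)
}

#' @export
tidy.es_rank_selection <- function(x, ...) {
  metrics <- names(x$acceptable)
  purrr::map_dfr(metrics, function(m) {
    tibble::tibble(metric = m, rank = x$votes$rank,
                   acceptable = x$votes$rank %in% x$acceptable[[m]])
  })
}

#' @export
glance.es_rank_selection <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k,
                 max_votes = max(x$votes$votes),
                 n_candidates = nrow(x$votes),
                 tolerance = x$tolerance)
}
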