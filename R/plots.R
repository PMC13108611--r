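#' Plot rank-survey quality metrics
#'
#' One line per metric across candidate ranks, each metric rescaled to
#' its own panel; the chosen rank (if a selection is supplied) is marked.
#'
#' @param metrics Tibble from [nmf_rank_survey()].
#' @param selection Optional [select_rank()] result.
#' @return A ggplot object.
#' @export
plot_rank_survey <- function(metrics, selection = NULL) {
  long <- tidyr::pivot_longer(tibble::as_tibble(metrics), -"rank",
                              names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "candidate rank k", y = NULL,
                  title = "NMF rank-survey quality metrics") +
    ggplot2::theme_minimal()
  if (!is.null(selection)) {
    p <- p + ggplot2::geom_vline(xintercept = selection$chosen_k,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' @export
autoplot.es_rank_metrics <- function(object, ...) plot_rank_survey(object, ...)

#' Heatmap of signature loadings
#'
#' Samples by signatures tile plot of the W matrix.
#'
#' @param object An `es_nmf` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.es_nmf <- function(object, ...) {
  tidy(object, matrix = "W") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$signature, y = .data$sample_id,
                                 fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading",
                  title = "Signature loadings (W)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Stacked dominant-signature composition bars
#'
#' @param composition Tibble from [composition_by_group()].
#' @return A ggplot object.
#' @export
plot_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$timepoint, y = .data$percent,
                               fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~line) +
    ggplot2::labs(x = NULL, y = "% of samples",
                  title = "Dominant-signature composition") +
    ggplot2::theme_minimal()
}

#' Cross-layer correlation tile plot
#'
#' @param corr Tibble from [cross_layer_correlation()].
#' @return A ggplot object.
#' @export
plot_cross_layer <- function(corr) {
  ggplot2::ggplot(corr, ggplot2::aes(x = .data$f_es, y = .data$t_es,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$rho), "",
                     sprintf("%.2f%s", .data$rho,
                             significance_stars(.data$p)))), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "functional signatures", y = "taxonomic signatures",
                  fill = "Spearman rho") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.es_stability <- function(object, ...) {
  ggplot2::ggplot(object$per_iteration,
                  ggplot2::aes(x = .data$signature, y = .data$jaccard)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "matched Jaccard",
                  title = "Subsampling stability") +
    ggplot2::theme_minimal()
}
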