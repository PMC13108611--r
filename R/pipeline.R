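#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()].  Defaults mirror the
#' package's reference analysis: candidate ranks 2-8 with 10 runs per
#' rank, 30 final runs, rank-selection tolerance 0.10 for taxonomic (MAG)
#' and 0.05 for functional (KO) matrices, 100 stability iterations on 80%
#' subsamples, top 30 features per signature, seed 12345.
#'
#' Inputs may be in-memory tibbles or file paths (TSV/CSV, read at run
#' time with [read_abundance()] / [readr::read_tsv()]).
#'
#' @param abundance MAG abundance table (tibble or path).
#' @param metadata Cohort metadata (tibble or path).
#' @param phenotypes Optional phenotype table (tibble or path).
#' @param ko Optional KO abundance table (tibble or path) for the
#'   functional layer and cross-layer integration.
#' @param ranks Candidate rank grid.
#' @param runs_per_rank,final_runs NMF runs during the survey and for the
#'   final fit.
#' @param tolerance,tolerance_ko Rank-selection tolerances for the MAG
#'   and KO layers.
#' @param stability_iter,stability_fraction,stability_runs Stability
#'   parameters.
#' @param top_n Top features per signature.
#' @param n_perm Permutations for the trend test and PERMANOVA.
#' @param seed Master seed.
#' @return A named list of class `es_config`.
#' @export
es_config <- function(abundance, metadata, phenotypes = NULL, ko = NULL,
                      ranks = 2:8, runs_per_rank = 10, final_runs = 30,
                      tolerance = 0.10, tolerance_ko = 0.05,
                      stability_iter = 100, stability_fraction = 0.8,
                      stability_runs = 5, top_n = 30, n_perm = 9999,
                      seed = 12345) {
  stopifnot(tolerance > 0, tolerance < 1, tolerance_ko > 0, tolerance_ko < 1,
            seed == as.integer(seed))
  structure(as.list(environment()), class = "es_config")
}

load_table <- function(x, kind = "MAG") {
  if (is.character(x)) {
    if (!file.exists(x)) stop("input file not found: ", x)
    if (kind %in% c("MAG", "KO")) return(read_abundance(x, kind))
    tbl <- readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
    return(tbl)
  }
  x
}

ensure_metadata_factors <- function(meta) {
  meta$line <- factor(meta$line, levels = intersect(c("TOL", "SEN"),
                                                    unique(meta$line)))
  if (!is.factor(meta$timepoint)) {
    meta$timepoint <- factor(meta$timepoint, levels = unique(meta$timepoint))
  }
  meta
}

analyse_layer <- function(tbl, meta, config, tolerance, layer, out_dir) {
  msg <- function(...) message("[", layer, "] ", ...)
  filtered <- filter_features(tbl)
  rep <- attr(filtered, "filter_report")
  msg("filtered ", rep$n_features_before, " -> ", rep$n_features_after,
      " features; sparsity ", round(100 * rep$sparsity_before, 1), "% -> ",
      round(100 * rep$sparsity_after, 1), "%")
  V <- tss_normalize(filtered)
  metrics <- nmf_rank_survey(V, ranks = config$ranks,
                             n_runs = config$runs_per_rank,
                             seed = config$seed)
  sel <- select_rank(metrics, tolerance = tolerance)
  msg("selected rank k = ", sel$chosen_k)
  runs <- nmf_multirun(V, sel$chosen_k, n_runs = config$final_runs,
                       seed = config$seed)
  stab <- subsample_stability(V, sel$chosen_k, metadata = meta,
                              n_iter = config$stability_iter,
                              fraction = config$stability_fraction,
                              n_runs = config$stability_runs,
                              top_n = config$top_n,
                              reference = runs$best, seed = config$seed)
  msg("stability: mean matched Jaccard ", round(stab$mean_jaccard, 3))
  fit <- runs$best
  scores <- signature_scores(fit)
  ranked <- rank_features(scores, top_n = config$top_n)
  labels <- dominant_signature(fit)
  comp <- composition_by_group(labels, meta)
  div <- loading_diversity(fit)
  clr <- normalize_loadings(fit)
  assoc <- fit_signature_models(clr, meta)

  prefix <- file.path(out_dir, layer)
  write_abundance(as_abundance_tibble(fit$W), paste0(prefix, "_W.tsv"))
  readr::write_tsv(tibble::as_tibble(fit$H, rownames = "signature"),
                   paste0(prefix, "_H.tsv"))
  readr::write_tsv(tibble::as_tibble(metrics), paste0(prefix, "_rank_metrics.tsv"))
  jsonlite::write_json(
    list(chosen_k = sel$chosen_k,
         votes = sel$votes, acceptable = sel$acceptable,
         tolerance = tolerance,
         filter = rep,
         stability = list(mean_jaccard = stab$mean_jaccard,
                          persistence = stab$persistence,
                          per_signature = stab$per_signature)),
    paste0(prefix, "_selection.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  readr::write_tsv(ranked, paste0(prefix, "_signatures.tsv"))
  readr::write_tsv(comp, paste0(prefix, "_composition.tsv"))
  readr::write_tsv(div, paste0(prefix, "_diversity.tsv"))
  readr::write_tsv(clr, paste0(prefix, "_clr.tsv"))
  readr::write_tsv(assoc$omnibus, paste0(prefix, "_omnibus.tsv"))
  readr::write_tsv(assoc$contrasts, paste0(prefix, "_contrasts.tsv"))

  list(filtered = filtered, V = V, metrics = metrics, selection = sel,
       fit = fit, stability = stab, signatures = ranked,
       composition = comp, diversity = div, clr = clr, association = assoc)
}

#' Run the full enterosignature pipeline
#'
#' Executes preparation, factorisation with rank selection, stability
#' validation, signature characterisation, loading normalisation and
#' mixed-model association for the MAG layer (and, when a KO table is
#' configured, the functional layer plus cross-layer integration:
#' Spearman correlation, centroid trend test and per-timepoint
#' PERMANOVA).  All artifacts are written as TSV/JSON under `out_dir`
#' together with a manifest (parameters, package version, content hashes)
#' that allows byte-identical replay; every randomised stage consumes an
#' explicit seed derived from the configuration.
#'
#' @param config An [es_config()] object.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a result bundle: per-layer results, optional
#'   `integration`, and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "es_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- ensure_metadata_factors(load_table(config$metadata, kind = "meta"))
  mag <- load_table(config$abundance, "MAG")
  message("[input] ", nrow(mag), " samples x ", ncol(mag) - 1, " MAG features")

  res <- list()
  res$mag <- analyse_layer(mag, meta, config, config$tolerance, "mag", out_dir)

  if (!is.null(config$ko)) {
    ko <- load_table(config$ko, "KO")
    res$ko <- analyse_layer(ko, meta, config, config$tolerance_ko, "ko", out_dir)

    w_tax <- as_abundance_tibble(res$mag$fit$W)
    w_fun <- as_abundance_tibble(res$ko$fit$W)
    corr <- cross_layer_correlation(w_tax, w_fun)
    trend <- centroid_trend_test(w_tax, meta, n_perm = config$n_perm,
                                 seed = config$seed)
    tps <- levels(droplevels(meta$timepoint))
    perma <- purrr::map_dfr(tps, function(tp) {
      sel <- meta$timepoint == tp
      pm <- es_permanova(res$mag$fit$W[meta$sample_id[sel], , drop = FALSE],
                         meta$line[sel], n_perm = config$n_perm,
                         seed = config$seed)
      tibble::tibble(timepoint = tp, R2 = pm$R2, F = pm$F, p = pm$p)
    })
    res$integration <- list(correlation = corr, trend = trend,
                            permanova = perma)
    readr::write_tsv(corr, file.path(out_dir, "cross_layer_correlation.tsv"))
    jsonlite::write_json(
      list(trend = trend[c("distances", "delta", "perm_p", "direction")],
           permanova = perma),
      file.path(out_dir, "integration.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if (!is.null(config$phenotypes)) {
    pheno <- load_table(config$phenotypes, kind = "pheno")
    passoc <- fit_phenotype_models(pheno, res$mag$clr, meta)
    res$phenotype_association <- passoc
    readr::write_tsv(passoc$omnibus, file.path(out_dir, "phenotype_omnibus.tsv"))
  }

  files <- sort(list.files(out_dir, full.names = TRUE,
                           pattern = "\\.(tsv|json)$"))
  files <- files[basename(files) != "manifest.json"]
  params <- config[!vapply(config, is.data.frame, logical(1))]
  params <- params[vapply(params, function(x)
    is.numeric(x) || is.character(x) || is.logical(x), logical(1))]
  manifest <- list(
    package = "enterosig",
    version = as.character(utils::packageVersion("enterosig")),
    parameters = params,
    outputs = setNames(as.list(unname(tools::md5sum(files))), basename(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
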