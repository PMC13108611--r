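#' TMM + CLR normalisation of signature loadings
#'
#' Two-step normalisation of the W loading matrix for statistical
#' testing.  First, trimmed-mean-of-M-values (TMM) scale factors are
#' computed per sample (edgeR: doubly trimmed log-ratios against the
#' reference sample whose upper-quartile loading is closest to the mean
#' upper quartile; trim fractions 0.3 on M-values, 0.05 on A-values) to
#' remove composition bias in total signature loading.  Each sample's
#' loadings are divided by its effective total (row total times TMM
#' factor).  Second, a pseudocount of half the smallest positive scaled
#' value is added and the centred log-ratio transform applied per sample:
#' `x -> ln(x) - mean(ln(x))`, so every row sums to zero.
#'
#' @param fit An `es_nmf` object or a loading tibble/matrix (samples x
#'   signatures, non-negative with positive row sums).
#' @return Tibble (`sample_id` + signature columns) of CLR-transformed
#'   loadings, with attributes `tmm_factors` (named per sample) and
#'   `pseudocount`.
#' @export
normalize_loadings <- function(fit) {
  W <- if (inherits(fit, "es_nmf")) fit$W else as_abundance_matrix(fit)
  check_nonnegative(W, "loading matrix")
  if (any(rowSums(W) == 0)) stop("loading matrix has all-zero rows")
  nf <- suppressWarnings(
    edgeR::calcNormFactors(edgeR::DGEList(counts = t(W)), method = "TMM")
  )$samples$norm.factors
  if (any(!is.finite(nf))) {
    warning("TMM factor undefined for ", sum(!is.finite(nf)),
            " sample(s) (no co-positive signatures with the reference); set to 1")
    nf[!is.finite(nf)] <- 1
  }
  names(nf) <- rownames(W)
  scaled <- W / (rowSums(W) * nf)
  pc <- min(scaled[scaled > 0]) / 2
  logx <- log(scaled + pc)
  clr <- logx - rowMeans(logx)
  out <- as_abundance_tibble(clr)
  attr(out, "tmm_factors") <- nf
  attr(out, "pseudocount") <- pc
  out
}

check_metadata <- function(metadata) {
  stopifnot(all(c("sample_id", "animal_id", "line", "timepoint") %in%
                  names(metadata)))
  metadata
}

sum_contrasts <- function() list(timepoint = "contr.sum", line = "contr.sum")

fit_flags <- function(m) {
  msgs <- unlist(m@optinfo$conv$lme4$messages)
  # a singular fit (animal variance estimated at zero) is valid and only
  # flagged; convergence failure means the optimiser itself complained
  msgs <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
  list(converged = length(msgs) == 0 && m@optinfo$conv$opt == 0,
       singular = lme4::isSingular(m))
}

#' Benjamini-Hochberg adjustment within families
#'
#' Step-up false-discovery-rate adjustment applied independently within
#' each family of tests (e.g. within each phenotype-by-signature
#' contrast family).
#'
#' @param p Numeric vector of p-values in \\[0, 1\\].
#' @param family Optional grouping vector of the same length; `NULL`
#'   treats all p-values as one family.
#' @return Adjusted p-values, same order as `p`.
#' @export
fdr_adjust <- function(p, family = NULL) {
  if (length(p) == 0) stop("empty p-value family")
  if (is.null(family)) return(p.adjust(p, method = "BH"))
  stopifnot(length(family) == length(p))
  out <- numeric(length(p))
  for (f in split(seq_along(p), family)) {
    out[f] <- p.adjust(p[f], method = "BH")
  }
  out
}

#' Longitudinal mixed model for one response
#'
#' Fits `y ~ timepoint * line + (1 | animal_id)` by REML with sum-to-zero
#' factor coding and returns the type-III ANOVA table with Satterthwaite
#' denominator degrees of freedom, plus convergence/singularity flags.
#' This is the per-signature workhorse behind [fit_signature_models()].
#'
#' @param data Data frame with columns `y`, `timepoint`, `line`,
#'   `animal_id`.
#' @return List with `model` (lmerModLmerTest), `anova` (tibble: effect,
#'   F, df_num, df_den, p), `converged`, `singular`.
#' @export
fit_es_model <- function(data) {
  stopifnot(all(c("y", "timepoint", "line", "animal_id") %in% names(data)))
  m <- suppressMessages(
    lmerTest::lmer(y ~ timepoint * line + (1 | animal_id), data = data,
                   contrasts = sum_contrasts())
  )
  a <- anova(m, type = 3)   # Satterthwaite is the lmerTest default
  flags <- fit_flags(m)
  list(model = m,
       anova = tibble::tibble(
         effect = rownames(a),
         F_value = a$`F value`,
         df_num = a$NumDF,
         df_den = a$DenDF,
         p = a$`Pr(>F)`
       ),
       converged = flags$converged,
       singular = flags$singular)
}

#' Marginal-mean contrasts on the line-by-timepoint grid
#'
#' Estimated marginal means (balanced factor weights) for every
#' line-by-timepoint cell, then two contrast families: the line
#' difference at each timepoint, and the temporal changes within each
#' line.  Standard errors come from the fixed-effect covariance; p-values
#' use t tests with Satterthwaite degrees of freedom and are
#' FDR-adjusted within each family.
#'
#' @param model A fitted `lmer`/`lmerModLmerTest` model containing
#'   `timepoint` and `line` fixed effects.
#' @return List with `emmeans` (grid tibble) and `contrasts` (tibble:
#'   family, contrast, group, estimate, SE, df, p, p_adj).
#' @export
marginal_contrasts <- function(model) {
  emm_lt <- emmeans::emmeans(model, ~ line | timepoint,
                             lmer.df = "satterthwaite")
  line_ct <- as.data.frame(summary(emmeans::contrast(emm_lt, "pairwise"),
                                   adjust = "none"))
  emm_tl <- emmeans::emmeans(model, ~ timepoint | line,
                             lmer.df = "satterthwaite")
  time_ct <- as.data.frame(summary(emmeans::contrast(emm_tl, "pairwise"),
                                   adjust = "none"))
  grid <- as.data.frame(summary(emm_lt))
  ct <- dplyr::bind_rows(
    tibble::tibble(family = "line_within_timepoint",
                   contrast = as.character(line_ct$contrast),
                   group = as.character(line_ct$timepoint),
                   estimate = line_ct$estimate, SE = line_ct$SE,
                   df = line_ct$df, p = line_ct$p.value),
    tibble::tibble(family = "time_within_line",
                   contrast = as.character(time_ct$contrast),
                   group = as.character(time_ct$line),
                   estimate = time_ct$estimate, SE = time_ct$SE,
                   df = time_ct$df, p = time_ct$p.value)
  )
  ct$p_adj <- fdr_adjust(ct$p, ct$family)
  list(emmeans = tibble::as_tibble(grid), contrasts = ct)
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    p < 0.10 ~ ".",
    TRUE ~ ""
  )
}

#' Associate signature loadings with the experimental design
#'
#' For every signature column of the (normalised) loading table, fits the
#' longitudinal mixed model `loading ~ timepoint * line + (1 | animal)`
#' and collects type-III Satterthwaite F tests (FDR-adjusted across
#' signatures within each effect), marginal-mean contrasts
#' (FDR-adjusted within each signature-by-family group), and per-timepoint
#' Cohen's d between lines with 95\% confidence intervals.  Models that
#' fail to converge are excluded from inference and flagged.
#'
#' @param loadings Loading tibble (`sample_id` + one column per
#'   signature), typically from [normalize_loadings()].
#' @param metadata Cohort metadata (`sample_id`, `animal_id`, `line`,
#'   `timepoint`).
#' @return Object of class `es_association`: `omnibus`, `contrasts`,
#'   `effect_sizes`, `emmeans`, `flags` tibbles.
#' @export
fit_signature_models <- function(loadings, metadata) {
  check_metadata(metadata)
  Wt <- as_abundance_matrix(loadings)
  meta <- metadata[match(rownames(Wt), metadata$sample_id), ]
  sigs <- colnames(Wt)
  omnibus <- list(); contrasts <- list(); esizes <- list()
  emms <- list(); flags <- list()
  for (s in sigs) {
    dat <- data.frame(y = Wt[, s], meta)
    fit <- fit_es_model(dat)
    flags[[s]] <- tibble::tibble(signature = s, converged = fit$converged,
                                 singular = fit$singular)
    if (!fit$converged) next
    omnibus[[s]] <- dplyr::mutate(fit$anova, signature = s, .before = 1)
    mc <- marginal_contrasts(fit$model)
    contrasts[[s]] <- dplyr::mutate(mc$contrasts, signature = s, .before = 1)
    emms[[s]] <- dplyr::mutate(mc$emmeans, signature = s, .before = 1)
    esizes[[s]] <- purrr::map_dfr(levels(droplevels(meta$timepoint)), function(tp) {
      sel <- meta$timepoint == tp
      x <- dat$y[sel & meta$line == levels(meta$line)[1]]
      y <- dat$y[sel & meta$line == levels(meta$line)[2]]
      es <- cohens_d(x, y)
      tibble::tibble(signature = s, timepoint = tp,
                     d = es$d, ci_low = es$ci_low, ci_high = es$ci_high)
    })
  }
  omnibus <- dplyr::bind_rows(omnibus)
  if (nrow(omnibus) > 0) {
    omnibus$p_adj <- fdr_adjust(omnibus$p, omnibus$effect)
    omnibus$significance <- significance_stars(omnibus$p_adj)
  }
  ct <- dplyr::bind_rows(contrasts)
  if (nrow(ct) > 0) {
    # re-adjust within (signature, family), the per-ES contrast family
    ct$p_adj <- fdr_adjust(ct$p, paste(ct$signature, ct$family))
  }
  structure(list(omnibus = omnibus,
                 contrasts = ct,
                 effect_sizes = dplyr::bind_rows(esizes),
                 emmeans = dplyr::bind_rows(emms),
                 flags = dplyr::bind_rows(flags)),
            class = "es_association")
}

#' Associate phenotypes with signature loadings
#'
#' For every phenotype-by-signature pair, fits the full-factorial mixed
#' model `P ~ loading * timepoint * line + (1 | animal)` (all two- and
#' three-way interactions retained as a pre-specified plan) and extracts
#' type-III Satterthwaite F tests; p-values are FDR-adjusted across
#' signatures within each (phenotype, effect) family.
#'
#' @param phenotypes Tibble (`sample_id` + one numeric column per
#'   phenotype).
#' @param loadings Loading tibble as in [fit_signature_models()].
#' @param metadata Cohort metadata.
#' @return Object of class `es_association` with `omnibus` and `flags`.
#' @export
fit_phenotype_models <- function(phenotypes, loadings, metadata) {
  check_metadata(metadata)
  Wt <- as_abundance_matrix(loadings)
  meta <- metadata[match(rownames(Wt), metadata$sample_id), ]
  ph_mat <- as_abundance_matrix(phenotypes)
  ph_mat <- ph_mat[rownames(Wt), , drop = FALSE]
  omnibus <- list(); flags <- list()
  for (ph in colnames(ph_mat)) {
    for (s in colnames(Wt)) {
      dat <- data.frame(P = ph_mat[, ph], es = Wt[, s], meta)
      m <- suppressMessages(
        lmerTest::lmer(P ~ es * timepoint * line + (1 | animal_id),
                       data = dat, contrasts = sum_contrasts())
      )
      fl <- fit_flags(m)
      flags[[paste(ph, s)]] <- tibble::tibble(
        phenotype = ph, signature = s,
        converged = fl$converged, singular = fl$singular)
      if (!fl$converged) next
      a <- anova(m, type = 3)
      beta_hat <- lme4::fixef(m)[["es"]]
      omnibus[[paste(ph, s)]] <- tibble::tibble(
        phenotype = ph, signature = s, effect = rownames(a),
        F_value = a$`F value`, df_num = a$NumDF, df_den = a$DenDF,
        p = a$`Pr(>F)`, beta = beta_hat)
    }
  }
  omnibus <- dplyr::bind_rows(omnibus)
  if (nrow(omnibus) > 0) {
    omnibus$p_adj <- fdr_adjust(omnibus$p,
                                paste(omnibus$phenotype, omnibus$effect))
    omnibus$significance <- significance_stars(omnibus$p_adj)
  }
  structure(list(omnibus = omnibus, contrasts = tibble::tibble(),
                 effect_sizes = tibble::tibble(), emmeans = tibble::tibble(),
                 flags = dplyr::bind_rows(flags)),
            class = "es_association")
}

#' @exportS3Method base::print
print.es_association <- function(x, ...) {
  cat("Mixed-model association results: ", nrow(x$omnibus),
      " omnibus tests\n", sep = "")
  print(head(dplyr::arrange(x$omnibus, .data$p_adj), 10))
  invisible(x)
}

#' @export
tidy.es_association <- function(x, ...) x$omnibus

#' @export
glance.es_association <- function(x, ...) {
  tibble::tibble(n_tests = nrow(x$omnibus),
                 n_significant = sum(x$omnibus$p_adj < 0.05, na.rm = TRUE),
                 n_models = nrow(x$flags),
                 n_converged = sum(x$flags$converged))
}

#' Cohen's d with a noncentral-t confidence interval
#'
#' Standardised mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' pooled standard deviation
#' `s_pooled^2 = ((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2)`,
#' and a confidence interval obtained by pivoting the noncentral t
#' distribution of the two-sample t statistic.  Conventional magnitude
#' thresholds: small 0.2, medium 0.5, large 0.8.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `d`, `ci_low`, `ci_high`.
#' @export
cohens_d <- function(x, y, conf_level = 0.95) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 == 0) stop("pooled standard deviation is zero")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  se_unit <- sqrt(1 / nx + 1 / ny)
  t_obs <- d / se_unit
  df <- nx + ny - 2
  alpha <- 1 - conf_level
  ncp_bound <- function(target) {
    # pnt precision warnings in the far tail are immaterial at this tol
    f <- function(ncp) suppressWarnings(pt(t_obs, df, ncp)) - target
    lo <- t_obs - 10 * (1 + abs(t_obs)); hi <- t_obs + 10 * (1 + abs(t_obs))
    while (f(lo) < 0) lo <- lo - 10
    while (f(hi) > 0) hi <- hi + 10
    stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  list(d = d,
       ci_low = ncp_bound(1 - alpha / 2) * se_unit,
       ci_high = ncp_bound(alpha / 2) * se_unit)
}
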