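test_that("TMM factors are unity for identical samples and CLR rows centre", {
  W <- matrix(rep(c(1, 2, 3, 4), each = 6), 6, 4,
              dimnames = list(paste0("s", 1:6), paste0("ES", 1:4)))
  clr <- normalize_loadings(W)
  expect_true(all(abs(attr(clr, "tmm_factors") - 1) < 1e-12))
  expect_lt(max(abs(rowSums(as_abundance_matrix(clr)))), 1e-9)

  # constant composition maps to the CLR origin
  flat <- matrix(1, 4, 4, dimnames = list(paste0("s", 1:4),
                                          paste0("ES", 1:4)))
  clr_flat <- as_abundance_matrix(normalize_loadings(flat))
  expect_lt(max(abs(clr_flat)), 1e-12)
})

test_that("CLR reproduces the closed-form log-ratio example", {
  # row (1, e^2, 1, 1): CLR = (-0.5, 1.5, -0.5, -0.5); a tiny positive
  # entry elsewhere makes the pseudocount negligible
  W <- rbind(c(1, exp(2), 1, 1),
             c(1e-9, 1, 1, 1))
  dimnames(W) <- list(c("s1", "s2"), paste0("ES", 1:4))
  clr <- as_abundance_matrix(normalize_loadings(W))
  expect_equal(unname(clr["s1", ]), c(-0.5, 1.5, -0.5, -0.5),
               tolerance = 1e-4)
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(numeric(0)), "empty")

  withr::local_seed(8)
  p <- runif(20)
  fam <- rep(c("a", "b"), 10)
  adj <- fdr_adjust(p, fam)
  for (f in c("a", "b")) {
    expect_equal(adj[fam == f], bh_by_hand(p[fam == f]))
    # monotone: adjustment never inverts the raw ordering
    expect_true(all(diff(adj[fam == f][order(p[fam == f])]) >= -1e-12))
  }
  expect_true(all(adj >= p - 1e-12))
})

test_that("a vanishing animal variance flags singularity and matches OLS", {
  withr::local_seed(21)
  meta <- simulate_metadata(6, 6, n_drop = 0, seed = 2)
  y <- rnorm(nrow(meta))
  y <- y - ave(y, meta$animal_id)  # animal means exactly zero
  dat <- data.frame(y = y, meta)
  fit <- fit_es_model(dat)
  expect_true(fit$singular)
  ols <- lm(y ~ timepoint * line, data = dat,
            contrasts = list(timepoint = "contr.sum", line = "contr.sum"))
  expect_equal(unname(lme4::fixef(fit$model)), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("marginal means reduce to cell means in a balanced design", {
  withr::local_seed(31)
  meta <- simulate_metadata(5, 5, n_drop = 0, seed = 3)
  dat <- data.frame(y = rnorm(nrow(meta)), meta)
  fit <- fit_es_model(dat)
  mc <- marginal_contrasts(fit$model)
  cell <- aggregate(y ~ line + timepoint, dat, mean)
  merged <- merge(mc$emmeans, cell, by = c("line", "timepoint"))
  expect_equal(merged$emmean, merged$y, tolerance = 1e-6)
})

test_that("a planted within-line temporal shift is recovered by contrast", {
  withr::local_seed(41)
  meta <- simulate_metadata(13, 12, n_drop = 0, seed = 4)
  delta <- 1.5
  shift <- ifelse(meta$line == "TOL" & meta$timepoint == "d14", delta, 0)
  a <- rnorm(25, 0, 0.3); names(a) <- unique(meta$animal_id)
  dat <- data.frame(y = shift + a[meta$animal_id] + rnorm(nrow(meta), 0, 0.3),
                    meta)
  fit <- fit_es_model(dat)
  mc <- marginal_contrasts(fit$model)
  row <- mc$contrasts[mc$contrasts$family == "time_within_line" &
                        mc$contrasts$group == "TOL" &
                        mc$contrasts$contrast == "d4 - d14", ]
  expect_lt(abs(row$estimate - (-delta)), 2 * row$SE)
  expect_lt(row$p_adj, 0.05)
})

test_that("phenotype models recover a planted regression coefficient", {
  withr::local_seed(51)
  meta <- simulate_metadata(13, 12, seed = 5)
  es <- runif(nrow(meta))
  P <- 2 * es + rnorm(nrow(meta), 0, 0.1)
  loadings <- tibble::tibble(sample_id = meta$sample_id, ES1 = es)
  pheno <- tibble::tibble(sample_id = meta$sample_id, trait = P)
  res <- fit_phenotype_models(pheno, loadings, meta)
  beta <- res$omnibus$beta[res$omnibus$effect == "es"][1]
  expect_lt(abs(beta - 2), 0.2)
  expect_lt(res$omnibus$p[res$omnibus$effect == "es"][1], 0.001)

  # a constant response produces no significant effects
  pheno0 <- tibble::tibble(sample_id = meta$sample_id,
                           trait = rep(1, nrow(meta)) + rnorm(nrow(meta), 0, 1e-8))
  res0 <- fit_phenotype_models(pheno0, loadings, meta)
  if (nrow(res0$omnibus) > 0) {
    expect_true(all(res0$omnibus$p_adj > 0.05 | is.na(res0$omnibus$p_adj)))
  }
})

test_that("Cohen's d matches hand arithmetic and brackets the truth", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5))$d, -2)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero")

  # unit-SD construction: means 1 vs 0, both groups SD 1
  x <- scale(rnorm(13))[, 1] + 1
  y <- scale(rnorm(12))[, 1]
  d <- cohens_d(x, y)
  expect_equal(d$d, 1.0, tolerance = 1e-12)
  expect_true(d$ci_low < d$d && d$d < d$ci_high)
})

test_that("full signature association returns coherent omnibus tables", {
  co <- simulate_cohort(n_tol = 6, n_sen = 6, n_features = 80, depth = 1e4,
                        seed = 13)
  fit <- nmf_multirun(tss_normalize(co$mag), 3, n_runs = 3, seed = 2)$best
  assoc <- fit_signature_models(normalize_loadings(fit), co$metadata)
  ok <- assoc$omnibus
  expect_true(all(ok$p_adj >= ok$p - 1e-12))
  expect_true(all(ok$p >= 0 & ok$p <= 1))
  expect_true(all(c("timepoint", "line", "timepoint:line") %in% ok$effect))
  expect_true(all(assoc$effect_sizes$ci_low <= assoc$effect_sizes$d &
                    assoc$effect_sizes$d <= assoc$effect_sizes$ci_high))
})
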