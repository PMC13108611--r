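test_that("metadata generator reproduces the cohort design", {
  meta <- simulate_metadata(13, 12, c("d4", "d8", "d14"), n_drop = 1, seed = 3)
  expect_equal(nrow(meta), 74)
  expect_equal(length(unique(meta$animal_id)), 25)
  # line constant within animal, at most one sample per (animal, timepoint)
  per_animal <- tapply(as.character(meta$line), meta$animal_id,
                       function(x) length(unique(x)))
  expect_true(all(per_animal == 1))
  expect_false(any(duplicated(meta[c("animal_id", "timepoint")])))

  expect_equal(nrow(simulate_metadata(1, 1, "d4", 0, seed = 1)), 2)
  m1 <- simulate_metadata(2, 2, c("d4", "d8"), n_drop = 1, seed = 7)
  m2 <- simulate_metadata(2, 2, c("d4", "d8"), n_drop = 1, seed = 7)
  expect_equal(nrow(m1), 7)
  expect_identical(m1, m2)

  expect_error(simulate_metadata(0, 5), "positive")
  expect_error(simulate_metadata(2, 2, "d4", n_drop = 4), "drop")
})

test_that("planted ground truth satisfies its simplex invariants", {
  meta <- simulate_metadata(seed = 1)
  tr <- plant_signatures(meta, k_true = 4, n_features = 200, seed = 2)
  expect_true(all(tr$W_true >= 0) && all(tr$H_true >= 0))
  expect_lt(max(abs(rowSums(tr$W_true) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(tr$H_true) - 1)), 1e-9)

  # Dirichlet concentration limit: huge alpha gives near-uniform memberships
  tr_flat <- plant_signatures(meta, k_true = 4, n_features = 50,
                              alpha = 1e6, seed = 3)
  expect_lt(max(abs(tr_flat$W_true - 0.25)), 0.01)

  # additive group effect shifts the targeted cell's mean loading
  eff <- tibble::tibble(signature = 1, line = "TOL", timepoint = "d14",
                        shift = 0.5)
  tr_eff <- plant_signatures(meta, k_true = 4, n_features = 50,
                             effects = eff, seed = 4)
  w1 <- tr_eff$W_true[, 1]
  tol_d14 <- meta$line == "TOL" & meta$timepoint == "d14"
  tol_d4 <- meta$line == "TOL" & meta$timepoint == "d4"
  expect_gt(mean(w1[tol_d14]), mean(w1[tol_d4]))
  expect_error(plant_signatures(meta, k_true = 3, n_features = 50,
                                effects = tibble::tibble(
                                  signature = 9, line = "TOL",
                                  timepoint = "d4", shift = 1)),
               "outside")

  # sparsity of the profile mask is the requested Bernoulli fraction
  tr_sp <- plant_signatures(meta, k_true = 4, n_features = 300,
                            h_sparsity = 0.9, seed = 5)
  expect_lt(abs(mean(tr_sp$H_true == 0) - 0.9), 0.05)
})

test_that("count sampling conserves depth and converges to expected proportions", {
  meta <- simulate_metadata(4, 4, c("d4", "d8"), 0, seed = 1)
  tr <- plant_signatures(meta, k_true = 3, n_features = 80, seed = 1)
  counts <- as_abundance_matrix(simulate_counts(tr, depth = 5000, seed = 2))
  expect_true(all(rowSums(counts) == 5000))
  expect_true(all(counts >= 0))

  # law of large numbers at high depth, no overdispersion
  deep <- as_abundance_matrix(simulate_counts(tr, depth = 1e6, seed = 3))
  P <- tr$W_true %*% tr$H_true
  expect_lt(max(abs(deep / 1e6 - P)), 1e-2)

  # a single draw lands on exactly one feature
  one <- as_abundance_matrix(simulate_counts(tr, depth = 1, seed = 4))
  expect_true(all(rowSums(one > 0) == 1))

  # identical seeds give identical tables
  expect_identical(simulate_counts(tr, depth = 1000, seed = 9),
                   simulate_counts(tr, depth = 1000, seed = 9))
})

test_that("KO aggregation sums MAG abundances over the map", {
  mag <- tibble::tibble(sample_id = "s1", M1 = 10)
  map <- tibble::tibble(mag_id = "M1", ko_id = c("K1", "K2"))
  ko <- derive_ko_matrix(mag, map)
  expect_equal(unname(as_abundance_matrix(ko)["s1", c("K1", "K2")]), c(10, 10))

  mag2 <- tibble::tibble(sample_id = "s1", M1 = 3, M2 = 4)
  map2 <- tibble::tibble(mag_id = c("M1", "M2"), ko_id = "K1")
  expect_equal(unname(as_abundance_matrix(derive_ko_matrix(mag2, map2))[1, "K1"]), 7)

  # full functional redundancy: identical KO repertoires collapse to
  # identical KO columns
  mag3 <- tibble::tibble(sample_id = c("a", "b"), M1 = c(1, 5), M2 = c(2, 1))
  map3 <- tidyr::expand_grid(mag_id = c("M1", "M2"), ko_id = c("K1", "K2", "K3"))
  ko3 <- as_abundance_matrix(derive_ko_matrix(mag3, map3))
  expect_true(all(ko3[, "K1"] == ko3[, "K2"]) && all(ko3[, "K1"] == ko3[, "K3"]))

  expect_error(derive_ko_matrix(mag, map[0, ]), "empty")
  expect_error(derive_ko_matrix(mag2, map), "absent")
})

test_that("phenotypes recover their planted linear coupling", {
  meta <- simulate_metadata(seed = 1)
  tr <- plant_signatures(meta, k_true = 4, n_features = 100, seed = 1)
  ph <- simulate_phenotypes(tr, meta, betas = list(p = c(1, 0, 0, 0)),
                            noise_sd = 0.1, seed = 2)
  slope <- coef(lm(ph$p ~ tr$W_true[, 1]))[2]
  expect_lt(abs(slope - 1), 0.15)

  ph0 <- simulate_phenotypes(tr, meta, betas = list(p = rep(0, 4)),
                             noise_sd = 1, seed = 3)
  expect_lt(abs(cor(ph0$p, tr$W_true[, 1])), 0.25)

  expect_error(simulate_phenotypes(tr, meta, betas = list(p = rep(0, 4)),
                                   noise_sd = 0), "positive")
  expect_error(simulate_phenotypes(tr, meta, betas = list(p = 1:2)), "k_true")
})
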