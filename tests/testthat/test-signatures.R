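test_that("enrichment and specificity follow their defining algebra", {
  # an exclusively loaded feature at k = 8 is the printed extreme case
  H <- matrix(0, 8, 3, dimnames = list(paste0("ES", 1:8), c("a", "b", "c")))
  H[1, "a"] <- 0.4
  H[, "b"] <- 0.1          # uniform across all signatures
  H[1:2, "c"] <- c(3, 1) / 10
  sc <- signature_scores(H)
  a1 <- sc[sc$feature_id == "a" & sc$signature == "ES1", ]
  expect_equal(a1$enrichment, 8.000)
  expect_equal(a1$specificity, 1.0)
  expect_true(all(sc$enrichment[sc$feature_id == "b"] == 1.0))

  # k = 4, loadings (3, 1, 0, 0)
  H4 <- matrix(c(3, 1, 0, 0), 4, 1,
               dimnames = list(paste0("ES", 1:4), "x"))
  s4 <- signature_scores(H4)
  expect_equal(s4$specificity, c(0.75, 0.25, 0, 0))
  expect_equal(s4$enrichment, c(3, 1, 0, 0))

  # invariants on a random H: enrichment = k * specificity, specificity
  # sums to one per feature, enrichment invariant to global rescaling
  withr::local_seed(2)
  Hr <- matrix(rgamma(5 * 40, 1), 5, 40,
               dimnames = list(paste0("ES", 1:5), paste0("f", 1:40)))
  sr <- signature_scores(Hr)
  expect_equal(sr$enrichment, 5 * sr$specificity)
  sums <- tapply(sr$specificity, sr$feature_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  sr2 <- signature_scores(Hr * 37.5)
  expect_equal(sr$enrichment, sr2$enrichment)
})

test_that("feature ranking switches mode on enrichment variability", {
  # equal enrichment everywhere: CV = 0, z-score mode
  H <- matrix(rep(c(5, 4, 3, 2, 1), each = 2), 2, 5, byrow = FALSE)
  H <- rbind(H[1, ], H[1, ])
  dimnames(H) <- list(c("ES1", "ES2"), paste0("f", 1:5))
  ranked <- suppressWarnings(rank_features(signature_scores(H), top_n = 3))
  expect_true(all(ranked$rank_mode == "zscore"))
  # monotone loadings: top set is the same under either mode
  expect_equal(sort(ranked$feature_id[ranked$signature == "ES1"]),
               c("f1", "f2", "f3"))

  # highly variable enrichment: fold-enrichment mode
  H2 <- matrix(c(8, 0.1, 0.1, 0.1,
                 0.1, 8, 0.1, 0.1), 2, 4, byrow = TRUE,
               dimnames = list(c("ES1", "ES2"), paste0("f", 1:4)))
  r2 <- suppressWarnings(rank_features(signature_scores(H2), top_n = 2))
  expect_true(all(r2$rank_mode == "fold_enrichment"))
  expect_equal(r2$feature_id[r2$signature == "ES1" & r2$rank == 1], "f1")

  # short signatures warn rather than fail
  expect_warning(rank_features(signature_scores(H2), top_n = 30), "features")
})

test_that("dominant-signature assignment is an argmax with flagged ties", {
  W <- matrix(c(0.1, 0.7, 0.2), 1, dimnames = list("s1", paste0("ES", 1:3)))
  lab <- dominant_signature(W)
  expect_equal(lab$signature, "ES2")
  expect_false(lab$tie)

  Wt <- matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("ES1", "ES2")))
  labt <- dominant_signature(Wt)
  expect_equal(labt$signature, "ES1")
  expect_true(labt$tie)

  withr::local_seed(4)
  Wr <- matrix(rgamma(30, 1), 10, 3,
               dimnames = list(paste0("s", 1:10), paste0("ES", 1:3)))
  scales <- runif(10, 0.1, 10)
  expect_equal(dominant_signature(Wr)$signature,
               dominant_signature(sweep(Wr, 1, scales, `*`))$signature)
  expect_error(dominant_signature(Wr * 0), "all-zero")
})

test_that("group composition percentages close to 100", {
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:12), animal_id = paste0("a", 1:12),
    line = factor(rep("SEN", 12)), timepoint = factor(rep("d4", 12))
  )
  labels <- tibble::tibble(sample_id = meta$sample_id,
                           signature = c(rep("ES3", 4), rep("ES7", 4),
                                         rep("ES8", 2), "ES5", "ES6"),
                           tie = FALSE)
  comp <- composition_by_group(labels, meta)
  expect_equal(comp$percent[comp$signature == "ES3"], 100 * 4 / 12,
               tolerance = 1e-9)  # the 33.3% cell
  expect_equal(sum(comp$percent), 100, tolerance = 1e-9)

  single <- composition_by_group(labels[1, ], meta[1, ])
  expect_equal(single$percent, 100)
})

test_that("loading diversity matches closed-form Shannon values", {
  W <- rbind(uniform = rep(1 / 8, 8),
             point = c(1, rep(0, 7)),
             half = c(0.5, 0.5, rep(0, 6)))
  colnames(W) <- paste0("ES", 1:8)
  div <- loading_diversity(W)
  expect_equal(div$shannon[1], log(8), tolerance = 1e-12)
  expect_equal(div$evenness[1], 1, tolerance = 1e-12)
  expect_equal(div$shannon[2], 0)
  expect_equal(div$evenness[2], 0)
  expect_equal(div$shannon[3], log(2), tolerance = 1e-12)
  expect_true(all(div$shannon >= 0 & div$shannon <= log(8) + 1e-12))
})
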