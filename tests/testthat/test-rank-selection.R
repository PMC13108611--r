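toy_metrics <- tibble::tibble(
  rank = c(2, 3, 4),
  cophenetic = c(0.99, 0.90, 0.80),
  silhouette = c(0.9, 0.5, 0.4),
  dispersion = c(0.95, 0.94, 0.5),
  evar = c(0.7, 0.9, 0.91),
  rss = c(30, 11, 10)
)

# brute-force acceptability: direct evaluation of both rules
brute_votes <- function(metrics, tolerance) {
  vote <- setNames(rep(0, nrow(metrics)), metrics$rank)
  for (m in c("cophenetic", "silhouette", "dispersion", "evar")) {
    acc <- metrics[[m]] >= (1 - tolerance) * max(metrics[[m]])
    vote[acc] <- vote[acc] + 1
  }
  acc <- metrics$rss <= (1 + tolerance) * min(metrics$rss)
  vote[acc] <- vote[acc] + 1
  vote
}

test_that("tolerance voting matches brute-force enumeration on the toy table", {
  sel <- select_rank(toy_metrics, tolerance = 0.10)
  votes <- brute_votes(toy_metrics, 0.10)
  expect_equal(setNames(sel$votes$votes, sel$votes$rank), votes)
  expect_equal(sel$chosen_k,
               as.numeric(names(votes)[max(which(votes == max(votes)))]))
  expect_equal(sel$chosen_k, 3)
  # every acceptable set contains that metric's own optimum
  expect_true(2 %in% sel$acceptable$cophenetic)
  expect_true(4 %in% sel$acceptable$rss)
})

test_that("a unanimous optimum wins with five votes and ties go high", {
  unan <- tibble::tibble(rank = 2:4,
                         cophenetic = c(0.5, 0.99, 0.5),
                         silhouette = c(0.3, 0.9, 0.3),
                         dispersion = c(0.4, 0.95, 0.4),
                         evar = c(0.5, 0.95, 0.5),
                         rss = c(30, 10, 30))
  sel <- select_rank(unan, 0.10)
  expect_equal(sel$chosen_k, 3)
  expect_equal(max(sel$votes$votes), 5)

  tied <- tibble::tibble(rank = c(7, 8),
                         cophenetic = c(0.99, 0.99),
                         silhouette = c(0.9, 0.9),
                         dispersion = c(0.95, 0.95),
                         evar = c(0.9, 0.9),
                         rss = c(10, 10))
  expect_equal(select_rank(tied, 0.10)$chosen_k, 8)
  expect_equal(select_rank(tied, 0.10, prefer_higher = FALSE)$chosen_k, 7)
})

test_that("widening tolerance never shrinks acceptable sets", {
  withr::local_seed(7)
  for (rep in 1:10) {
    met <- tibble::tibble(rank = 2:6,
                          cophenetic = runif(5), silhouette = runif(5, -0.2, 1),
                          dispersion = runif(5), evar = runif(5),
                          rss = rgamma(5, 2))
    s1 <- select_rank(met, 0.05)
    s2 <- select_rank(met, 0.25)
    for (m in names(s1$acceptable)) {
      expect_true(all(s1$acceptable[[m]] %in% s2$acceptable[[m]]))
    }
    # chosen rank always has a maximal vote count
    expect_equal(s1$votes$votes[s1$votes$rank == s1$chosen_k],
                 max(s1$votes$votes))
  }
})

test_that("vanishing tolerance accepts only each metric's optimum", {
  sel <- select_rank(toy_metrics, tolerance = 1e-9)
  expect_equal(sel$acceptable$cophenetic, 2)
  expect_equal(sel$acceptable$silhouette, 2)
  expect_equal(sel$acceptable$dispersion, 2)
  expect_equal(sel$acceptable$evar, 4)
  expect_equal(sel$acceptable$rss, 4)
})

test_that("missing metric values abstain instead of failing", {
  met <- toy_metrics
  met$silhouette[2] <- NA
  sel <- select_rank(met, 0.10)
  expect_false(3 %in% sel$acceptable$silhouette)
  expect_true(all(sel$votes$votes <= 5))
})
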