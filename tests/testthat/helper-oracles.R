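# Independent oracles used across test files.

# exhaustive assignment maximiser: tries every permutation (k <= 8)
brute_force_assignment <- function(score) {
  n <- nrow(score)
  perms <- gtools_permutations(n)
  best <- -Inf; best_perm <- NULL
  for (i in seq_len(nrow(perms))) {
    tot <- sum(score[cbind(seq_len(n), perms[i, ])])
    if (tot > best) { best <- tot; best_perm <- perms[i, ] }
  }
  list(total = best, assignment = best_perm)
}

# all permutations of 1..n without external packages
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# hand-rolled Benjamini-Hochberg step-up
bh_by_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# a noiseless block-structured abundance table: k disjoint feature blocks,
# samples concentrated on one block each with mild mixing
block_matrix <- function(n_per_block = 18, k = 4, feats_per_block = 60,
                         mix = 0.05, seed = 1) {
  withr::local_seed(seed)
  n <- n_per_block * k
  m <- feats_per_block * k
  H <- matrix(0, k, m)
  for (s in seq_len(k)) {
    cols <- ((s - 1) * feats_per_block + 1):(s * feats_per_block)
    H[s, cols] <- rlnorm(feats_per_block)
  }
  H <- H / rowSums(H)
  W <- matrix(mix / (k - 1), n, k)
  for (s in seq_len(k)) {
    W[((s - 1) * n_per_block + 1):(s * n_per_block), s] <- 1 - mix
  }
  V <- W %*% H
  rownames(V) <- sprintf("s%03d", seq_len(n))
  colnames(V) <- sprintf("f%03d", seq_len(m))
  list(V = as_abundance_tibble(V), W = W, H = H)
}

# metadata for simulation-based model tests
null_model_data <- function(n_tol = 13, n_sen = 12, sd_animal = 1,
                            sd_resid = 1) {
  meta <- simulate_metadata(n_tol, n_sen, n_drop = 0, seed = 1)
  a <- rnorm(n_tol + n_sen, 0, sd_animal)
  names(a) <- unique(meta$animal_id)
  data.frame(y = a[meta$animal_id] + rnorm(nrow(meta), 0, sd_resid), meta)
}
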