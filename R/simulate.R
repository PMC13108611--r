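#' Simulate a longitudinal cohort design
#'
#' Builds the sample metadata for a two-line, repeated-measures design:
#' `n_tol` heat-tolerant and `n_sen` heat-sensitive animals, each sampled
#' once per timepoint, with `n_drop` samples removed uniformly at random
#' (emulating sequencing failures).  Defaults reproduce the study design
#' this package targets: 13 + 12 sows over lactation days 4, 8 and 14,
#' with one of the 75 samples discarded, leaving 74.
#'
#' @param n_tol,n_sen Number of animals in the TOL and SEN lines.
#' @param timepoints Character vector of timepoint labels (kept in order).
#' @param n_drop Number of samples to drop uniformly at random.
#' @param seed Integer seed; identical seeds reproduce identical tables.
#' @return A tibble with columns `sample_id`, `animal_id`, `line`
#'   (factor TOL/SEN) and `timepoint` (factor in the given order).
#' @examples
#' meta <- simulate_metadata(seed = 1)
#' nrow(meta)  # 74
#' @export
simulate_metadata <- function(n_tol = 13, n_sen = 12,
                              timepoints = c("d4", "d8", "d14"),
                              n_drop = 1, seed = 12345) {
  if (n_tol < 1 || n_sen < 1) stop("animal counts must be positive")
  n_animals <- n_tol + n_sen
  if (n_drop >= n_animals * length(timepoints)) {
    stop("cannot drop ", n_drop, " of ", n_animals * length(timepoints), " samples")
  }
  animals <- c(sprintf("TOL%02d", seq_len(n_tol)),
               sprintf("SEN%02d", seq_len(n_sen)))
  lines <- rep(c("TOL", "SEN"), c(n_tol, n_sen))
  meta <- tidyr::expand_grid(
    animal_id = animals,
    timepoint = factor(timepoints, levels = timepoints)
  )
  meta <- dplyr::mutate(
    meta,
    line = factor(lines[match(.data$animal_id, animals)], levels = c("TOL", "SEN")),
    sample_id = paste0(.data$animal_id, "_", .data$timepoint)
  )
  if (n_drop > 0) {
    withr::local_seed(seed)
    drop_idx <- sample(nrow(meta), n_drop)
    meta <- meta[-drop_idx, ]
  }
  dplyr::select(meta, "sample_id", "animal_id", "line", "timepoint")
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Plant latent subcommunity structure
#'
#' Generates the ground truth a factorisation is meant to recover: a
#' mixed-membership loading matrix `W_true` (one simplex row per sample,
#' symmetric Dirichlet) and sparse non-negative signature profiles
#' `H_true` (rows renormalised to sum 1).  Group effects are injected
#' additively on the simplex and renormalised, so loadings stay
#' interpretable as mixed membership.
#'
#' @param metadata Cohort metadata from [simulate_metadata()].
#' @param k_true Number of planted subcommunities (>= 2).
#' @param n_features Number of features (MAG columns) in the profiles.
#' @param alpha Symmetric Dirichlet concentration for sample memberships;
#'   small values (default 0.3) give samples dominated by one signature,
#'   as observed in real gut communities.
#' @param h_sparsity Expected fraction of exact zeros in each signature
#'   profile before renormalisation.  Nonzero magnitudes are log-normal
#'   with `sdlog = 2.5`, emulating heavy-tailed taxon loadings; together
#'   with the default sparsity this reproduces the ~38% zero fraction
#'   typical of strain-resolved MAG count tables at the default
#'   sequencing depth.
#' @param effects Optional tibble with columns `signature`, `line`,
#'   `timepoint`, `shift`: the additive loading shift applied to matching
#'   samples before renormalisation.
#' @param feature_prefix Prefix for generated feature IDs.
#' @param seed Integer seed.
#' @return An object of class `es_truth`: list with `W_true`, `H_true`
#'   (matrices), `k_true`, `metadata`, `effects`, `seed`.
#' @export
plant_signatures <- function(metadata, k_true = 4, n_features = 300,
                             alpha = 0.3, h_sparsity = 0.7, effects = NULL,
                             feature_prefix = "MAG", seed = 12345) {
  stopifnot(k_true >= 2, n_features >= k_true)
  if (alpha <= 0) stop("alpha must be positive")
  if (h_sparsity < 0 || h_sparsity >= 1) stop("h_sparsity must be in [0, 1)")
  if (!is.null(effects)) {
    stopifnot(all(c("signature", "line", "timepoint", "shift") %in% names(effects)))
    if (any(effects$signature < 1 | effects$signature > k_true)) {
      stop("effects reference a signature outside 1..k_true")
    }
  }
  n <- nrow(metadata)
  withr::local_seed(seed)

  W <- rdirichlet(n, rep(alpha, k_true))
  if (!is.null(effects) && nrow(effects) > 0) {
    for (r in seq_len(nrow(effects))) {
      hit <- metadata$line == effects$line[r] &
        metadata$timepoint == effects$timepoint[r]
      W[hit, effects$signature[r]] <- W[hit, effects$signature[r]] + effects$shift[r]
    }
    W[W < 0] <- 0
    W <- W / rowSums(W)
  }
  rownames(W) <- metadata$sample_id
  colnames(W) <- paste0("ES", seq_len(k_true))

  # Sparse signature profiles; a feature carried by no signature simply
  # never occurs (filtered later), but every signature keeps >= 1 feature
  mask <- matrix(rbinom(k_true * n_features, 1, 1 - h_sparsity),
                 nrow = k_true)
  empty_rows <- which(rowSums(mask) == 0)
  if (length(empty_rows) > 0) {
    mask[cbind(empty_rows,
               sample(n_features, length(empty_rows), replace = TRUE))] <- 1
  }
  H <- mask * matrix(rlnorm(k_true * n_features, meanlog = 0, sdlog = 2.5),
                     nrow = k_true)
  H <- H / rowSums(H)
  rownames(H) <- colnames(W)
  colnames(H) <- sprintf("%s%04d", feature_prefix, seq_len(n_features))

  structure(list(W_true = W, H_true = H, k_true = k_true,
                 metadata = metadata, effects = effects, seed = seed),
            class = "es_truth")
}

#' @exportS3Method base::print
print.es_truth <- function(x, ...) {
  cat("Planted ground truth: ", nrow(x$W_true), " samples x ",
      ncol(x$H_true), " features, k_true = ", x$k_true, "\n", sep = "")
  invisible(x)
}

#' Draw sequencing-like counts from planted structure
#'
#' Per sample, counts are multinomial with `depth` trials and cell
#' probabilities given by the sample's row of `W_true %*% H_true`.  With
#' `overdispersion > 0` the probabilities are first perturbed by a
#' Dirichlet draw with concentration `p / overdispersion`
#' (Dirichlet-multinomial noise, the standard overdispersed count model
#' for metagenomic data); `overdispersion = 0` is plain multinomial.
#'
#' @param truth An `es_truth` object from [plant_signatures()].
#' @param depth Sequencing depth per sample (row sums equal this exactly).
#' @param overdispersion Non-negative dispersion; 0 disables.
#' @param seed Integer seed.
#' @return Abundance tibble (`sample_id` + feature columns) of counts.
#' @export
simulate_counts <- function(truth, depth = 1e5, overdispersion = 0,
                            seed = 12345) {
  stopifnot(inherits(truth, "es_truth"), depth >= 1, overdispersion >= 0)
  P <- truth$W_true %*% truth$H_true
  if (any(abs(rowSums(P) - 1) > 1e-6)) {
    stop("rows of W_true %*% H_true must sum to 1")
  }
  withr::local_seed(seed)
  counts <- t(apply(P, 1, function(p) {
    if (overdispersion > 0) {
      p <- as.numeric(rdirichlet(1, pmax(p, 1e-12) / overdispersion))
    }
    rmultinom(1, size = depth, prob = p)[, 1]
  }))
  dimnames(counts) <- dimnames(P)
  as_abundance_tibble(counts)
}

#' Generate a MAG-to-KO map with guild structure
#'
#' Emulates functional redundancy: MAGs are grouped into guilds, all MAGs
#' carry a shared core block of KOs, and each guild additionally carries
#' its own KO block.  A per-MAG dropout rate introduces accessory-genome
#' variation.
#'
#' @param mag_ids Character vector of MAG feature IDs.
#' @param n_ko Total number of KO identifiers.
#' @param n_guilds Number of guilds sharing KO blocks.
#' @param core_fraction Fraction of KOs carried by every MAG.
#' @param dropout Per-(MAG, KO) probability that a carried KO is missing.
#' @param seed Integer seed.
#' @return Tibble with columns `mag_id`, `ko_id` (one row per association).
#' @export
simulate_ko_map <- function(mag_ids, n_ko = 1200, n_guilds = 8,
                            core_fraction = 0.3, dropout = 0.1,
                            seed = 12345) {
  stopifnot(length(mag_ids) > 0, n_ko >= n_guilds + 1)
  withr::local_seed(seed)
  kos <- sprintf("K%05d", seq_len(n_ko))
  n_core <- max(1, round(core_fraction * n_ko))
  core <- kos[seq_len(n_core)]
  blocks <- split(kos[-seq_len(n_core)],
                  rep_len(seq_len(n_guilds), n_ko - n_core))
  guild <- rep_len(seq_len(n_guilds), length(mag_ids))
  map <- purrr::map2_dfr(mag_ids, guild, function(mag, g) {
    carried <- c(core, blocks[[g]])
    carried <- carried[runif(length(carried)) >= dropout]
    tibble::tibble(mag_id = mag, ko_id = carried)
  })
  map
}

#' Aggregate a MAG abundance table into a KO abundance table
#'
#' The abundance of a KO in a sample is the sum of the abundances of all
#' MAGs carrying that KO (gene-level annotations weighted by the
#' abundance of their genome of origin).
#'
#' @param mag_tbl MAG abundance tibble (`sample_id` + MAG columns).
#' @param ko_map Tibble with columns `mag_id`, `ko_id`; every MAG column
#'   of `mag_tbl` must appear.
#' @return KO abundance tibble; columns are the sorted union of mapped KOs.
#' @export
derive_ko_matrix <- function(mag_tbl, ko_map) {
  if (is.null(ko_map) || nrow(ko_map) == 0) stop("empty MAG-to-KO map")
  V <- as_abundance_matrix(mag_tbl)
  missing <- setdiff(colnames(V), unique(ko_map$mag_id))
  if (length(missing) > 0) {
    stop("MAGs absent from the map: ", paste(head(missing, 5), collapse = ", "))
  }
  ko_map <- ko_map[ko_map$mag_id %in% colnames(V), ]
  kos <- sort(unique(ko_map$ko_id))
  M <- Matrix::sparseMatrix(
    i = match(ko_map$mag_id, colnames(V)),
    j = match(ko_map$ko_id, kos),
    x = 1,
    dims = c(ncol(V), length(kos)),
    dimnames = list(colnames(V), kos)
  )
  out <- as.matrix(V %*% M)
  as_abundance_tibble(out)
}

#' Simulate phenotypes linearly coupled to signature loadings
#'
#' Each phenotype is an intercept plus a linear combination of the
#' planted loadings, optional line/timepoint offsets, and Gaussian noise:
#' `P = mu + W_true %*% beta + offsets + N(0, noise_sd)`.
#'
#' @param truth An `es_truth` object.
#' @param metadata Cohort metadata (defaults to the truth's own).
#' @param betas Named list: one numeric vector of length `k_true` per
#'   phenotype (regression coefficient of each signature loading).
#' @param mu Named numeric vector of phenotype intercepts (default 0).
#' @param line_offsets,time_offsets Optional named lists giving, per
#'   phenotype, a named numeric vector of additive offsets by line level
#'   or timepoint level.
#' @param noise_sd Residual standard deviation (> 0, or exactly 0 for a
#'   noiseless check is not allowed; use a tiny value instead).
#' @param seed Integer seed.
#' @return Tibble with `sample_id` plus one numeric column per phenotype.
#' @export
simulate_phenotypes <- function(truth, metadata = truth$metadata,
                                betas,
                                mu = NULL,
                                line_offsets = NULL, time_offsets = NULL,
                                noise_sd = 0.5, seed = 12345) {
  stopifnot(inherits(truth, "es_truth"))
  if (noise_sd <= 0) stop("noise_sd must be positive")
  bad <- vapply(betas, function(b) length(b) != truth$k_true, logical(1))
  if (any(bad)) stop("each beta vector must have length k_true")
  W <- truth$W_true[metadata$sample_id, , drop = FALSE]
  withr::local_seed(seed)
  out <- tibble::tibble(sample_id = metadata$sample_id)
  for (ph in names(betas)) {
    y <- as.numeric(W %*% betas[[ph]])
    y <- y + if (!is.null(mu) && ph %in% names(mu)) mu[[ph]] else 0
    if (!is.null(line_offsets[[ph]])) {
      y <- y + line_offsets[[ph]][as.character(metadata$line)]
    }
    if (!is.null(time_offsets[[ph]])) {
      y <- y + time_offsets[[ph]][as.character(metadata$timepoint)]
    }
    out[[ph]] <- y + rnorm(nrow(W), 0, noise_sd)
  }
  out
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [simulate_metadata()],
#' [plant_signatures()], [simulate_counts()], [simulate_ko_map()] /
#' [derive_ko_matrix()] and [simulate_phenotypes()] with a single seed.
#'
#' @param k_true,n_features,alpha,h_sparsity,effects,depth,overdispersion
#'   Passed through to the component generators.
#' @param n_tol,n_sen,timepoints,n_drop Cohort design parameters.
#' @param betas,noise_sd Phenotype coupling; defaults couple one phenotype
#'   per signature with unit coefficient.
#' @param with_ko Also derive a KO abundance table through a guild map.
#' @param seed Integer master seed; component seeds are small fixed
#'   offsets of it.
#' @return List with `metadata`, `truth`, `mag` (counts tibble),
#'   optionally `ko_map` and `ko`, and `phenotypes`.
#' @export
simulate_cohort <- function(k_true = 4, n_features = 300, alpha = 0.3,
                            h_sparsity = 0.7, effects = NULL,
                            depth = 1e5, overdispersion = 0,
                            n_tol = 13, n_sen = 12,
                            timepoints = c("d4", "d8", "d14"), n_drop = 1,
                            betas = NULL, noise_sd = 0.5,
                            with_ko = FALSE, seed = 12345) {
  meta <- simulate_metadata(n_tol, n_sen, timepoints, n_drop, seed = seed)
  truth <- plant_signatures(meta, k_true, n_features, alpha, h_sparsity,
                            effects, seed = seed + 1)
  mag <- simulate_counts(truth, depth, overdispersion, seed = seed + 2)
  if (is.null(betas)) {
    betas <- setNames(
      lapply(seq_len(k_true), function(j) {
        b <- numeric(k_true); b[j] <- 1; b
      }),
      paste0("pheno_", seq_len(k_true))
    )
  }
  pheno <- simulate_phenotypes(truth, meta, betas, noise_sd = noise_sd,
                               seed = seed + 3)
  out <- list(metadata = meta, truth = truth, mag = mag, phenotypes = pheno)
  if (with_ko) {
    out$ko_map <- simulate_ko_map(colnames(truth$H_true), seed = seed + 4)
    out$ko <- derive_ko_matrix(mag, out$ko_map)
  }
  out
}
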