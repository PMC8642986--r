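# Independent oracles and fixture generators used across the test files.
# Everything here deliberately avoids the package's own computation paths.

# random ungapped sequences as single strings
random_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# independent high-precision K2P evaluation: transition/transversion
# proportions counted via pair-string lookup, then the closed form
oracle_k2p <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  valid <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  pair <- paste0(va[valid], vb[valid])
  n <- length(pair)
  ts_pairs <- c("AG", "GA", "CT", "TC")
  tv_pairs <- c("AC", "CA", "AT", "TA", "GC", "CG", "GT", "TG")
  P <- sum(pair %in% ts_pairs) / n
  Q <- sum(pair %in% tv_pairs) / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(Inf)
  -0.5 * log1p(-(2 * P + Q)) - 0.25 * log1p(-2 * Q)
}

# random additive distance matrix from a random tree with positive branch
# lengths; returns list(tree, matrix)
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 1)
  list(tree = tr, d = stats::cophenetic(tr))
}

# build a k2p_dist object directly from a symmetric matrix (for tests of
# logic that sits on top of distances, independent of K2P itself)
as_k2p_dist <- function(d) {
  structure(list(ids = rownames(d), d = d,
                 overlap = matrix(1000L, nrow(d), ncol(d),
                                  dimnames = dimnames(d))),
            class = "k2p_dist")
}

# metadata table for a plain vector of species labels
meta_for <- function(ids, species, population = "P1") {
  tibble::tibble(specimen_id = ids, species = species,
                 group = "true_mangrove", site_id = population,
                 population_id = population)
}

# exhaustive-enumeration barcode-gap oracle: per-species max intra and min
# inter by explicit loops over all pairs
oracle_gap <- function(d, species) {
  ids <- rownames(d)
  out <- lapply(sort(unique(species)), function(s) {
    own <- which(species == s)
    other <- which(species != s)
    intra <- c()
    for (i in own) for (j in own) if (i < j) intra <- c(intra, d[i, j])
    inter <- c()
    for (i in own) for (j in other) inter <- c(inter, d[i, j])
    data.frame(species = s,
               max_intra = if (length(intra)) max(intra) else NA_real_,
               min_inter = if (length(inter)) min(inter) else NA_real_)
  })
  do.call(rbind, out)
}

# exhaustive signed-rank p-value: full 2^N enumeration of sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# small single-marker community simulation used by several property tests
tiny_sim <- function(seed, n_species = 6, theta = 0.003, depth = 0.3,
                     n_ind = 2, L = 300L, rate = 1) {
  cfg <- sim_config(
    n_species = n_species,
    markers = tibble::tibble(marker = "m1", length = L, rate = rate,
                             kappa = 2, gc = 0.5, indel_events = 0L,
                             recovery = 1, genome = "nuclear"),
    tree_depth = depth, n_populations = 1L,
    individuals_per_population = n_ind, theta = theta,
    between_population_divergence = 0, n_hybrids = 0L,
    nuclear_marker = "m1")
  simulate_community(cfg, seed = seed)
}
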