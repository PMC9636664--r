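# Independent brute-force oracles and fixture builders. The oracles use
# plain double loops and never call the package code paths they check.

# Random valid tad_set via the generator (validated on construction).
random_tad_set <- function(seed, n_bins = 100L, min_size = 3L, max_size = 12L,
                           gap_prob = 0.3, gap_max = 4L, label = paste0("r", seed)) {
  generate_partition(
    synthetic_spec(n_bins = n_bins, min_size = min_size, max_size = max_size,
                   gap_prob = gap_prob, gap_max = gap_max, seed = seed),
    label = label
  )
}

# Exhaustive all-pairs boundary matching.
oracle_shared_boundaries <- function(a, b, tol) {
  n <- 0L
  for (x in a) {
    hit <- FALSE
    for (y in b) if (abs(x - y) <= tol) hit <- TRUE
    if (hit) n <- n + 1L
  }
  n
}

# Exhaustive all-pairs domain matching (both ends within tolerance).
oracle_shared_domains <- function(a, b, tol) {
  da <- a$domains
  db <- b$domains
  n <- 0L
  for (i in seq_len(nrow(da))) {
    hit <- FALSE
    for (j in seq_len(nrow(db))) {
      if (abs(da$start_bin[i] - db$start_bin[j]) <= tol &&
          abs(da$end_bin[i] - db$end_bin[j]) <= tol) hit <- TRUE
    }
    if (hit) n <- n + 1L
  }
  n
}

# Brute-force MoC: explicit double loop over domain pairs.
oracle_moc <- function(a, b) {
  da <- a$domains
  db <- b$domains
  na <- nrow(da)
  nb <- nrow(db)
  if (na == 1L && nb == 1L) return(1)
  s <- 0
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      ov <- max(0, min(da$end_bin[i], db$end_bin[j]) -
                   max(da$start_bin[i], db$start_bin[j]))
      s <- s + ov^2 / ((da$end_bin[i] - da$start_bin[i]) *
                         (db$end_bin[j] - db$start_bin[j]))
    }
  }
  (s - 1) / (sqrt(na * nb) - 1)
}

# Two-family design used by the clustering-recovery checks: n_rep perturbed
# replicates of each of two independently generated base partitions.
two_family_sets <- function(seed, n_bins = 200L, n_rep = 5L, magnitude = 2L) {
  base1 <- generate_partition(
    synthetic_spec(n_bins = n_bins, min_size = 5L, max_size = 25L,
                   gap_prob = 0, seed = seed), label = "f1")
  base2 <- generate_partition(
    synthetic_spec(n_bins = n_bins, min_size = 5L, max_size = 25L,
                   gap_prob = 0, seed = seed + 100000L), label = "f2")
  sets <- list()
  for (r in seq_len(n_rep)) {
    s1 <- jitter_tads(base1, magnitude, seed = seed + r)
    s1$label <- paste0("f1_", r)
    s2 <- jitter_tads(base2, magnitude, seed = seed + 1000L + r)
    s2$label <- paste0("f2_", r)
    sets <- c(sets, list(s1, s2))
  }
  list(sets = sets, truth = rep(c(1L, 2L), n_rep))
}

# Rate of correct family recovery by k-means(2) on a 2D embedding,
# measured with the adjusted Rand index.
embedding_ari <- function(emb, truth) {
  km <- withr::with_seed(1L, stats::kmeans(cbind(emb$x, emb$y), centers = 2L, nstart = 10L))
  mclust::adjustedRandIndex(km$cluster, truth)
}
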