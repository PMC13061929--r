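# shared fixtures and independent oracles used across test files

# adjusted Rand-free simple Rand index: fraction of sample pairs on which two
# partitions agree (same/different cluster)
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# direct two-distribution JSD evaluation, independent of jsd_matrix
jsd_direct <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    t <- a * log2(a / b)
    sum(t[a > 0])
  }
  sqrt(kl(p, m) / 2 + kl(q, m) / 2)
}

# exhaustive PAM oracle: minimum objective over all C(n, k) medoid subsets
brute_pam_objective <- function(d, k) {
  n <- nrow(d)
  subsets <- utils::combn(n, k)
  best <- Inf
  for (s in seq_len(ncol(subsets))) {
    obj <- sum(apply(d[, subsets[, s], drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

# pair-counting AUC oracle: concordant pairs + half ties
brute_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# small planted-cluster cohort, filtered and closed, for typing tests
planted_cohort <- function(seed, n = 150, k = 3, n_genera = 20,
                           concentration = 150) {
  cfg <- cohort_config(n_samples = n, n_genera = n_genera, n_rare = 5,
                       k_clusters = k,
                       cluster_weights = rep(1 / k, k),
                       concentration = concentration,
                       covariate_effects = list(), seed = seed)
  co <- generate_cohort(cfg)
  rel <- to_relative(filter_by_detection_rate(co$abundance)$table)
  list(rel = rel, labels = co$true_labels, config = cfg)
}

# archetypes in which only the first two genera differ between clusters
signal_archetypes <- function(k = 3, p = 10) {
  sig <- rbind(c(0.30, 0.05), c(0.05, 0.30), c(0.175, 0.175))[seq_len(k), ]
  rest <- matrix((1 - rowSums(sig)) / (p - 2), k, p - 2)
  arch <- cbind(sig, rest)
  colnames(arch) <- paste0("G", seq_len(p))
  arch / rowSums(arch)
}

# graph of two 4-cliques joined by a single bridge edge
two_clique_edges <- function() {
  cl1 <- t(utils::combn(1:4, 2))
  cl2 <- t(utils::combn(5:8, 2))
  rbind(cl1, cl2, c(4, 5))
}
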