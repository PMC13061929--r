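test_that("Jensen-Shannon distances match direct evaluation and its bounds", {
  tab <- abundance_table(rbind(a = c(0.5, 0.5), b = c(0.9, 0.1),
                               c = c(1, 0), d = c(0, 1), e = c(0.5, 0.5)),
                         kind = "relative")
  D <- jsd_matrix(tab)$d
  expect_equal(D["a", "e"], 0)
  expect_equal(D["c", "d"], 1)                       # disjoint support, base 2
  expect_equal(D["a", "b"], jsd_direct(c(0.5, 0.5), c(0.9, 0.1)),
               tolerance = 1e-12)
  expect_error(jsd_matrix(abundance_table(rbind(c(2, 2)))), "relative")
})

test_that("JSD is a metric on random compositions", {
  set.seed(7)
  x <- matrix(rgamma(30 * 6, 0.8), 30, 6)
  x <- x / rowSums(x)
  D <- jsd_matrix(abundance_table(x, kind = "relative"))$d
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 30))
  expect_true(all(D >= 0 & D <= 1))
  for (r in 1:200) {
    ijk <- sample(30, 3)
    expect_lte(D[ijk[1], ijk[2]],
               D[ijk[1], ijk[3]] + D[ijk[3], ijk[2]] + 1e-9)
  }
})

test_that("PAM separates zero-distance groups exactly", {
  d <- matrix(1, 6, 6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0
  res <- pam_cluster(d, 2)
  expect_equal(res$objective, 0)
  expect_equal(length(unique(res$labels[1:3])), 1)
  expect_equal(length(unique(res$labels[4:6])), 1)
  expect_false(res$labels[1] == res$labels[4])
})

test_that("PAM attains the exhaustive optimum for n <= 8", {
  set.seed(11)
  for (n in 5:8) {
    for (k in 2:3) {
      pts <- matrix(runif(n * 2), n, 2)
      d <- as.matrix(dist(pts))
      res <- pam_cluster(d, k)
      expect_equal(res$objective, brute_pam_objective(d, k), tolerance = 1e-12)
      # labels consistent: every sample at its nearest medoid
      dm <- d[, res$medoid_indices, drop = FALSE]
      expect_equal(res$labels, unname(apply(dm, 1, which.min)))
      # medoids labeled as their own cluster
      expect_equal(res$labels[res$medoid_indices], seq_len(k))
    }
    # k = n - 1 leaves one non-medoid at its nearest neighbour
    d <- as.matrix(dist(matrix(runif(n * 2), n, 2)))
    res <- pam_cluster(d, n - 1)
    expect_equal(res$objective, brute_pam_objective(d, n - 1),
                 tolerance = 1e-12)
  }
  expect_error(pam_cluster(matrix(0, 3, 3), 3), "k must be <")
  expect_error(pam_cluster(matrix(c(0, NA, NA, 0), 2, 2), 2), "non-finite|k must")
})

test_that("the CH index prefers the true labeling of separated blobs", {
  set.seed(3)
  pts <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
               matrix(rnorm(40, 5, 0.2), 20, 2))
  d <- as.matrix(dist(pts))
  truth <- rep(1:2, each = 20)
  ch_true <- calinski_harabasz(d, truth)
  for (r in 1:100)
    expect_gt(ch_true, calinski_harabasz(d, sample(truth)))
  expect_error(calinski_harabasz(d, rep(1, 40)), "at least 2")
})

test_that("select_k scans the range and picks the CH maximum", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2),
               matrix(rnorm(30, 4, 0.3), 15, 2))
  d <- as.matrix(dist(pts))
  only2 <- select_k(d, 2)
  expect_equal(only2$best_k, 2L)
  sel <- select_k(d, 2:6)
  expect_length(sel$ch, 5)
  expect_equal(sel$best_k, sel$k_range[which.max(sel$ch)])
  expect_error(select_k(d, integer(0)), "empty")
})

test_that("select_k recovers planted cluster numbers on synthetic cohorts", {
  for (s in 1:5) {
    pc <- planted_cohort(seed = s, n = 120)
    D <- jsd_matrix(pc$rel)
    sel <- select_k(D, 2:6)
    expect_equal(sel$best_k, 3L)
    expect_gte(rand_index(sel$best$labels, pc$labels), 0.95)
  }
})

test_that("clusters are named by their dominant genus with collision suffixes", {
  v <- rbind(c(0.7, 0.2, 0.1), c(0.6, 0.3, 0.1),
             c(0.1, 0.8, 0.1), c(0.2, 0.7, 0.1))
  colnames(v) <- c("Neisseria", "Prevotella", "Other genera")
  tab <- abundance_table(v, kind = "relative")
  lab <- label_orotypes(tab, c(1L, 1L, 2L, 2L))
  expect_equal(unname(lab$cluster_names), c("Neisseria", "Prevotella"))

  lab2 <- label_orotypes(tab, c(1L, 1L, 2L, 1L))
  expect_equal(length(unique(lab2$cluster_names)), 2)

  # the pooled category never names a cluster even when dominant
  v3 <- rbind(c(0.1, 0.2, 0.7), c(0.2, 0.1, 0.7))
  colnames(v3) <- colnames(v)
  lab3 <- label_orotypes(abundance_table(v3, kind = "relative"), c(1L, 2L))
  expect_false(any(grepl("Other genera", lab3$cluster_names)))
})

test_that("planted dominant genera become the orotype names", {
  pc <- planted_cohort(seed = 2, n = 120)
  sel <- select_k(jsd_matrix(pc$rel), 2:4)
  lab <- label_orotypes(pc$rel, sel$best)
  expect_setequal(unname(lab$cluster_names),
                  c("Neisseria", "Prevotella", "Streptococcus"))
})

test_that("alpha diversity matches closed forms and vegan", {
  tab <- abundance_table(rbind(u = rep(0.25, 4),
                               s = c(1, 0, 0, 0),
                               m = c(0.5, 0.25, 0.25, 0)),
                         kind = "relative")
  div <- alpha_diversity(tab)
  expect_equal(div$shannon[1], log(4))
  expect_equal(div$simpson[1], 0.75)
  expect_equal(div$shannon[2], 0)
  expect_equal(div$simpson[2], 0)
  expect_equal(div$shannon[3],
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)

  skip_if_not_installed("vegan")
  set.seed(13)
  x <- matrix(rgamma(5 * 8, 1), 5, 8); x <- x / rowSums(x)
  d2 <- alpha_diversity(abundance_table(x, kind = "relative"))
  expect_equal(d2$shannon, unname(vegan::diversity(x, "shannon")),
               tolerance = 1e-12)
  expect_equal(d2$simpson, unname(vegan::diversity(x, "simpson")),
               tolerance = 1e-12)
  # Shannon maximal iff uniform
  expect_true(all(d2$shannon < log(8)))
})

test_that("PCoA embeds Euclidean distances exactly and flags negative axes", {
  set.seed(19)
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(pts))
  emb <- pcoa(d, n_components = 10)
  expect_lt(max(abs(as.matrix(dist(emb$coordinates)) - d)), 1e-9)
  expect_length(emb$negative_eigenvalues, 0)

  zero <- pcoa(matrix(0, 4, 4), 4)
  expect_equal(ncol(zero$coordinates), 0)

  # 4-point configuration with no Euclidean embedding
  d4 <- matrix(1, 4, 4); diag(d4) <- 0
  d4[1, 2] <- d4[2, 1] <- 2
  emb4 <- pcoa(d4, 4)
  expect_gt(length(emb4$negative_eigenvalues), 0)

  skip_if_not_installed("ape")
  ap <- ape::pcoa(as.dist(d))
  expect_equal(sort(abs(emb$eigenvalues), decreasing = TRUE)[1:2],
               ap$values$Eigenvalues[1:2], tolerance = 1e-8)
})
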