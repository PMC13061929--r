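rel_table <- function(x, prefix = "f") {
  colnames(x) <- paste0(prefix, seq_len(ncol(x)))
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  abundance_table(x / rowSums(x), kind = "relative")
}

test_that("splitting is exhaustive, seeded and stratified by counting", {
  set.seed(1)
  x <- matrix(rgamma(10 * 3, 1), 10, 3)
  tab <- rel_table(x)
  labs <- rep(c("a", "b"), each = 5)
  sp <- split_data(tab, labs,
                   split_spec(fraction = 0.7, stratify = FALSE, seed = 5))
  expect_equal(length(sp$train_idx), 7)
  expect_equal(length(sp$test_idx), 3)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:10)

  sp2 <- split_data(tab, labs,
                    split_spec(fraction = 0.7, stratify = FALSE, seed = 5))
  expect_identical(sp$train_idx, sp2$train_idx)

  # stratified: per-class train proportion within one sample of global
  sps <- split_data(tab, labs, split_spec(fraction = 0.7, seed = 5))
  expect_true(all(abs(as.vector(table(sps$train_labels)) - 3.5) <= 0.5))

  x100 <- matrix(rgamma(100 * 3, 1), 100, 3)
  labs100 <- rep(c("a", "b", "c"), times = c(60, 30, 10))
  sp3 <- split_data(rel_table(x100), labs100, split_spec(0.7, seed = 2))
  expect_equal(as.vector(table(sp3$train_labels)), c(42, 21, 7))
  expect_error(split_data(rel_table(x100), c("z", labs100[-1])),
               "2 samples per class")
})

test_that("softmax fits separable data and shrinks under heavy ridge", {
  x <- matrix(c(seq(0.1, 0.4, length.out = 10),
                seq(0.6, 0.9, length.out = 10)), 20, 1)
  tab <- rel_table(cbind(x, 1 - x))
  labs <- rep(c("lo", "hi"), each = 10)
  m <- fit_softmax(tab, labs, lambda = 1e-4)
  pred <- colnames(predict_proba(m, tab))[
    max.col(predict_proba(m, tab))]
  expect_equal(mean(pred == labs), 1)

  mbig <- fit_softmax(tab, labs, lambda = 1e6)
  expect_lt(max(abs(mbig$coefficients[-1, ])), 1e-3)
  pr <- predict_proba(mbig, tab)
  expect_equal(unname(colMeans(pr)), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("the fitted deviance beats random coefficient draws", {
  set.seed(8)
  x <- matrix(rgamma(20 * 2, 2), 20, 2)
  tab <- rel_table(cbind(x, 3) )
  labs <- sample(c("A", "B", "C"), 20, replace = TRUE)
  lambda <- 1e-3
  m <- fit_softmax(tab, labs, lambda = lambda)

  nll <- function(coefs) {
    eta <- cbind(1, tab$values) %*% coefs
    p <- exp(eta - apply(eta, 1, max))
    p <- p / rowSums(p)
    -sum(log(p[cbind(1:20, match(labs, sort(unique(labs))))])) +
      lambda / 2 * sum(coefs[-1, -1]^2)
  }
  fitted_nll <- nll(m$coefficients)
  set.seed(9)
  for (r in 1:1000) {
    rc <- m$coefficients
    rc[, -1] <- rnorm(length(rc[, -1]), sd = 2)
    expect_gte(nll(rc), fitted_nll - 1e-9)
  }
})

test_that("softmax probabilities agree with an established multinomial fit", {
  skip_if_not_installed("nnet")
  set.seed(3)
  pc <- planted_cohort(seed = 3, n = 90)
  m <- fit_softmax(pc$rel, pc$labels, lambda = 1e-4)
  pr <- predict_proba(m, pc$rel)
  df <- data.frame(y = factor(pc$labels), pc$rel$values, check.names = TRUE)
  nn <- nnet::multinom(y ~ ., df, decay = 1e-4, maxit = 500, trace = FALSE)
  prn <- predict(nn, df, type = "probs")
  expect_lt(max(abs(pr - prn)), 0.02)
})

test_that("probability predictions are proper and shift-invariant", {
  set.seed(4)
  tab <- rel_table(matrix(rgamma(30, 1), 10, 3))
  labs <- rep(c("A", "B", "C"), times = c(4, 3, 3))
  m <- fit_softmax(tab, labs, lambda = 0.01)
  pr <- predict_proba(m, tab)
  expect_equal(unname(rowSums(pr)), rep(1, 10), tolerance = 1e-9)

  m0 <- m; m0$coefficients[] <- 0
  expect_true(all(abs(predict_proba(m0, tab) - 1 / 3) < 1e-12))

  mshift <- m; mshift$coefficients[1, ] <- mshift$coefficients[1, ] + 5
  expect_equal(predict_proba(mshift, tab), pr, tolerance = 1e-9)

  bad <- tab; bad$taxon_names <- paste0("x", 1:3)
  expect_error(predict_proba(m, bad), "feature set")
})

test_that("one-vs-rest AUC equals the pair-counting oracle", {
  pr2 <- cbind(A = rep(0.5, 6), B = rep(0.5, 6))
  expect_equal(unname(roc_auc_ovr(pr2, rep(c("A", "B"), 3))$auc),
               c(0.5, 0.5))

  pr <- cbind(A = c(0.9, 0.8, 0.3, 0.2), B = c(0.1, 0.2, 0.7, 0.8))
  expect_equal(unname(roc_auc_ovr(pr, c("A", "A", "B", "B"))$auc), c(1, 1))

  # tie-containing fixture vs exhaustive enumeration
  score <- c(0.3, 0.5, 0.5, 0.2, 0.9, 0.5)
  lab <- c("A", "A", "B", "B", "A", "B")
  rep6 <- roc_auc_ovr(cbind(A = score, B = 1 - score), lab)
  expect_equal(unname(rep6$auc["A"]), brute_auc(score, lab == "A"))
  expect_equal(unname(rep6$auc["B"]), brute_auc(1 - score, lab == "B"))

  set.seed(12)
  for (r in 1:20) {
    n <- sample(6:30, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    lb <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    got <- roc_auc_ovr(cbind(A = sc, B = 1 - sc), lb)
    expect_equal(unname(got$auc["A"]), brute_auc(sc, lb == "A"))
  }

  # single-class probability column undefined, flagged NA
  one <- roc_auc_ovr(cbind(A = c(.2, .8), B = c(.8, .2)), c("A", "A"))
  expect_true(is.na(one$auc["B"]))
  expect_equal(unname(one$macro_auc), unname(one$auc["A"]))
})

test_that("KNN probabilities follow neighbour class frequencies", {
  set.seed(5)
  tr <- rel_table(matrix(rgamma(10 * 4, 1), 10, 4))
  labs <- rep(c("A", "B"), each = 5)

  same <- knn_predict(tr, labs, tr, k = 1)
  expect_true(all(same[cbind(1:10, as.integer(factor(labs)))] == 1))

  all_k <- knn_predict(tr, labs, tr, k = 10)
  expect_true(all(abs(all_k - 0.5) < 1e-12))

  te <- rel_table(matrix(rgamma(3 * 4, 1), 3, 4))
  got <- knn_predict(tr, labs, te, k = 3)
  d <- matrix(0, 3, 10)     # brute-force neighbour sort oracle
  for (i in 1:3) for (j in 1:10)
    d[i, j] <- jsd_direct(te$values[i, ], tr$values[j, ])
  for (i in 1:3) {
    nb <- order(d[i, ])[1:3]
    expect_equal(unname(got[i, "A"]), mean(labs[nb] == "A"))
  }
  expect_error(knn_predict(tr, labs, te, k = 0), "positive")
})

test_that("backward elimination records a nested path from p to 1 features", {
  set.seed(6)
  x <- matrix(rgamma(40 * 2, 2), 40, 2)
  tab <- rel_table(cbind(x, 2))
  labs <- rep(c("A", "B"), 20)
  sp <- split_data(tab, labs, split_spec(seed = 3))
  # 3-feature input: path has exactly 3 records, sizes 3, 2, 1
  path <- stepwise_backward(sp$train, sp$train_labels,
                            sp$test, sp$test_labels)
  expect_equal(path$n_features, c(3, 2, 1))
  expect_true(is.na(path$removed[1]))

  # head consistency: full-model AUC equals a direct fit + score
  m <- fit_softmax(sp$train, sp$train_labels)
  full_auc <- roc_auc_ovr(predict_proba(m, sp$test), sp$test_labels)$macro_auc
  expect_equal(path$macro_auc[1], full_auc, tolerance = 1e-12)

  # retained sets are nested
  rets <- strsplit(path$retained, ",")
  for (i in 2:length(rets))
    expect_true(all(rets[[i]] %in% rets[[i - 1]]))
})

test_that("backward elimination keeps the signal-carrying genera last", {
  kept_last <- 0
  for (s in 1:3) {
    cfg <- cohort_config(n_samples = 240, n_genera = 10, n_rare = 0,
                         cluster_weights = rep(1 / 3, 3),
                         archetypes = signal_archetypes(3, 10),
                         concentration = 200, latent_sd = 0.2,
                         block_structure = list(),
                         covariate_effects = list(), seed = s)
    co <- generate_cohort(cfg)
    rel <- to_relative(co$abundance)
    sp <- split_data(rel, co$true_labels, split_spec(seed = s))
    path <- stepwise_backward(sp$train, sp$train_labels,
                              sp$test, sp$test_labels)
    last2 <- strsplit(path$retained[path$n_features == 2], ",")[[1]]
    kept_last <- kept_last + setequal(last2, c("G1", "G2"))
  }
  expect_gte(kept_last, 2)
})

test_that("a model transfers to a fresh cohort from the same design", {
  cfg <- cohort_config(n_samples = 400, seed = 41)
  co <- generate_cohort(cfg)
  rel <- to_relative(filter_by_detection_rate(co$abundance)$table)
  sp <- split_data(rel, co$true_labels, split_spec(seed = 41))
  m <- fit_softmax(sp$train, sp$train_labels)
  auc_test <- roc_auc_ovr(predict_proba(m, sp$test), sp$test_labels)$macro_auc

  cfg2 <- cohort_config(n_samples = 400, seed = 4100)
  co2 <- generate_cohort(cfg2)
  rel2 <- to_relative(filter_by_detection_rate(co2$abundance)$table)
  # align features: same design keeps the same kept-taxon set
  expect_setequal(rel2$taxon_names, rel$taxon_names)
  rel2 <- abundance_table(rel2$values[, rel$taxon_names],
                          rel2$sample_ids, rel$taxon_names, kind = "relative")
  auc_fresh <- roc_auc_ovr(predict_proba(m, rel2), co2$true_labels)$macro_auc
  expect_lt(auc_test - auc_fresh, 0.05)
})
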