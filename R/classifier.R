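at_subset <- function(table, rows) {
  abundance_table(table$values[rows, , drop = FALSE],
                  table$sample_ids[rows], table$taxon_names,
                  kind = table$kind)
}

#' Train/test split specification
#'
#' @param fraction training fraction in (0, 1); default 0.7 (a 7:3 split).
#' @param stratify preserve per-class proportions (default TRUE).
#' @param seed integer seed for the split.
#' @return a `split_spec` list.
#' @export
split_spec <- function(fraction = 0.7, stratify = TRUE, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  structure(list(fraction = fraction, stratify = isTRUE(stratify),
                 seed = as.integer(seed)), class = "split_spec")
}

#' Split samples into training and test sets
#'
#' Disjoint, exhaustive split. Under stratification the number of training
#' samples per class is `round(fraction * n_class)`, so per-class train
#' proportions deviate from the global fraction by at most one sample.
#'
#' @param table an [abundance_table].
#' @param labels class labels aligned with rows.
#' @param spec a [split_spec].
#' @return list with `train`, `test` (abundance tables), `train_labels`,
#'   `test_labels`, `train_idx`, `test_idx`.
#' @export
split_data <- function(table, labels, spec = split_spec()) {
  stopifnot_abundance(table)
  n <- nrow(table$values)
  if (length(labels) != n) stop("labels do not align with table rows")
  labels <- as.factor(labels)
  set.seed(spec$seed)
  if (spec$stratify) {
    if (any(table(labels) < 2))
      stop("stratified split needs at least 2 samples per class")
    train_idx <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_tr <- max(1L, min(length(idx) - 1L,
                          as.integer(floor(spec$fraction * length(idx) + 0.5))))
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
    train_idx <- sort(train_idx)
  } else {
    n_tr <- as.integer(floor(spec$fraction * n + 0.5))
    train_idx <- sort(sample.int(n, n_tr))
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = at_subset(table, train_idx),
       test = at_subset(table, test_idx),
       train_labels = labels[train_idx],
       test_labels = labels[test_idx],
       train_idx = train_idx, test_idx = test_idx)
}

softmax_probs <- function(eta) {
  m <- apply(eta, 1, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

#' Fit a ridge-penalized multinomial (softmax) logistic model
#'
#' Minimizes the multinomial negative log-likelihood plus
#' `(lambda/2) * ||coefficients||^2` (intercepts unpenalized) by damped
#' Newton iteration with step halving. The first class's parameters are
#' pinned to zero (reference coding) for identifiability. Features are the
#' relative genus abundances, unstandardized. The small default ridge keeps
#' coefficients finite under separable data without materially moving
#' predicted probabilities.
#'
#' @param train an [abundance_table] (`kind = "relative"`) of training
#'   samples.
#' @param labels class labels (>= 2 classes) aligned with rows.
#' @param lambda ridge penalty (default 1e-4).
#' @param tol convergence threshold on the gradient max-norm (default 1e-6).
#' @param max_iter Newton iteration cap (default 100).
#' @return a `softmax_model`: `classes`, `features`, `coefficients`
#'   ((p + 1) x K matrix including the zero reference column, intercept in
#'   row 1), `lambda`, and `convergence` (iterations, final gradient norm,
#'   converged flag).
#' @export
fit_softmax <- function(train, labels, lambda = 1e-4, tol = 1e-6,
                        max_iter = 100L) {
  stopifnot_abundance(train)
  if (train$kind != "relative")
    stop("fit_softmax expects relative abundances")
  labels <- as.factor(labels)
  classes <- levels(labels)
  K <- length(classes)
  if (K < 2) stop("need at least 2 classes")
  x1 <- cbind(`(Intercept)` = 1, train$values)
  n <- nrow(x1); d <- ncol(x1)
  y <- matrix(0, n, K); y[cbind(seq_len(n), as.integer(labels))] <- 1
  npar <- d * (K - 1)
  pen_mask <- rep(c(0, rep(1, d - 1)), K - 1)   # intercepts unpenalized

  nll_fn <- function(b) {
    bm <- matrix(b, d, K - 1)
    eta <- cbind(0, x1 %*% bm)
    m <- apply(eta, 1, max)
    -sum((eta - m - log(rowSums(exp(eta - m))))[cbind(seq_len(n), as.integer(labels))]) +
      lambda / 2 * sum((b * pen_mask)^2)
  }
  grad_fn <- function(b, pr) {
    bm <- matrix(b, d, K - 1)
    g <- t(x1) %*% (pr[, -1, drop = FALSE] - y[, -1, drop = FALSE])
    as.vector(g) + lambda * b * pen_mask
  }

  b <- rep(0, npar)
  f <- nll_fn(b)
  gnorm <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    bm <- matrix(b, d, K - 1)
    pr <- softmax_probs(cbind(0, x1 %*% bm))
    g <- grad_fn(b, pr)
    gnorm <- max(abs(g))
    if (gnorm < tol) break
    # Hessian: blocks H[a,b] = X' diag(p_a (delta_ab - p_b)) X + lambda
    H <- matrix(0, npar, npar)
    for (a in seq_len(K - 1)) for (bb in seq_len(K - 1)) {
      w <- pr[, a + 1] * ((a == bb) - pr[, bb + 1])
      H[(a - 1) * d + seq_len(d), (bb - 1) * d + seq_len(d)] <-
        t(x1) %*% (x1 * w)
    }
    diag(H) <- diag(H) + lambda * pen_mask + 1e-10
    step <- tryCatch(solve(H, g), error = function(e) g / max(abs(diag(H))))
    # damping: halve until the objective decreases
    alpha <- 1
    repeat {
      bnew <- b - alpha * step
      fnew <- nll_fn(bnew)
      if (is.finite(fnew) && fnew <= f + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { bnew <- b; fnew <- f; break }
    }
    if (identical(bnew, b) && gnorm >= tol) break
    b <- bnew; f <- fnew
  }
  pr <- softmax_probs(cbind(0, x1 %*% matrix(b, d, K - 1)))
  gnorm <- max(abs(grad_fn(b, pr)))
  report <- list(iterations = iter, gradient_norm = gnorm,
                 converged = gnorm < tol)
  if (!report$converged)
    stop(errorCondition(
      sprintf("softmax fit did not converge in %d iterations (gradient norm %.3g)",
              iter, gnorm),
      class = "softmax_nonconvergence", report = report))
  coefs <- cbind(0, matrix(b, d, K - 1))
  dimnames(coefs) <- list(colnames(x1), classes)
  structure(list(classes = classes, features = train$taxon_names,
                 coefficients = coefs, lambda = lambda,
                 convergence = report),
            class = "softmax_model")
}

#' @export
print.softmax_model <- function(x, ...) {
  cat(sprintf("softmax_model: %d classes (%s), %d features, lambda = %g\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$features), x$lambda))
  invisible(x)
}

#' Predict class probabilities from a softmax model
#'
#' @param model a `softmax_model` from [fit_softmax].
#' @param table an [abundance_table] with exactly the training features.
#' @return n x K matrix of class probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, table) {
  stopifnot_abundance(table)
  if (!identical(table$taxon_names, model$features))
    stop("feature set does not match the training features")
  eta <- cbind(1, table$values) %*% model$coefficients
  pr <- softmax_probs(eta)
  dimnames(pr) <- list(table$sample_ids, model$classes)
  pr
}

auc_mw <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)             # mid-ranks on ties
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest ROC-AUC
#'
#' Per class, the AUC is the Mann-Whitney statistic of that class's
#' predicted probability for its samples versus all others, with mid-ranks
#' on ties; the macro AUC is the unweighted mean over classes with at least
#' one positive and one negative (others are `NA` and excluded).
#'
#' @param probabilities n x K matrix of class probabilities with class
#'   column names.
#' @param labels true class labels aligned with rows.
#' @return a `roc_report`: `auc` (named per-class vector), `macro_auc`,
#'   and `curves` (per-class data frame of FPR/TPR points).
#' @export
roc_auc_ovr <- function(probabilities, labels) {
  labels <- as.character(labels)
  classes <- colnames(probabilities)
  if (is.null(classes)) stop("probability matrix needs class column names")
  auc <- stats::setNames(rep(NA_real_, length(classes)), classes)
  curves <- list()
  for (cl in classes) {
    pos <- labels == cl
    auc[cl] <- auc_mw(probabilities[, cl], pos)
    if (!is.na(auc[cl])) {
      ths <- sort(unique(probabilities[, cl]), decreasing = TRUE)
      tpr <- vapply(ths, function(t) mean(probabilities[pos, cl] >= t), numeric(1))
      fpr <- vapply(ths, function(t) mean(probabilities[!pos, cl] >= t), numeric(1))
      curves[[cl]] <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
    }
  }
  structure(list(auc = auc, macro_auc = mean(auc, na.rm = TRUE),
                 curves = curves),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat("one-vs-rest ROC-AUC:\n")
  print(round(x$auc, 4))
  cat(sprintf("macro AUC: %.4f\n", x$macro_auc))
  invisible(x)
}

jsd_cross <- function(a, b) {
  plogp <- function(m) { out <- m * log2(m); out[m == 0] <- 0; out }
  ha <- rowSums(plogp(a)); hb <- rowSums(plogp(b))
  d <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    m <- (b + matrix(a[i, ], nrow(b), ncol(b), byrow = TRUE)) / 2
    v <- (ha[i] + hb) / 2 - rowSums(plogp(m))
    d[i, ] <- sqrt(pmin(pmax(v, 0), 1))
  }
  d
}

#' K-nearest-neighbour orotype prediction
#'
#' Comparator model: class probabilities of a test sample are the class
#' frequencies among its `k` nearest training samples under Jensen-Shannon
#' distance between relative-abundance rows. Distance ties break toward the
#' lower training index.
#'
#' @param train,test relative [abundance_table]s over the same taxa.
#' @param labels training class labels.
#' @param k number of neighbours (default 21).
#' @return n_test x K probability matrix.
#' @export
knn_predict <- function(train, labels, test, k = 21L) {
  stopifnot_abundance(train); stopifnot_abundance(test)
  if (k <= 0) stop("k must be positive")
  if (k > nrow(train$values)) stop("k exceeds the number of training samples")
  labels <- as.factor(labels)
  d <- jsd_cross(test$values, train$values)
  pr <- matrix(0, nrow(d), nlevels(labels),
               dimnames = list(test$sample_ids, levels(labels)))
  for (i in seq_len(nrow(d))) {
    nb <- order(d[i, ])[seq_len(k)]   # order() breaks ties by index
    tab <- table(labels[nb])
    pr[i, names(tab)] <- as.numeric(tab) / k
  }
  pr
}

#' Stepwise backward feature elimination on test-set AUC
#'
#' Starting from all features, each step refits the softmax model on the
#' training set once per remaining feature with that feature removed, scores
#' macro one-vs-rest AUC on the (fixed) test set, and removes the feature
#' whose removal yields the highest AUC; ties break toward the feature with
#' the smaller coefficient norm in the current model, then the lower column
#' index. The path is recorded down to a single feature. Evaluating on a
#' fixed test set mirrors how variable-reduction curves are usually drawn,
#' and is optimistically biased relative to cross-validation.
#'
#' @param train,test relative [abundance_table]s over the same taxa.
#' @param train_labels,test_labels class labels aligned with the tables.
#' @param lambda ridge penalty passed to [fit_softmax].
#' @return a `selection_path` data frame: one record per model size from
#'   `p` down to 1, with columns `n_features`, `removed` (NA for the full
#'   model), `retained` (comma-joined), `macro_auc`.
#' @export
stepwise_backward <- function(train, train_labels, test, test_labels,
                              lambda = 1e-4) {
  stopifnot_abundance(train); stopifnot_abundance(test)
  feats <- train$taxon_names
  if (length(feats) < 2) stop("need at least 2 features")
  # sub-compositions no longer close to 1; they stay valid model features,
  # so the relative flag is carried over without re-validating closure
  sub_rel <- function(tab, cols) {
    out <- tab
    out$values <- tab$values[, cols, drop = FALSE]
    out$taxon_names <- cols
    out
  }
  fit_auc <- function(cols) {
    m <- fit_softmax(sub_rel(train, cols), train_labels, lambda = lambda)
    pr <- predict_proba(m, sub_rel(test, cols))
    list(model = m, auc = roc_auc_ovr(pr, test_labels)$macro_auc)
  }
  cur <- feats
  full <- fit_auc(cur)
  records <- data.frame(n_features = length(cur), removed = NA_character_,
                        retained = paste(cur, collapse = ","),
                        macro_auc = full$auc, stringsAsFactors = FALSE)
  model <- full$model
  while (length(cur) > 1) {
    aucs <- vapply(seq_along(cur), function(j) {
      tryCatch(fit_auc(cur[-j])$auc, error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(aucs))) break   # propagated fit failures: partial path
    best <- max(aucs, na.rm = TRUE)
    cand <- which(!is.na(aucs) & aucs >= best - 1e-12)
    if (length(cand) > 1) {
      cn <- vapply(cand, function(j)
        sqrt(sum(model$coefficients[cur[j], ]^2)), numeric(1))
      cand <- cand[cn == min(cn)]
    }
    j <- min(cand)
    removed <- cur[j]
    cur <- cur[-j]
    refit <- fit_auc(cur)
    model <- refit$model
    records <- rbind(records,
                     data.frame(n_features = length(cur), removed = removed,
                                retained = paste(cur, collapse = ","),
                                macro_auc = refit$auc,
                                stringsAsFactors = FALSE))
  }
  structure(records, class = c("selection_path", "data.frame"))
}
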