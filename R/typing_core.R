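#' Jensen-Shannon distance matrix
#'
#' Pairwise Jensen-Shannon distance between relative-abundance rows:
#' `D[a, b] = sqrt(KL(p_a || m)/2 + KL(p_b || m)/2)` with
#' `m = (p_a + p_b)/2`, logarithms base 2 and the convention
#' `0 * log 0 = 0`, so distances live in `[0, 1]`. JSD is a metric on the
#' simplex, the distance the community-typing workflow clusters on.
#'
#' @param table an [abundance_table] with `kind = "relative"`.
#' @return a `distance_matrix`: list with `sample_ids` and the symmetric
#'   n x n matrix `d`.
#' @export
jsd_matrix <- function(table) {
  stopifnot_abundance(table)
  if (table$kind != "relative")
    stop("jsd_matrix expects relative abundances (see to_relative)")
  x <- table$values
  n <- nrow(x)
  # negentropy term sum p log2 p, with 0 log 0 = 0
  plogp <- function(m) {
    out <- m * log2(m)
    out[m == 0] <- 0
    out
  }
  hx <- rowSums(plogp(x))
  d2 <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    m <- (x[js, , drop = FALSE] + matrix(x[i, ], length(js), ncol(x), byrow = TRUE)) / 2
    hm <- rowSums(plogp(m))
    v <- (hx[i] + hx[js]) / 2 - hm        # JS divergence, base 2
    d2[i, js] <- d2[js, i] <- pmin(pmax(v, 0), 1)
  }
  d <- sqrt(d2)
  dimnames(d) <- list(table$sample_ids, table$sample_ids)
  structure(list(sample_ids = table$sample_ids, d = d),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d x %d (Jensen-Shannon)\n",
              nrow(x$d), ncol(x$d)))
  invisible(x)
}

as_dist_matrix <- function(D) {
  if (inherits(D, "distance_matrix")) return(D$d)
  if (inherits(D, "dist")) return(as.matrix(D))
  as.matrix(D)
}

# SWAP phase from a given medoid set: repeatedly apply the best strictly
# improving medoid/non-medoid exchange until none exists; ties toward the
# lowest index
pam_swap <- function(d, medoids) {
  n <- nrow(d)
  repeat {
    dm <- d[, medoids, drop = FALSE]
    ord <- apply(dm, 1, order)
    near_idx <- ord[1, ]                  # index into medoids
    d1 <- dm[cbind(seq_len(n), near_idx)]
    d2 <- dm[cbind(seq_len(n), ord[2, ])]
    obj <- sum(d1)
    best <- list(delta = 0, mi = NULL)
    nonmed <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      affected <- near_idx == mi
      base <- ifelse(affected, d2, d1)    # distance if medoid mi removed
      for (h in nonmed) {
        delta <- sum(pmin(base, d[, h])) - obj
        if (delta < best$delta - 1e-15)
          best <- list(delta = delta, mi = mi, h = h)
      }
    }
    if (is.null(best$mi)) break
    medoids[best$mi] <- best$h
  }
  medoids
}

pam_objective <- function(d, medoids) {
  sum(apply(d[, medoids, drop = FALSE], 1, min))
}

#' Partitioning Around Medoids on a distance matrix
#'
#' Classic PAM: a deterministic greedy BUILD phase (add the medoid that most
#' reduces the total distance of samples to their nearest medoid) followed by
#' a SWAP phase that repeatedly applies the best strictly improving
#' medoid/non-medoid exchange until none exists; all ties break toward the
#' lowest index. Because best-improvement SWAP can stall in a local optimum,
#' the SWAP phase is additionally restarted from `n_restarts` seeded random
#' medoid sets and the best objective wins (the BUILD solution is kept on
#' ties). The result is deterministic given the distances, `k` and `seed`.
#'
#' @param D a `distance_matrix` from [jsd_matrix], a `dist`, or a square
#'   symmetric matrix.
#' @param k number of clusters, `2 <= k < n`.
#' @param seed integer seed driving the random restarts.
#' @param n_restarts number of random-initialization SWAP restarts
#'   (default 10) in addition to the deterministic BUILD run.
#' @return a `clustering_result`: `k`, `medoid_indices`, `labels` (integer
#'   in `1..k`, each sample assigned to its nearest medoid, ties to the
#'   lowest medoid index), and `objective` (sum of distances to assigned
#'   medoids).
#' @export
pam_cluster <- function(D, k, seed = 1L, n_restarts = 10L) {
  d <- as_dist_matrix(D)
  n <- nrow(d)
  if (!all(is.finite(d))) stop("non-finite distances")
  if (k < 2) stop("k must be >= 2")
  if (k >= n) stop("k must be < number of samples")
  # BUILD
  medoids <- which.min(colSums(d))
  dnear <- d[, medoids]
  while (length(medoids) < k) {
    gain <- colSums(pmax(dnear - d, 0))
    gain[medoids] <- -Inf
    m <- which.max(gain)                 # which.max takes the first maximum
    medoids <- c(medoids, m)
    dnear <- pmin(dnear, d[, m])
  }
  medoids <- pam_swap(d, medoids)
  obj <- pam_objective(d, medoids)
  if (n_restarts > 0) {
    if (is.null(seed)) seed <- 1L
    starts <- local({
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      replicate(n_restarts, sample.int(n, k), simplify = FALSE)
    })
    for (st in starts) {
      m2 <- pam_swap(d, st)
      o2 <- pam_objective(d, m2)
      if (o2 < obj - 1e-15) { medoids <- m2; obj <- o2 }
    }
  }
  medoids <- medoids[order(medoids)]
  dm <- d[, medoids, drop = FALSE]
  labels <- unname(apply(dm, 1, which.min)) # ties -> lowest medoid index
  objective <- sum(dm[cbind(seq_len(n), labels)])
  structure(list(k = as.integer(k), medoid_indices = as.integer(medoids),
                 labels = as.integer(labels), objective = objective),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: k = %d, objective = %.4f\n",
              x$k, x$objective))
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-D^2/2` followed by a symmetric
#' eigendecomposition. Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues, sorted by decreasing eigenvalue.
#' Axes with negative eigenvalues — which arise when the distance is not
#' Euclidean-embeddable — are dropped and reported.
#'
#' @param D a `distance_matrix`, `dist`, or square symmetric matrix.
#' @param n_components maximum number of axes to return.
#' @return list with `coordinates` (n x m, m <= n_components),
#'   `eigenvalues` (all n, sorted decreasing), and
#'   `negative_eigenvalues` (those below `-1e-8 * max(abs(eig))`).
#' @export
pcoa <- function(D, n_components = 2) {
  d <- as_dist_matrix(D)
  n <- nrow(d)
  if (n_components > n) stop("n_components must be <= number of samples")
  a <- -0.5 * d^2
  rm_ <- rowMeans(a); gm <- mean(a)
  b <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1e-300)
  pos <- which(e$values > tol)
  keep <- pos[seq_len(min(length(pos), n_components))]
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  rownames(coords) <- rownames(d)
  if (length(keep))
    colnames(coords) <- paste0("PCo", seq_along(keep))
  list(coordinates = coords,
       eigenvalues = e$values,
       negative_eigenvalues = e$values[e$values < -tol])
}

# within/between sums of squares in a full-rank PCoA embedding
ch_from_embedding <- function(coords, labels) {
  n <- nrow(coords)
  k <- length(unique(labels))
  if (k < 2) stop("Calinski-Harabasz index needs at least 2 clusters")
  if (k >= n) stop("Calinski-Harabasz index undefined when every cluster is a singleton")
  centroid <- colMeans(coords)
  w <- 0; b <- 0
  for (c in unique(labels)) {
    idx <- labels == c
    cc <- colMeans(coords[idx, , drop = FALSE])
    w <- w + sum(sweep(coords[idx, , drop = FALSE], 2, cc)^2)
    b <- b + sum(idx) * sum((cc - centroid)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

#' Calinski-Harabasz index of a clustering on a distance matrix
#'
#' The input distances are embedded by [pcoa] (all positive-eigenvalue
#' axes); the CH pseudo-F statistic `[B/(k-1)] / [W/(n-k)]` is then computed
#' from between/within sums of squared Euclidean deviations in that
#' embedding. Embedding first keeps the variance-based CH statistic
#' well-defined when the input is a distance matrix rather than raw
#' coordinates, matching the canonical enterotyping workflow.
#'
#' @param D a `distance_matrix`, `dist`, or square symmetric matrix.
#' @param labels cluster labels (>= 2 distinct values, none empty).
#' @return the CH index (larger = better separated).
#' @export
calinski_harabasz <- function(D, labels) {
  d <- as_dist_matrix(D)
  emb <- pcoa(d, n_components = nrow(d))
  ch_from_embedding(emb$coordinates, labels)
}

#' Choose the number of community types by the CH index
#'
#' Runs [pam_cluster] for every k in `k_range`, scores each partition with
#' [calinski_harabasz] (on a PCoA embedding computed once), and picks the k
#' with the maximal CH value. The full CH curve is retained for reporting.
#'
#' @param D a `distance_matrix`, `dist`, or square symmetric matrix.
#' @param k_range integer vector of candidate cluster numbers within
#'   `[2, n - 1]`.
#' @param seed passed to [pam_cluster] (unused by the deterministic scheme).
#' @return a `cluster_selection`: `k_range`, `ch` (CH per candidate k),
#'   `best_k`, `best` (the winning `clustering_result`), and `results`
#'   (all per-k `clustering_result`s).
#' @export
select_k <- function(D, k_range = 2:10, seed = NULL) {
  d <- as_dist_matrix(D)
  n <- nrow(d)
  k_range <- as.integer(k_range)
  if (length(k_range) == 0) stop("k_range is empty")
  if (any(k_range < 2 | k_range >= n)) stop("k_range must lie within [2, n - 1]")
  emb <- pcoa(d, n_components = n)
  results <- lapply(k_range, function(k) pam_cluster(d, k, seed))
  ch <- vapply(results, function(r) ch_from_embedding(emb$coordinates, r$labels),
               numeric(1))
  best <- which.max(ch)
  structure(list(k_range = k_range, ch = ch, best_k = k_range[best],
                 best = results[[best]], results = results),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat("cluster_selection (Calinski-Harabasz):\n")
  print(stats::setNames(round(x$ch, 2), paste0("k=", x$k_range)))
  cat("chosen k =", x$best_k, "\n")
  invisible(x)
}

#' Name clusters after their dominant genus
#'
#' Each cluster is named by the taxon with the highest cluster-mean relative
#' abundance, excluding the pooled and "Unclassified" categories — the
#' convention behind calling Neisseria-, Prevotella- and
#' Streptococcus-dominant communities the N, P and S types. When two
#' clusters share a dominant genus, names are disambiguated by suffixing the
#' cluster index so the cluster-name map stays a bijection.
#'
#' @param table a relative [abundance_table] whose rows align with `labels`.
#' @param result a `clustering_result` from [pam_cluster] (or any object
#'   with a `labels` element), or an integer label vector.
#' @param exclude taxon names never used as cluster names.
#' @return an `orotype_labeling`: `cluster_names` (per-cluster), and
#'   `sample_types` (per-sample type name).
#' @export
label_orotypes <- function(table, result,
                           exclude = c("Other genera", "Unclassified")) {
  stopifnot_abundance(table)
  labels <- if (is.list(result)) result$labels else as.integer(result)
  if (length(labels) != nrow(table$values))
    stop("labels do not align with table rows")
  ks <- sort(unique(labels))
  candidates <- setdiff(table$taxon_names, exclude)
  nm <- character(length(ks))
  for (i in seq_along(ks)) {
    mu <- colMeans(table$values[labels == ks[i], candidates, drop = FALSE])
    nm[i] <- candidates[which.max(mu)]
  }
  dup <- duplicated(nm) | duplicated(nm, fromLast = TRUE)
  nm[dup] <- paste0(nm[dup], ".", ks[dup])
  structure(list(cluster_names = stats::setNames(nm, ks),
                 sample_types = nm[match(labels, ks)]),
            class = "orotype_labeling")
}

#' Per-sample alpha diversity
#'
#' Shannon index `H = -sum p_i ln p_i` (natural log) and Gini-Simpson index
#' `1 - sum p_i^2`, with `0 * ln 0 = 0`.
#'
#' @param table an [abundance_table] with `kind = "relative"`.
#' @return data frame with columns `sample_id`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(table) {
  stopifnot_abundance(table)
  if (table$kind != "relative")
    stop("alpha_diversity expects relative abundances")
  x <- table$values
  lx <- x * log(x)
  lx[x == 0] <- 0
  data.frame(sample_id = table$sample_ids,
             shannon = -rowSums(lx),
             simpson = 1 - rowSums(x^2),
             row.names = NULL)
}
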