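spearman <- function(x, y) stats::cor(x, y, method = "spearman")

fisher_z <- function(r, cap = 1 - 1e-7) {
  r <- pmin(pmax(r, -cap), cap)
  atanh(r)
}

# Spearman correlation matrix of all columns; columns with zero variance
# give NA rows/columns
spearman_matrix <- function(x) {
  r <- apply(x, 2, rank)
  suppressWarnings(stats::cor(r))
}

# pooled-variance two-sample z-test p-values comparing, per pair, the
# Fisher-z bootstrap distribution against the Fisher-z permutation null
pooled_z_pvalues <- function(boot_sum, boot_ss, boot_n,
                             null_sum, null_ss, null_n) {
  mb <- boot_sum / boot_n
  mn <- null_sum / null_n
  vb <- pmax((boot_ss - boot_sum^2 / boot_n) / (boot_n - 1), 0)
  vn <- pmax((null_ss - null_sum^2 / null_n) / (null_n - 1), 0)
  sp <- sqrt(((boot_n - 1) * vb + (null_n - 1) * vn) / (boot_n + null_n - 2))
  z <- (mb - mn) / sp
  p <- 2 * pnorm(-abs(z))
  p[sp == 0 & mb == mn] <- 1
  p[sp == 0 & mb != mn] <- 0
  p
}

#' Compositionality-corrected pairwise correlations
#'
#' For every unordered taxon pair, the observed association is the Spearman
#' correlation of the two relative-abundance columns. Because compositions
#' are closed to 1, naive correlations on proportions are biased; the
#' significance of each pair is therefore judged against a
#' permutation-renormalization (ReBoot/CCREPE-style) null: in each
#' iteration every column is permuted independently across samples and
#' every sample row re-closed to sum 1 before the pair's Spearman
#' correlation is recomputed, so the null distribution carries exactly the
#' closure-induced dependence that independent taxa would show. A bootstrap
#' distribution (resampling samples with replacement, all columns jointly)
#' captures the sampling variability of the observed correlation. Both
#' distributions are Fisher z-transformed and compared with a
#' pooled-variance two-sample z statistic; the two-sided normal p-value is
#' reported per pair, with Benjamini-Hochberg q-values across all defined
#' pairs. Bootstrap draws in which a column becomes constant are dropped
#' for the pairs involving that column. Samples are put in a canonical
#' order before any draw, so results are invariant to input row order.
#'
#' @param table an [abundance_table] with `kind = "relative"`, at least 3
#'   samples.
#' @param n_iter permutation/bootstrap iterations (>= 100; default 1000).
#' @param seed integer seed; results are deterministic given it.
#' @return data frame with one row per unordered pair: `taxon_a`,
#'   `taxon_b`, `rho`, `p`, `q`, and `defined` (FALSE for pairs with a
#'   constant column, which are excluded from the FDR family).
#' @export
reboot_correlations <- function(table, n_iter = 1000, seed = 1L) {
  stopifnot_abundance(table)
  if (table$kind != "relative")
    stop("reboot_correlations expects relative abundances")
  if (n_iter < 100) stop("n_iter must be >= 100")
  x <- table$values
  n <- nrow(x); p <- ncol(x)
  if (n < 3) stop("need at least 3 samples")
  x <- x[do.call(order, as.data.frame(x)), , drop = FALSE]  # canonical order
  r_obs <- spearman_matrix(x)
  col_ok <- apply(x, 2, var) > 0
  set.seed(seed)
  zero <- matrix(0, p, p)
  boot_sum <- boot_ss <- null_sum <- null_ss <- zero
  boot_n <- null_n <- zero
  for (b in seq_len(n_iter)) {
    # null: permute every column independently, re-close each sample row
    xp <- vapply(seq_len(p), function(j) x[sample.int(n), j], numeric(n))
    xp <- xp / rowSums(xp)
    zn <- fisher_z(spearman_matrix(xp))
    ok <- is.finite(zn)
    null_sum[ok] <- null_sum[ok] + zn[ok]
    null_ss[ok] <- null_ss[ok] + zn[ok]^2
    null_n <- null_n + ok
    # bootstrap: resample samples with replacement (all columns jointly)
    zb <- fisher_z(spearman_matrix(x[sample.int(n, n, replace = TRUE), ,
                                     drop = FALSE]))
    ok <- is.finite(zb)
    boot_sum[ok] <- boot_sum[ok] + zb[ok]
    boot_ss[ok] <- boot_ss[ok] + zb[ok]^2
    boot_n <- boot_n + ok
  }
  pv <- pooled_z_pvalues(boot_sum, boot_ss, boot_n, null_sum, null_ss, null_n)
  pairs <- utils::combn(p, 2)
  m <- ncol(pairs)
  i <- pairs[1, ]; j <- pairs[2, ]
  rho <- r_obs[cbind(i, j)]
  pval <- pv[cbind(i, j)]
  defined <- col_ok[i] & col_ok[j] &
    boot_n[cbind(i, j)] >= 2 & null_n[cbind(i, j)] >= 2 & is.finite(pval)
  rho[!col_ok[i] | !col_ok[j]] <- NA_real_
  pval[!defined] <- NA_real_
  q <- rep(NA_real_, m)
  q[defined] <- bh_adjust(pval[defined])
  data.frame(taxon_a = table$taxon_names[i],
             taxon_b = table$taxon_names[j],
             rho = rho, p = pval, q = q, defined = defined,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1, returned in the
#' input order (delegates to [stats::p.adjust]).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Threshold correlations into a co-occurrence network
#'
#' Keeps edges whose correlation passes `|rho| > rho_min` and `q < q_max`
#' (both strict). Edge sign (positive/negative correlation) and `|rho|`
#' weight are recorded; taxa with no passing edge remain as isolated nodes.
#'
#' @param correlations data frame from [reboot_correlations].
#' @param rho_min minimum absolute correlation (default 0.3).
#' @param q_max maximum FDR q-value (default 0.05).
#' @param nodes node (taxon) set; defaults to all taxa appearing in
#'   `correlations`.
#' @return a `cooccurrence_network`: `nodes`, `edges` (data frame with
#'   `taxon_a`, `taxon_b`, `rho`, `q`, `sign`, `weight`), `graph` (igraph),
#'   and per-node `degree`.
#' @export
build_network <- function(correlations, rho_min = 0.3, q_max = 0.05,
                          nodes = NULL) {
  if (is.null(nodes))
    nodes <- unique(c(correlations$taxon_a, correlations$taxon_b))
  keep <- !is.na(correlations$rho) & !is.na(correlations$q) &
    abs(correlations$rho) > rho_min & correlations$q < q_max
  edges <- correlations[keep, c("taxon_a", "taxon_b", "rho", "p", "q"),
                        drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  edges$weight <- abs(edges$rho)
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("taxon_a", "taxon_b", "weight")],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  deg <- igraph::degree(g)
  structure(list(nodes = nodes, edges = edges, graph = g,
                 degree = deg, rho_min = rho_min, q_max = q_max),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges (|rho| > %g, q < %g)\n",
              length(x$nodes), nrow(x$edges), x$rho_min, x$q_max))
  invisible(x)
}

#' Node degrees of a co-occurrence network
#'
#' @param net a `cooccurrence_network` from [build_network].
#' @return named integer vector, one entry per node (0 for isolated nodes).
#' @export
node_degrees <- function(net) net$degree

#' Edge-betweenness (Girvan-Newman) community detection
#'
#' Repeatedly removes the edge with maximal betweenness (unweighted shortest
#' paths) and returns, among the resulting partition sequence, the one with
#' maximal Newman-Girvan modularity on the original unweighted graph.
#' Community detection deliberately ignores edge weights and signs: the
#' network mixes positive and negative correlation edges and no weighting
#' scheme is implied by either.
#'
#' @param net a `cooccurrence_network` from [build_network], or an igraph
#'   graph.
#' @return a `community_partition`: `membership` (named integer vector),
#'   `modularity`, and `merges` (the dendrogram of the removal process, as
#'   an igraph merge matrix; `NULL` for an edgeless graph).
#' @export
detect_communities <- function(net) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")
  if (igraph::ecount(g) == 0) {
    memb <- stats::setNames(seq_len(igraph::vcount(g)),
                            igraph::V(g)$name)
    return(structure(list(membership = memb, modularity = 0, merges = NULL),
                     class = "community_partition"))
  }
  cl <- igraph::cluster_edge_betweenness(g, weights = NULL, directed = FALSE)
  memb <- igraph::membership(cl)
  structure(list(membership = stats::setNames(as.integer(memb), names(memb)),
                 modularity = igraph::modularity(g, memb),
                 merges = cl$merges),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d communities, modularity %.4f\n",
              length(unique(x$membership)), x$modularity))
  invisible(x)
}
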