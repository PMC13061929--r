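#' Default cluster archetypes for a three-orotype tongue community
#'
#' Builds per-cluster mean compositions over `n_genera` informative genera
#' plus `n_rare` rare-tail genera. Each cluster is dominated by one archetype
#' genus (Neisseria, Prevotella, Streptococcus for the default k = 3, the
#' dominants typical of oral community types); the remaining informative mass
#' decays geometrically with a cluster-specific tilt so the archetypes are
#' well separated (pairwise Jensen-Shannon distance > 0.4 at the defaults).
#' Rare-tail genera share an exponentially decaying sliver of mass so that
#' detection-rate pooling has something to pool.
#'
#' @param k_clusters number of community types.
#' @param n_genera number of informative genera (default 46).
#' @param n_rare number of rare-tail genera (default 20).
#' @param dominant_mass archetype mass of each cluster's dominant genus.
#' @param rare_mass total archetype mass of the rare tail.
#' @return a k x (n_genera + n_rare) row-stochastic matrix with genus column
#'   names; rownames are the dominant genus of each cluster.
#' @export
default_archetypes <- function(k_clusters = 3, n_genera = 46, n_rare = 20,
                               dominant_mass = 0.45, rare_mass = 0.02) {
  oral_genera <- c("Neisseria", "Prevotella", "Streptococcus", "Veillonella",
                   "Rothia", "Actinomyces", "Haemophilus", "Fusobacterium",
                   "Granulicatella", "Gemella", "Porphyromonas", "Leptotrichia",
                   "Capnocytophaga", "Campylobacter", "Alloprevotella",
                   "Solobacterium", "Atopobium", "Oribacterium",
                   "Stomatobaculum", "Megasphaera", "Lachnoanaerobaculum",
                   "Selenomonas", "Saccharibacteria_TM7", "Lautropia",
                   "Aggregatibacter", "Eikenella", "Corynebacterium",
                   "Tannerella", "Treponema", "Peptostreptococcus")
  if (k_clusters > length(oral_genera))
    stop("too many clusters for the built-in genus pool")
  n_extra <- max(0, n_genera - length(oral_genera))
  names_inf <- c(oral_genera,
                 if (n_extra > 0) paste0("Genus", sprintf("%02d", seq_len(n_extra))))
  names_inf <- names_inf[seq_len(n_genera)]
  names_rare <- if (n_rare > 0) paste0("RareGenus", sprintf("%02d", seq_len(n_rare))) else character(0)
  p <- n_genera + n_rare
  arch <- matrix(0, k_clusters, p,
                 dimnames = list(names_inf[seq_len(k_clusters)],
                                 c(names_inf, names_rare)))
  base <- 0.90^(seq_len(n_genera))          # shared geometric backbone
  for (c in seq_len(k_clusters)) {
    w <- base
    # cluster-specific tilt: rotate the backbone so each cluster favours a
    # different slice of the non-dominant genera
    w <- w[1 + ((seq_len(n_genera) - 1 + (c - 1) * floor(n_genera / k_clusters)) %% n_genera)]
    w[c] <- 0                               # dominant handled separately
    w <- w / sum(w) * (1 - dominant_mass - rare_mass)
    w[c] <- dominant_mass
    arch[c, seq_len(n_genera)] <- w
  }
  if (n_rare > 0) {
    tail <- exp(-0.5 * seq_len(n_rare))
    tail <- tail / sum(tail) * rare_mass
    arch[, n_genera + seq_len(n_rare)] <- matrix(tail, k_clusters, n_rare,
                                                 byrow = TRUE)
  }
  arch / rowSums(arch)
}

#' Configuration of a synthetic tongue-microbiota cohort
#'
#' Bundles and validates all parameters of the generative model used by
#' [generate_cohort] and [generate_longitudinal]. Defaults emulate the kind
#' of cohort the typing pipeline targets: three community types with
#' marginal frequencies 35.8/44.2/20.0%, 46 informative genera plus a rare
#' tail, MiSeq-scale sequencing depths, lifestyle covariates mildly
#' associated with type membership, and three survey visits with
#' type-specific retention.
#'
#' @param n_samples number of individuals.
#' @param n_genera number of informative genera.
#' @param n_rare number of rare-tail genera (pooled by detection-rate
#'   filtering downstream).
#' @param k_clusters number of community types.
#' @param cluster_weights probability vector of length `k_clusters`
#'   (sums to 1 within 1e-12).
#' @param archetypes k x p row-stochastic matrix of per-cluster mean
#'   compositions; `NULL` builds [default_archetypes].
#' @param concentration Dirichlet precision per cluster (scalar or length-k,
#'   all > 0); larger values give compositions tighter around the archetype.
#' @param block_structure list of blocks, each `list(genera = <indices>,
#'   rho = <within-block latent correlation in (-1, 1)>)`; correlation is
#'   induced on latent log-abundances before closure.
#' @param latent_sd standard deviation of the logistic-normal perturbation
#'   applied to log-abundances.
#' @param rare_presence per-sample presence probability of the first
#'   rare-tail genus; subsequent rare genera decay by a factor 0.9. Rare
#'   taxa in real genus tables are sporadically detected, which is exactly
#'   what detection-rate pooling exists for; keeping presence below 0.5
#'   makes the rare tail poolable at the conventional 50% threshold.
#' @param depth_range integer `c(min, max)` reads per sample, min >= 100.
#' @param transition_matrix k x k row-stochastic matrix governing visit-to-
#'   visit type transitions.
#' @param n_visits number of longitudinal visits (>= 1).
#' @param covariate_effects named list, one entry per covariate, each a
#'   length-k vector of log-odds shifts on cluster membership.
#' @param seed integer root seed; all sub-stages derive their streams from
#'   it, so a fixed config yields a byte-identical cohort.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 300,
                          n_genera = 46,
                          n_rare = 20,
                          k_clusters = 3,
                          cluster_weights = NULL,
                          archetypes = NULL,
                          concentration = 120,
                          block_structure = NULL,
                          latent_sd = 0.35,
                          rare_presence = 0.40,
                          depth_range = c(10000L, 50000L),
                          transition_matrix = NULL,
                          n_visits = 1,
                          covariate_effects = NULL,
                          seed = 1L) {
  if (n_samples < 1 || n_genera < 1 || k_clusters < 1)
    stop("n_samples, n_genera and k_clusters must be positive")
  if (is.null(cluster_weights))
    cluster_weights <- if (k_clusters == 3) c(0.358, 0.442, 0.200)
                       else rep(1 / k_clusters, k_clusters)
  if (length(cluster_weights) != k_clusters)
    stop("cluster_weights must have length k_clusters")
  if (abs(sum(cluster_weights) - 1) > 1e-12)
    stop("cluster_weights must sum to 1 (within 1e-12)")
  if (is.null(archetypes))
    archetypes <- default_archetypes(k_clusters, n_genera, n_rare)
  archetypes <- as.matrix(archetypes)
  if (nrow(archetypes) != k_clusters)
    stop("archetypes must have one row per cluster")
  if (ncol(archetypes) != n_genera + n_rare)
    stop(sprintf("archetypes have %d columns; expected n_genera + n_rare = %d",
                 ncol(archetypes), n_genera + n_rare))
  if (any(abs(rowSums(archetypes) - 1) > 1e-12))
    stop("every archetype must sum to 1 (within 1e-12)")
  concentration <- rep_len(concentration, k_clusters)
  if (any(concentration <= 0)) stop("concentration must be > 0")
  if (is.null(block_structure)) {
    # three co-varying genus blocks among the non-dominant informative genera
    b <- function(i) list(genera = i, rho = 0.6)
    block_structure <- list(b(4:9), b(10:15), b(16:21))
    block_structure <- lapply(block_structure, function(x) {
      x$genera <- x$genera[x$genera <= n_genera]; x })
    block_structure <- Filter(function(x) length(x$genera) >= 2, block_structure)
  }
  for (bl in block_structure) {
    if (is.null(bl$genera) || is.null(bl$rho))
      stop("each block needs elements 'genera' and 'rho'")
    if (any(bl$genera < 1 | bl$genera > n_genera + n_rare))
      stop("block genus index out of range")
    if (bl$rho <= -1 || bl$rho >= 1) stop("block rho must be in (-1, 1)")
  }
  depth_range <- as.integer(round(depth_range))
  if (length(depth_range) != 2 || depth_range[1] > depth_range[2])
    stop("depth_range must be c(min, max) with min <= max")
  if (depth_range[1] < 100) stop("depth_range minimum must be >= 100")
  if (is.null(transition_matrix)) {
    # diagonal-heavy defaults: two consecutive transitions give full-
    # trajectory retention near the 48/52/32% reported for N/P/S types
    transition_matrix <- if (k_clusters == 3)
      rbind(c(0.70, 0.20, 0.10),
            c(0.14, 0.72, 0.14),
            c(0.18, 0.25, 0.57))
    else diag(k_clusters) * 0.7 + (1 - diag(k_clusters)) * (0.3 / (k_clusters - 1))
    if (k_clusters == 1) transition_matrix <- matrix(1, 1, 1)
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == k_clusters))
    stop("transition_matrix must be k x k")
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12))
    stop("transition_matrix rows must be non-negative and sum to 1 (within 1e-12)")
  if (n_visits < 1) stop("n_visits must be >= 1")
  if (is.null(covariate_effects))
    covariate_effects <- list(
      smoking  = if (k_clusters == 3) c(0, 0.8, 0.4) else rep(0, k_clusters),
      age_std  = if (k_clusters == 3) c(0, 0.25, -0.15) else rep(0, k_clusters))
  for (ce in covariate_effects)
    if (length(ce) != k_clusters)
      stop("each covariate effect must be a length-k vector of log-odds shifts")
  structure(list(n_samples = as.integer(n_samples),
                 n_genera = as.integer(n_genera),
                 n_rare = as.integer(n_rare),
                 k_clusters = as.integer(k_clusters),
                 cluster_weights = cluster_weights,
                 archetypes = archetypes,
                 concentration = concentration,
                 block_structure = block_structure,
                 latent_sd = latent_sd,
                 rare_presence = rare_presence,
                 depth_range = depth_range,
                 transition_matrix = transition_matrix,
                 n_visits = as.integer(n_visits),
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic sub-seeds so each generation stage has its own stream
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) { g[which.max(alpha)] <- 1 }  # degenerate tiny-alpha guard
  g / sum(g)
}

# compositions for a vector of cluster labels: Dirichlet around the cluster
# archetype, then a logistic-normal perturbation with block-correlated
# latent factors on the log scale, re-closed to 1
draw_compositions <- function(config, labels) {
  n <- length(labels)
  p <- ncol(config$archetypes)
  comp <- matrix(0, n, p)
  in_block <- rep(FALSE, p)
  for (bl in config$block_structure) in_block[bl$genera] <- TRUE
  for (i in seq_len(n)) {
    c <- labels[i]
    g <- rdirichlet1(config$concentration[c] * config$archetypes[c, ])
    z <- stats::rnorm(p)
    for (bl in config$block_structure) {
      f <- stats::rnorm(1)
      a <- abs(bl$rho)
      # negative rho: alternate loading signs, giving anti-correlated pairs
      s <- if (bl$rho >= 0) 1 else rep_len(c(1, -1), length(bl$genera))
      z[bl$genera] <- sqrt(a) * f * s + sqrt(1 - a) * z[bl$genera]
    }
    w <- log(pmax(g, 1e-12)) + config$latent_sd * z
    w <- exp(w - max(w))
    if (config$n_rare > 0 && config$rare_presence < 1) {
      # sporadic presence of rare-tail genera (zero-inflation before closure)
      ri <- config$n_genera + seq_len(config$n_rare)
      pres <- config$rare_presence * 0.9^(seq_len(config$n_rare) - 1)
      w[ri] <- w[ri] * stats::rbinom(config$n_rare, 1, pres)
    }
    comp[i, ] <- w / sum(w)
  }
  colnames(comp) <- colnames(config$archetypes)
  comp
}

draw_covariates <- function(config, n) {
  data.frame(smoking = stats::rbinom(n, 1, 0.25),
             age_std = stats::rnorm(n))
}

draw_labels <- function(config, covariates) {
  n <- nrow(covariates)
  k <- config$k_clusters
  eta <- matrix(log(config$cluster_weights), n, k, byrow = TRUE)
  for (nm in names(config$covariate_effects)) {
    if (!nm %in% names(covariates)) next
    eta <- eta + outer(covariates[[nm]], config$covariate_effects[[nm]])
  }
  pr <- exp(eta - apply(eta, 1, max))
  pr <- pr / rowSums(pr)
  vapply(seq_len(n), function(i) sample.int(k, 1, prob = pr[i, ]), integer(1))
}

counts_from_compositions <- function(config, comp) {
  n <- nrow(comp)
  depth <- sample(seq(config$depth_range[1], config$depth_range[2]), n,
                  replace = TRUE)
  cnt <- t(vapply(seq_len(n),
                  function(i) stats::rmultinom(1, depth[i], comp[i, ])[, 1],
                  numeric(ncol(comp))))
  colnames(cnt) <- colnames(comp)
  cnt
}

#' Generate a synthetic cross-sectional cohort
#'
#' Draws, per sample: lifestyle covariates; a community-type label from the
#' cluster weights shifted on the log-odds scale by the covariate effects; a
#' composition from a Dirichlet centred on the cluster archetype, perturbed
#' by block-correlated logistic-normal noise on latent log-abundances before
#' closure; and read counts from a multinomial at a depth uniform on
#' `depth_range`. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config].
#' @return a `synthetic_cohort` list: `abundance` (counts
#'   [abundance_table]), `true_labels` (integer vector in `1..k`),
#'   `covariates` (data frame), `visit_ids` (all 1 here), `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("expected a cohort_config")
  seeds <- derive_seeds(config$seed, 4)
  n <- config$n_samples
  set.seed(seeds[1]); covariates <- draw_covariates(config, n)
  set.seed(seeds[2]); labels <- draw_labels(config, covariates)
  set.seed(seeds[3]); comp <- draw_compositions(config, labels)
  set.seed(seeds[4]); cnt <- counts_from_compositions(config, comp)
  rownames(cnt) <- sprintf("S%04d_v1", seq_len(n))
  structure(list(abundance = abundance_table(cnt, kind = "counts"),
                 true_labels = labels,
                 covariates = covariates,
                 visit_ids = rep(1L, n),
                 config = config),
            class = "synthetic_cohort")
}

#' Extend a baseline cohort with longitudinal visits
#'
#' Visit-t labels are drawn from the `transition_matrix` row of the
#' visit-(t-1) label (a first-order Markov chain over community types);
#' compositions and counts are re-drawn from the new cluster's archetype
#' model at every visit. Rows are ordered visit-major (all samples at visit
#' 1, then visit 2, ...).
#'
#' @param config a [cohort_config] with `n_visits >= 2`.
#' @param baseline a `synthetic_cohort` from [generate_cohort] under the
#'   same config (its labels seed the chain).
#' @return a `synthetic_cohort` whose `abundance` has
#'   `n_samples * n_visits` rows, with `true_labels` and `visit_ids`
#'   aligned to rows and a `label_matrix` (samples x visits) element.
#' @export
generate_longitudinal <- function(config, baseline) {
  if (!inherits(config, "cohort_config")) stop("expected a cohort_config")
  if (config$n_visits < 2) stop("generate_longitudinal requires n_visits >= 2")
  if (!inherits(baseline, "synthetic_cohort") || is.null(baseline$true_labels))
    stop("baseline must be a synthetic_cohort with visit-0 labels")
  n <- config$n_samples
  if (length(baseline$true_labels) < n)
    stop("baseline labels do not cover n_samples")
  seeds <- derive_seeds(config$seed + 1L, 2 * config$n_visits)
  labm <- matrix(0L, n, config$n_visits)
  labm[, 1] <- baseline$true_labels[seq_len(n)]
  for (t in 2:config$n_visits) {
    set.seed(seeds[t])
    labm[, t] <- vapply(labm[, t - 1], function(c)
      sample.int(config$k_clusters, 1, prob = config$transition_matrix[c, ]),
      integer(1))
  }
  counts <- vector("list", config$n_visits)
  counts[[1]] <- baseline$abundance$values[seq_len(n), , drop = FALSE]
  for (t in 2:config$n_visits) {
    set.seed(seeds[config$n_visits + t])
    comp <- draw_compositions(config, labm[, t])
    cnt <- counts_from_compositions(config, comp)
    rownames(cnt) <- sprintf("S%04d_v%d", seq_len(n), t)
    counts[[t]] <- cnt
  }
  all_cnt <- do.call(rbind, counts)
  structure(list(abundance = abundance_table(all_cnt, kind = "counts"),
                 true_labels = as.integer(labm),
                 label_matrix = labm,
                 covariates = baseline$covariates,
                 visit_ids = rep(seq_len(config$n_visits), each = n),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples x %d taxa, %d visit(s), k = %d\n",
              x$config$n_samples, ncol(x$abundance$values),
              max(x$visit_ids), x$config$k_clusters))
  invisible(x)
}
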