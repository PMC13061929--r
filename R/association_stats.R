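#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon test between two groups of values. The
#' p-value is exact (full enumeration of the rank-sum distribution) when the
#' pooled sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used — the same switch [stats::wilcox.test] applies, which does the
#' computation here.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact_max pooled sample size up to which the exact path is taken
#'   (default 20).
#' @return list with `U` (Mann-Whitney statistic of `x` vs `y`), `p`
#'   (two-sided), and `exact` (logical, which path was used).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 20L) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1)
    return(list(U = length(x) * length(y) / 2, p = 1, exact = TRUE))
  exact <- !ties && (length(x) + length(y)) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = unname(wt$p.value), exact = exact)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` per p-value, with `m` at least the number of p-values —
#' e.g. `m = 3` for the three pairwise orotype comparisons of one variable.
#'
#' @param pvalues numeric p-values.
#' @param m number of comparisons (default `length(pvalues)`).
#' @return adjusted p-values, same order.
#' @export
bonferroni <- function(pvalues, m = length(pvalues)) {
  if (m < length(pvalues)) stop("m must be >= number of p-values")
  pmin(1, m * pvalues)
}

or_from_glm <- function(fit, term_names, outcome, reference = NA_character_,
                        adjusted_for = character(0)) {
  sm <- summary(fit)$coefficients
  est <- stats::coef(fit)
  if (anyNA(est)) {
    bad <- names(est)[is.na(est)]
    stop("rank-deficient design (collinear term): ",
         paste(bad, collapse = ", "))
  }
  # crude separation diagnostic: absurd coefficient magnitude
  big <- names(est)[abs(est) > 15 & names(est) != "(Intercept)"]
  if (length(big))
    stop("possible separation for term(s): ", paste(big, collapse = ", "))
  out <- lapply(term_names, function(tm) {
    b <- sm[tm, "Estimate"]; se <- sm[tm, "Std. Error"]
    data.frame(exposure = tm, outcome = outcome,
               or = exp(b),
               ci_low = exp(b - stats::qnorm(0.975) * se),
               ci_high = exp(b + stats::qnorm(0.975) * se),
               p = sm[tm, "Pr(>|z|)"],
               reference = reference,
               adjusted_for = paste(adjusted_for, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' One-vs-rest exposure associations with orotype membership
#'
#' For each orotype T, fits a binary logistic regression of "is type T"
#' versus the rest on all selected exposures jointly (mutual adjustment) and
#' reports Wald odds ratios with 95% confidence intervals per exposure.
#' Complete cases only.
#'
#' @param covariates data frame of numeric/binary-coded exposures.
#' @param labels orotype labels aligned with rows.
#' @param exposures column names to include; default all columns.
#' @return data frame, one row per (orotype, exposure): `orotype`,
#'   `exposure`, `or`, `ci_low`, `ci_high`, `p`.
#' @export
ovr_exposure_association <- function(covariates, labels,
                                     exposures = colnames(covariates)) {
  if (nrow(covariates) != length(labels))
    stop("covariates and labels must align")
  dat <- covariates[, exposures, drop = FALSE]
  cc <- stats::complete.cases(dat) & !is.na(labels)
  dat <- dat[cc, , drop = FALSE]
  labels <- as.factor(labels[cc])
  out <- lapply(levels(labels), function(tp) {
    df <- cbind(.y = as.integer(labels == tp), dat)
    fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
    r <- or_from_glm(fit, setdiff(names(stats::coef(fit)), "(Intercept)"),
                     outcome = tp,
                     adjusted_for = exposures)
    data.frame(orotype = tp, r[, c("exposure", "or", "ci_low", "ci_high", "p")],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Orotype-to-outcome associations against a reference type
#'
#' Logistic regression of a binary outcome (e.g. a health indicator outside
#' its reference range) on orotype dummy variables plus confounders; odds
#' ratios are reported per non-reference orotype relative to the reference
#' type.
#'
#' @param labels orotype labels.
#' @param outcome binary (0/1 or logical) outcome aligned with labels.
#' @param confounders optional data frame of confounders.
#' @param reference reference orotype (default the first level).
#' @return data frame, one row per non-reference orotype: `orotype`, `or`,
#'   `ci_low`, `ci_high`, `p`, `reference`.
#' @export
outcome_association <- function(labels, outcome, confounders = NULL,
                                reference = NULL) {
  labels <- as.factor(labels)
  if (!is.null(reference)) {
    if (!reference %in% levels(labels)) stop("reference type not present")
    labels <- stats::relevel(labels, ref = reference)
  }
  reference <- levels(labels)[1]
  outcome <- as.integer(outcome)
  if (length(unique(outcome[!is.na(outcome)])) < 2)
    stop("outcome is constant")
  df <- data.frame(.y = outcome, orotype = labels)
  if (!is.null(confounders)) df <- cbind(df, confounders)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  terms <- paste0("orotype", levels(labels)[-1])
  r <- or_from_glm(fit, terms, outcome = "outcome", reference = reference,
                   adjusted_for = if (is.null(confounders)) character(0)
                                  else colnames(confounders))
  data.frame(orotype = levels(labels)[-1],
             r[, c("or", "ci_low", "ci_high", "p")],
             reference = reference, stringsAsFactors = FALSE)
}

#' Screen covariates by unadjusted association with orotype
#'
#' Filter-method variable selection: each covariate is tested for an
#' unadjusted association with the orotype labels — Kruskal-Wallis rank test
#' for numeric covariates with more than two distinct values, chi-squared
#' test on the contingency table otherwise — and kept when its p-value is
#' below the (deliberately liberal) threshold.
#'
#' @param covariates data frame.
#' @param labels orotype labels.
#' @param p_threshold selection threshold (default 0.1).
#' @return character vector of selected covariate names; the per-covariate
#'   p-values are attached as attribute `"p"`.
#' @export
variable_screen <- function(covariates, labels, p_threshold = 0.1) {
  labels <- as.factor(labels)
  ps <- vapply(colnames(covariates), function(nm) {
    v <- covariates[[nm]]
    ok <- !is.na(v) & !is.na(labels)
    if (length(unique(v[ok])) < 2) return(1)
    if (is.numeric(v) && length(unique(v[ok])) > 2)
      stats::kruskal.test(v[ok], labels[ok])$p.value
    else
      suppressWarnings(stats::chisq.test(table(v[ok], labels[ok]))$p.value)
  }, numeric(1))
  sel <- colnames(covariates)[ps < p_threshold]
  attr(sel, "p") <- ps
  sel
}

#' Longitudinal orotype transition and retention summary
#'
#' From per-visit labels of the same individuals: a K x K transition count
#' matrix per consecutive visit pair, per-type baseline counts, and
#' full-trajectory retention — individuals keeping the same type at every
#' visit — as a count and a percentage of that type's baseline (rounded half
#' up to the nearest integer for reporting).
#'
#' @param labels_by_visit matrix or data frame, individuals x visits, or a
#'   list of per-visit label vectors.
#' @return a `transition_summary`: `visits`, `transitions` (list of K x K
#'   matrices), `baseline_counts`, `retention_counts`,
#'   `retention_percent`.
#' @export
transition_summary <- function(labels_by_visit) {
  if (is.list(labels_by_visit) && !is.data.frame(labels_by_visit)) {
    lens <- lengths(labels_by_visit)
    if (length(unique(lens)) != 1)
      stop("every visit must label the same individuals")
    labm <- do.call(cbind, labels_by_visit)
  } else labm <- as.matrix(labels_by_visit)
  if (ncol(labm) < 2) stop("need at least 2 visits")
  types <- sort(unique(as.vector(labm)))
  transitions <- lapply(seq_len(ncol(labm) - 1), function(t)
    table(factor(labm[, t], levels = types),
          factor(labm[, t + 1], levels = types),
          dnn = c(paste0("visit", t), paste0("visit", t + 1))))
  baseline <- table(factor(labm[, 1], levels = types))
  stable <- apply(labm, 1, function(r) length(unique(r)) == 1)
  retention <- table(factor(labm[stable, 1], levels = types))
  pct <- ifelse(as.numeric(baseline) > 0,
                floor(100 * as.numeric(retention) / as.numeric(baseline) + 0.5),
                NA_real_)
  structure(list(visits = ncol(labm),
                 transitions = transitions,
                 baseline_counts = baseline,
                 retention_counts = retention,
                 retention_percent = stats::setNames(pct, types)),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("transition_summary over %d visits\n", x$visits))
  for (tp in names(x$retention_percent))
    cat(sprintf("  type %s: %d/%d retained (%g%%)\n", tp,
                as.integer(x$retention_counts[tp]),
                as.integer(x$baseline_counts[tp]),
                x$retention_percent[tp]))
  invisible(x)
}

#' Orotype counts and percentages
#'
#' @param labels orotype labels, or a named vector of per-type counts.
#' @return data frame with `orotype`, `n`, `percent` (100 * n / total,
#'   rounded to one decimal).
#' @export
orotype_proportions <- function(labels) {
  if (is.numeric(labels) && !is.null(names(labels))) {
    counts <- labels
  } else {
    if (length(labels) == 0) stop("labels are empty")
    counts <- table(labels)
  }
  data.frame(orotype = names(counts),
             n = as.integer(counts),
             percent = round(100 * as.numeric(counts) / sum(counts), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Chi-squared test for a shift in orotype distribution
#'
#' Pearson chi-squared test (no continuity correction) on the 2 x K
#' contingency table of visit by orotype, df = K - 1 — the check behind
#' statements that the type distribution changed between surveys.
#'
#' @param labels_a,labels_b orotype labels of the two visits (same type
#'   universe).
#' @return list with `statistic`, `df`, `p`, and `warning` (non-NULL when
#'   an expected cell count is below 1).
#' @export
distribution_shift_test <- function(labels_a, labels_b) {
  if (length(labels_a) == 0 || length(labels_b) == 0)
    stop("both label vectors must be non-empty")
  types <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  if (length(types) < 2)
    stop("distribution shift test is degenerate with a single type")
  tab <- rbind(table(factor(labels_a, levels = types)),
               table(factor(labels_b, levels = types)))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  warn <- if (any(ct$expected < 1))
    "expected cell count below 1; chi-squared approximation unreliable"
  else NULL
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), warning = warn)
}
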