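---
title: "Community typing of tongue microbiota: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community typing of tongue microbiota: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orotyper)
```

## Scope and model

`orotyper` implements the community-typing workflow used for oral (tongue)
microbiota: genus-level compositions are clustered into a small number of
community types ("orotypes", by analogy with gut enterotypes), the types are
characterized through co-occurrence networks and diversity statistics, a
multinomial classifier predicts the type of new samples, and type-covariate
associations and longitudinal type trajectories are summarized. Every stage
operates on a samples-by-genera abundance table; all analyses run on relative
abundances, so the package is explicitly in the business of compositional
data.

## Preprocessing

Counts are converted to relative abundances per sample. Genera with a
detection rate (fraction of samples with at least one read) at or below 50%
are pooled into a single "Other genera" category; a pre-existing
"Unclassified" column is kept as its own variable. The threshold is a
convention of genus-level oral-microbiome studies; `filter_by_detection_rate`
exposes it as a parameter. Pooling conserves each sample's total mass
exactly, and pooling commutes with closing the composition, which the test
suite verifies. Detection is computed on all retained samples; no per-sample
minimum read count is imposed before computing it.

## Typing: JSD, PAM, Calinski-Harabasz

The between-sample distance is the Jensen-Shannon distance with logarithms
base 2, so distances live in [0, 1]; the bounded scale keeps network
thresholds and plots comparable across runs. The Shannon index uses the
natural logarithm (the dominant convention in microbial ecology) and the
Simpson index is the Gini-Simpson form `1 - sum p^2`; these conventions
matter for absolute diversity values and are therefore stated here.

Clustering is classic partitioning-around-medoids: a deterministic greedy
BUILD phase followed by best-improvement SWAP, all ties broken toward the
lowest index. Best-improvement SWAP can stall in a local optimum (we observed
this on random 8-point fixtures, where the reference `cluster::pam`
implementation stalls at the same configuration), so `pam_cluster` also
restarts SWAP from 10 seeded random medoid sets and keeps the best objective.
The run is deterministic given the distance matrix, `k` and `seed`.

The number of clusters is chosen by the Calinski-Harabasz pseudo-F statistic.
CH is variance-based, while our input is a distance matrix, so samples are
first embedded by principal coordinates analysis (all positive-eigenvalue
axes); CH is computed from between/within sums of squares in that embedding.
This matches the canonical enterotyping workflow. Axes with negative
eigenvalues — possible because JSD is not Euclidean-embeddable in general —
are dropped and reported. Each cluster is named after its most abundant
genus on the cluster mean composition, excluding the pooled and
"Unclassified" categories; name collisions are disambiguated by suffixing
the cluster index so the type-name map stays a bijection.

## Co-occurrence networks

Naive correlations between relative abundances are biased by closure: because
rows sum to 1, even independent taxa show spurious (typically negative)
correlation. `reboot_correlations` follows the permutation-renormalization
(ReBoot/CCREPE) idea: each null iteration permutes **every** genus column
independently across samples and re-closes each row before recomputing the
pair's Spearman correlation, so the null distribution carries exactly the
dependence closure would induce among independent taxa. A bootstrap
distribution (rows resampled with replacement) captures the sampling
variability of the observed correlation. Both distributions are Fisher
z-transformed and compared with a pooled-variance two-sample z statistic;
the two-sided normal p-value is reported and Benjamini-Hochberg q-values are
computed across all pairs with defined correlations (constant columns are
flagged and excluded from the FDR family).

Two numerical details: correlations are clamped away from ±1 before the
Fisher transform (`1e-7`), and bootstrap draws in which a column becomes
constant are dropped for the affected pairs. Samples are put into a
canonical order before any draw, making p-values exactly invariant to input
row order. The default of 1000 iterations follows CCREPE's convention.

An early design used a two-column permutation (permute only the pair,
keep the other columns fixed). That null does not reproduce the closure
geometry of independent taxa — the type-I error rate was measurably inflated
(about 0.17 at a nominal 0.05) — so the full-table permutation was adopted;
under it the measured type-I rate sits at the nominal level. This is also
the variant that neutralizes the closure-artifact fixture (a taxon defined
as the complement of the others), while the naive Spearman correlation on
the same fixture is strongly negative.

Edges require `|rho| > 0.3` and `q < 0.05` (both strict); the sign and
`|rho|` weight are stored, isolated nodes are retained. Communities are
found by Girvan-Newman edge-betweenness removal via igraph, run on the
unweighted, sign-blind graph — the network mixes positive and negative edges
and no weighting scheme is implied — returning the partition of maximal
modularity along the removal sequence.

## Orotype classifier

The classifier is a ridge-penalized multinomial (softmax) logistic
regression fit by damped Newton iteration with step halving; the first
class's parameters are pinned to zero (reference coding). Features are the
relative genus abundances, unstandardized — the coefficient table is then on
the composition scale. The default penalty `lambda = 1e-4` exists because
unpenalized maximum likelihood diverges under separable data (common when
types are well separated); at this size it does not materially move
predicted probabilities, which the tests confirm against an independent
multinomial fit. A fit that does not bring the gradient max-norm under `tol`
within `max_iter` iterations fails explicitly, carrying its convergence
report.

Evaluation is one-vs-rest ROC-AUC: per class, the Mann-Whitney statistic of
that class's predicted probability with mid-ranks on ties; the macro AUC is
the unweighted mean over classes with both positives and negatives. The 7:3
train/test split is stratified by default (prevents empty-class test sets at
small n) and seeded. A k-nearest-neighbour comparator (Jensen-Shannon
distance, default k = 21) is provided. Random-forest and SVM comparators are
not implemented: any model exposing the fit/predict-probability contract can
be evaluated with `roc_auc_ovr` directly, and mature implementations of both
already exist.

Stepwise backward elimination refits the model once per remaining feature at
each step and removes the feature whose removal yields the highest macro AUC
on the fixed test set; ties break toward the smaller coefficient norm, then
the lower column index. Scoring on a fixed test set mirrors how
variable-reduction curves are usually constructed and is optimistically
biased relative to cross-validation; the path (down to one feature) records
the retained sets, which are nested by construction.

## Association statistics

Group comparisons of abundances or diversity use the two-sided Wilcoxon
rank-sum test — exact by enumeration for pooled n of at most 20 without
ties, otherwise the tie- and continuity-corrected normal approximation —
with Bonferroni correction over the number of pairwise type comparisons
(m = 3 for three types). Lifestyle exposures are related to types by
one-vs-rest binary logistic regressions on all selected exposures jointly
(mutual adjustment), with Wald odds ratios and 95% confidence intervals;
health outcomes are regressed on type dummies plus confounders against a
reference type. Covariate screening is a filter method: Kruskal-Wallis for
continuous covariates, chi-squared for categorical ones, at a deliberately
liberal p < 0.1.

Longitudinal trajectories are summarized by consecutive-visit transition
count matrices and full-trajectory retention (same type at every visit),
reported as a percentage of each type's baseline count, rounded half-up to
integers. A shift in type distribution between two visits is tested with a
Pearson chi-squared test on the 2 x K table (no continuity correction);
the choice of test is ours, as distribution-shift testing is a generic
contingency problem.

## Synthetic cohorts: what they emulate, and what they do not

Because genus tables from health-checkup cohorts are typically not publicly
sharable, the package ships a generative model so that every stage is
testable end to end:

* **Types.** Samples draw a cluster from weights (default 0.358/0.442/0.200,
  the marginal type frequencies typical of a three-type tongue cohort),
  shifted on the log-odds scale by per-covariate effects (smoking and a
  standardized age by default; the effect sizes are free parameters chosen
  at plausible magnitudes, not calibrated to any reported odds ratios).
* **Compositions.** A Dirichlet draw centred on the cluster archetype
  (precision `concentration`, default 120) is perturbed by logistic-normal
  noise on latent log-abundances; genus blocks share a latent Gaussian
  factor, inducing within-block correlation **before** closure. Correlation
  is planted pre-closure deliberately: closure itself induces spurious
  correlation, which is exactly the artifact the permutation-renormalization
  null must absorb, so the generator must keep the two sources separable.
* **Archetypes.** Three archetypes dominated by Neisseria, Prevotella and
  Streptococcus (dominant mass 0.45), with a geometric backbone over the
  remaining informative genera rotated per cluster so archetypes are well
  separated (pairwise JSD around 0.8 at the defaults).
* **Rare tail.** Genera beyond the informative set share an exponentially
  decaying sliver of mass (2%) and are only sporadically present
  (presence probability 0.4 decaying by 0.9 per rank), so the 50%
  detection-rate filter has something to pool — as it does on real genus
  tables, where rare genera are sporadically detected.
* **Depths.** Read counts are multinomial at a depth uniform on
  10,000-50,000, the scale of a MiSeq 16S run.
* **Longitudinal visits.** Visit-to-visit types follow a first-order Markov
  chain; the default transition matrix is diagonal-heavy with two-step
  retention near the 48/52/32% observed for N/P/S types over three
  triennial visits. Compositions are re-drawn at every visit.

A single integer seed drives one root generator from which every sub-stage
deterministically derives its own stream, so a fixed configuration yields a
byte-identical cohort.

The generator does **not** emulate read-level artifacts (chimeras, PCR
bias), taxonomic misassignment, zero-inflation of informative genera,
inter-genus phylogenetic structure, or realistic covariate distributions.
Passing tests on synthetic cohorts therefore show that the algorithms
recover planted structure under the stated generative assumptions — they do
not certify performance on real cohort data.

## Problem sizes and tolerances used in the test suite

The package's own checks use planted cohorts of 120-500 samples, 20-replicate
seeded simulations for stochastic properties (recovery of the planted
cluster number with Rand index at least 0.95, held-out macro AUC at least
0.95, retention of planted signal genera, network community recovery, all at
a 90% success criterion), exhaustive oracles where feasible (PAM medoid
subsets for n of at most 8, all set partitions of 8 nodes for modularity,
pair-counting AUC, rank-sum enumeration), and 500-iteration
permutation/bootstrap runs for the correlation machinery. Exact identities
are asserted at 1e-9 to 1e-12; Monte-Carlo quantities at 2-3 standard
errors of the relevant binomial. Degenerate inputs (zero-sum rows, constant
columns, single-class labels, empty edge sets, identity transitions) have
defined behaviour, tested.

## Known limitations

* PAM restarts make the local-optimum failure mode rare, not impossible;
  for publication-grade cluster numbers, inspect the CH curve rather than
  trusting the argmax blindly.
* The pooled-variance z p-value of the correlation step is a normal
  approximation to a permutation comparison; with very few iterations
  (`n_iter` near the minimum of 100) its tails are unreliable.
* Stepwise selection on a fixed test set overstates the AUC of small
  retained sets; treat the path as descriptive.
* The softmax Hessian is built densely, so fits with many hundreds of
  features will be slow; genus-level tables (tens of features) are the
  intended scale.
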