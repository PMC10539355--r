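---
title: "Methods: discovering ICP-lncRNA cooperative regulation pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering ICP-lncRNA cooperative regulation pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

Immune checkpoint genes (ICPs) such as PD-1, PD-L1 and CTLA-4 are the
targets of checkpoint-inhibitor immunotherapy, and a growing body of work
implicates long non-coding RNAs (lncRNAs) in their regulation. `icplnc`
implements a pan-cancer screening pipeline that discovers *cooperatively
regulated ICP-lncRNA pairs* from bulk expression data and evaluates them
as prognostic and immunotherapy-response biomarkers. The pipeline runs in
six stages, each exposed as ordinary R functions:

1. **Immune screen** — identify ICPs and lncRNAs highly expressed across
   purified immune cell types, after quantile normalization and batch
   adjustment.
2. **Infiltration scoring** — score tumor samples with a single-sample
   gene-set enrichment statistic and keep the high-infiltration fraction.
3. **ICR stratification** — consensus-cluster the retained samples on the
   20-gene immunologic constant of rejection (ICR) signature into high and
   low immune-activation groups, and screen genes differential between
   them.
4. **Pair discovery** — accept an ICP-lncRNA pair when it passes both a
   Pearson correlation criterion and a mutual-information criterion.
5. **Network analysis** — build the per-cohort bipartite pair network,
   assess scale-free behaviour, extract degree hubs, and classify hubs as
   common or cancer-specific across cohorts.
6. **Biomarker evaluation** — a split-cohort, held-out risk-score
   permutation screen for prognosis, and SVM / LASSO classifiers for
   immune-checkpoint-inhibitor (ICI) response.

A synthetic-cohort generator with planted ground truth accompanies the
pipeline; every stage is validated against it and against small
independent oracles in the test suite.

# The screening rules and their parameters

All thresholds live in one configuration object, `pipeline_config()`:

| parameter | default | meaning |
|---|---|---|
| `high_expr_quantile` | 0.5 | within-class rank quantile a gene must exceed to count as highly expressed in a cell type (top 50%) |
| `immune_score_quantile` | 0.75 | fraction of tumor samples retained by immune score (top 75%) |
| `pcc_abs_min` | 0.3 | strict lower bound on \|Pearson r\| for pair acceptance |
| `alpha` | 0.05 | significance level for every screen (strict) |
| `hub_quantile` | 0.95 | degree quantile above which a node is a hub (top 5%) |
| `common_hub_min_cancers` | 6 | minimum cohorts for a common hub ("more than five") |
| `n_survival_perms` | 1000 | outcome permutations in the survival screen |
| `mi_null_perms` | 100 | permutations for the mutual-information null |
| `ssgsea_weight` | 0.25 | rank-weight exponent of the enrichment statistic |

In the immune screen, lncRNAs highly expressed in *exactly one* cell type
are immune-specific, and those highly expressed in *more than nine* of
the 18 canonical immune cell types are immune-general; we read "one kind
of immune cell" as exactly one, since otherwise the general rule would be
redundant, and parameterize the general cutoff as `ceiling(n/2)` when the
panel does not have 18 cell types. Ranking is within gene class (ICPs
against ICPs, lncRNAs against lncRNAs) with ties broken by gene id so the
screen is deterministic.

# Models and procedures

## Single-sample enrichment score

For a sample with expression vector $x$ over $N$ genes and a gene set
$G$, genes are ranked by expression ($r_i$, large = high). Walking down
the ranking, the score accumulates the difference between a rank-weighted
in-set empirical distribution and an unweighted out-set distribution:

$$ES = \sum_{j=1}^{N}\left(
  \frac{\sum_{i \le j,\, i \in G} r_i^{w}}{\sum_{i \in G} r_i^{w}}
  - \frac{|\{i \le j : i \notin G\}|}{N - |G|}\right), \qquad w = 0.25 .$$

Only ranks enter, so scores are invariant under any strictly monotone
transform of a sample's values — the property the test suite verifies to
1e-9. Scores are *not* normalized across samples by default; the
response module's comprehensive pair score applies min-max normalization
(a degenerate zero range maps to 0).

## Consensus clustering of the ICR signature

Monti-style consensus clustering: 100 resampling rounds, each drawing 80%
of the samples without replacement and running k-means (k = 2, the high /
low immune-activation dichotomy is fixed by design) on gene-standardized
ICR expression. The consensus matrix holds co-clustering frequencies
among co-sampled rounds; final labels come from average-linkage
hierarchical clustering of `1 - consensus` cut at two, and the group with
the higher mean ICR expression is labelled *high*. The inner algorithm
had to be chosen (k-means) as did the final cut (hierarchical), matching
the behaviour of the standard consensus-clustering implementations.

## Pair acceptance

Differential ICPs and lncRNAs are crossed, and a pair is accepted when

* $|r| > 0.3$ (strict) with two-sided $p < 0.05$ from
  $t = r\sqrt{(n-2)/(1-r^2)}$, **and**
* its mutual information is significant at $p < 0.05$ under an empirical
  permutation null.

The MI estimator is a plug-in on equal-frequency (rank-based) bins with
$B = \lfloor\sqrt{n/5}\rfloor$ bins per axis (minimum 2), making it
invariant under monotone transforms. Because the plug-in estimate carries
the well-known positive bias $(B-1)^2/(2n\ln 2)$, raw MI values are never
thresholded directly; significance always comes from the permutation
null, $p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(n_\mathrm{perm}+1)$,
in which the bias cancels. P-values are not multiplicity-adjusted (the
screening rules are raw cutoffs); a Benjamini-Hochberg toggle is
available in the configuration. The *coincidence rate* — the fraction of
Pearson-accepted pairs confirmed by MI — is reported per cohort.

## Network analytics

Accepted pairs form a bipartite network. Scale-free behaviour is
summarized by the $R^2$ of an ordinary least-squares fit of
$\log_{10}(\mathrm{frequency})$ on $\log_{10}(\mathrm{degree})$; a flat
frequency profile is reported as $R^2 = 0$ (no trend explained). Hubs
are the top 5% of nodes by degree, boundary ties included, pooled across
the ICP and lncRNA sides; hubs recurring in more than five cohorts are
*common*, hubs of exactly one cohort *specific*, the rest *other*.
Cross-cohort similarity uses shared-entity counts normalized by the
smaller set (Jaccard is available via configuration), applied separately
to ICPs, lncRNAs, and pairs.

## Survival permutation screen

For each accepted pair: the cohort is split 50/50 (training takes the
extra sample at odd n); a multivariate Cox model with Efron tie handling
is fitted on the training half over the z-scored pair members plus age
and sex as confounders; held-out samples get the risk score
$\beta_1 z(x_\mathrm{ICP}) + \beta_2 z(x_\mathrm{lncRNA})$ with z-scoring
frozen at training statistics and confounder terms excluded; held-out
samples are dichotomized at the median score and compared by the
two-group log-rank test. The permutation null jointly permutes
`(os_time, os_event)` against the covariates — preserving the survival
marginal and the covariate correlation structure — while the split stays
fixed, isolating the outcome association. The empirical p-value uses the
add-one formula; failed null replicates (e.g. non-converged fits) are
discarded with the denominator adjusted. "Standardized coefficient" is
implemented as z-scored covariates (not coefficient/SE), and the log-rank
statistic (not the Cox Wald statistic) is the screened quantity, matching
the held-out Kaplan-Meier framing of the procedure.

Within the permutation loop the training design matrix and held-out
z-scores are precomputed once — they are invariant under outcome
permutation — and each replicate refits the Cox model through
`survival::coxph.fit` and recomputes a vectorized log-rank statistic;
both are verified against `survival::coxph` and `survival::survdiff` in
the tests.

## Response prediction

Features are either the per-sample enrichment score of the union of pair
member genes (min-max normalized) or per-pair mean expression; the
pair-level recipe is the default for model fitting since it preserves
per-pair information. The SVM is linear-kernel, soft margin (C = 1),
with feature standardization frozen at training statistics; responder
calls use the decision-value sign. The LASSO panel is L1-penalized
logistic regression with the penalty chosen by stratified 5-fold
cross-validated deviance under the one-standard-error rule — the
cross-validation-minimum penalty systematically retains an order of
magnitude more noise features, while `lambda.1se` meets the
selection-fidelity contract (at least two of three informative features,
at most five false ones, at n = 300). An all-zero selection is flagged,
not an error. ROC curves come from a full threshold sweep and the AUC
equals the Mann-Whitney statistic with half credit for ties; association
of predicted responders with ICR groups uses the two-sided Fisher exact
test.

# The synthetic-data generator

`sim_config()` defines a Gaussian log2-expression generative model — not
counts, since every statistic in the pipeline operates on normalized
log-scale values and preprocessing is out of scope:

* **Immune panels**: baseline Normal(5, 1); per cell type, a designated
  immune-high subset of the ICP/lncRNA genes shifted +2 log2 units;
  additive per-(gene, batch) offsets Normal(0, `batch_shift_sd`).
* **Tumor cohorts**: a latent infiltration score $u \sim N(0,1)$ per
  sample; ICR and immune-signature genes (and planted pair members)
  loaded on $u$ with slope `infiltration_effect`; planted pairs receive
  bivariate-normal residuals with correlation $\rho$, so $\rho$ is the
  *partial* correlation given infiltration and the model-implied total
  correlation is $(\rho\sigma^2 + \lambda^2)/(\sigma^2 + \lambda^2)$ —
  tests compare against that quantity. Survival is exponential with
  log-hazard $\sum_p \beta_p \cdot (\bar{x}_p - \overline{\bar{x}_p})$
  over prognostic pairs ($\bar{x}_p$ the pair mean expression; centering
  keeps the time scale interpretable), censored administratively at the
  empirical quantile matching `censor_rate` so the event fraction is
  exact. ICI response is Bernoulli with logit
  $\sum_p w_p \cdot z(\bar{x}_p)$; age is Normal(60, 10), sex
  Bernoulli(0.5).

The generator emulates the statistical structure the pipeline assumes —
planted co-expression, infiltration-driven signatures, outcome-linked
pairs — but not features of real tumor data such as count noise,
compositional effects, subtype structure, copy-number confounding, or
non-proportional hazards. Passing tests therefore demonstrate that the
procedures recover what they are designed to recover under their own
model assumptions; they do not certify performance on real cohorts.

# Numerical choices and degenerate inputs

* Percentile conventions are nearest-rank with boundary ties retained
  (conservative: keeps more samples); the high-infiltration cutoff is the
  k-th largest score with k = floor(0.75 n).
* All screening inequalities are strict, so an exact r = 0.30 pair is
  rejected.
* Ranking and hub ties are broken deterministically (gene id, boundary
  inclusion); hub counts use k = n − floor(0.95 n) computed with a small
  epsilon to avoid floating-point boundary errors.
* Constant vectors are correlation errors, not NA; constant genes carry
  zero weight in consensus clustering; a degenerate score range maps to
  0 under min-max normalization.
* Every stochastic stage derives its seed from the master seed and a
  stage label (`stage_seed`), so stages are individually reproducible
  and mutually independent.
* Unknown genes are explicit lookup errors — never silently classed as
  "other"; a gene set with no overlap with the matrix, or covering all
  of it, is an error naming the set.

# Problem sizes used in validation

The packaged validation study uses two simulated cohorts of 300 samples
with 20 planted pairs ($\rho = 0.6$), five prognostic pairs
($\beta = 0.8$) and three response-driving pairs (logit weight 2); the
survival screen runs at 200 permutations and its type-I error is
calibrated on 200 null pairs in a 100-sample cohort. These sizes give
sampling error small enough to resolve the planted effects while keeping
the full validation run in the low minutes on a single core; the
1000-permutation default of `pipeline_config()` is recommended for real
analyses.

# Known limitations

* The batch adjustment is per-(gene, cell-type) mean-centering — the
  minimal location adjustment; empirical-Bayes shrinkage is not
  implemented.
* The ICR panel and curated ICP list are user-supplied inputs (GMT /
  TSV); the package ships only synthetic placeholders generated by the
  simulator.
* Causal direction between ICP and lncRNA is deliberately out of scope;
  an accepted pair is a co-expression statement only.
* ssGSEA scores are per-sample rank statistics, so cross-cohort
  application recomputes features on the new cohort without cross-cohort
  batch correction.
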