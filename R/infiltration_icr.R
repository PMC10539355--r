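#' Single-sample gene-set enrichment scores
#'
#' Per-sample rank-walk enrichment statistic: for each sample, genes are
#' ranked by expression; walking down the ranking, an in-set empirical
#' distribution weighted by rank^weight and an unweighted out-set
#' distribution are accumulated, and the score is the sum of their
#' difference over all positions. Because only ranks enter, scores are
#' invariant to any strictly monotone transform of a sample's values.
#'
#' @param m expression matrix.
#' @param sets named list of gene sets; each must overlap the matrix genes
#'   and must not cover all of them.
#' @param weight rank-weight exponent (0.25 by default; 0 gives the
#'   unweighted Kolmogorov-Smirnov-style walk).
#' @param normalize if TRUE, min-max normalize each set's scores across
#'   samples to [0, 1] (a degenerate zero range maps to 0).
#' @return numeric matrix of scores, samples x sets.
#' @export
ssgsea_score <- function(m, sets, weight = 0.25, normalize = FALSE) {
  sets <- validate_gene_sets(sets)
  genes <- rownames(m)
  n <- length(genes)
  idx_sets <- lapply(names(sets), function(nm) {
    idx <- which(genes %in% sets[[nm]])
    if (!length(idx))
      stop("gene set '", nm, "' has no overlap with the expression matrix")
    if (length(idx) == n)
      stop("gene set '", nm, "' covers every gene; out-set is empty")
    idx
  })
  names(idx_sets) <- names(sets)
  scores <- matrix(NA_real_, nrow = ncol(m), ncol = length(sets),
                   dimnames = list(colnames(m), names(sets)))
  for (s in seq_len(ncol(m))) {
    x <- m[, s]
    r <- rank(x, ties.method = "average")  # high expression -> high rank
    ord <- order(r, decreasing = TRUE)
    for (k in seq_along(idx_sets)) {
      in_set <- logical(n)
      in_set[idx_sets[[k]]] <- TRUE
      in_ord <- in_set[ord]
      w <- abs(r[ord])^weight
      w[!in_ord] <- 0
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!in_ord) / sum(!in_ord)
      scores[s, k] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    for (k in seq_len(ncol(scores))) {
      rng <- range(scores[, k])
      scores[, k] <- if (diff(rng) == 0) 0 else
        (scores[, k] - rng[1]) / diff(rng)
    }
  }
  scores
}

#' Retain tumor samples with high immune scores
#'
#' Keeps the top fraction of samples by enrichment score (top 75% by
#' default). The cutoff is the k-th largest score with
#' k = floor(fraction * n); samples tied with the cutoff are retained,
#' so when all scores are equal every sample is kept.
#'
#' @param scores score matrix from [ssgsea_score()] (samples x sets).
#' @param set_name which set's scores to threshold.
#' @param cfg a [pipeline_config()]; uses `immune_score_quantile`.
#' @return character vector of retained sample ids, in input order.
#' @export
select_high_infiltration <- function(scores, set_name,
                                     cfg = pipeline_config()) {
  if (!set_name %in% colnames(scores))
    stop("no scores for set '", set_name, "'")
  x <- scores[, set_name]
  n <- length(x)
  if (n < 4) stop("need >= 4 samples to threshold immune scores")
  k <- floor(cfg$immune_score_quantile * n)
  cutoff <- sort(x, decreasing = TRUE)[k]
  rownames(scores)[x >= cutoff]
}

#' Consensus clustering of samples on the ICR signature
#'
#' Monti-style consensus clustering: repeated subsampling (default 100
#' rounds of 80% of samples without replacement), k-means with k = 2 on
#' gene-standardized ICR expression in each round, and a consensus matrix
#' of co-clustering frequencies among co-sampled rounds. Final labels come
#' from average-linkage hierarchical clustering of 1 - consensus cut at 2;
#' the group with the higher mean ICR expression is labelled `high`.
#'
#' @param m expression matrix restricted to the ICR panel genes
#'   (>= 2 genes, >= 8 samples).
#' @param cfg a [pipeline_config()]; uses `consensus_reps`,
#'   `consensus_frac`, `rng_seed`.
#' @param seed optional seed overriding the config-derived stream.
#' @return an `icr_grouping` list: `labels` (named character,
#'   `high`/`low`), `consensus` (samples x samples in [0, 1]), `k` (2).
#' @export
consensus_cluster_icr <- function(m, cfg = pipeline_config(), seed = NULL) {
  if (nrow(m) < 2) stop("need >= 2 ICR genes in the matrix")
  n <- ncol(m)
  if (n < 8) stop("need >= 8 samples for consensus clustering")
  z <- t(scale(t(unclass(m))))        # standardize genes
  z[!is.finite(z)] <- 0               # constant genes carry no signal
  x <- t(z)                           # samples as rows
  if (is.null(seed)) seed <- stage_seed(cfg$rng_seed, "consensus")
  co <- matrix(0, n, n)
  tog <- matrix(0, n, n)
  m_sub <- max(2L, floor(cfg$consensus_frac * n))
  with_seed(seed, {
    for (r in seq_len(cfg$consensus_reps)) {
      idx <- sample.int(n, m_sub)
      km <- kmeans(x[idx, , drop = FALSE], centers = 2, nstart = 3)
      same <- outer(km$cluster, km$cluster, "==")
      tog[idx, idx] <- tog[idx, idx] + 1
      co[idx, idx] <- co[idx, idx] + same
    }
  })
  cons <- ifelse(tog > 0, co / tog, 0)
  diag(cons) <- 1
  dimnames(cons) <- list(colnames(m), colnames(m))
  hc <- hclust(as.dist(1 - cons), method = "average")
  cl <- cutree(hc, k = 2)
  mean_icr <- colMeans(unclass(m))
  g1 <- mean(mean_icr[cl == 1])
  g2 <- mean(mean_icr[cl == 2])
  labels <- ifelse(cl == (if (g1 >= g2) 1 else 2), "high", "low")
  names(labels) <- colnames(m)
  if (!all(c("high", "low") %in% labels))
    stop("consensus clustering produced an empty group")
  structure(list(labels = labels, consensus = cons, k = 2L),
            class = "icr_grouping")
}

#' @export
print.icr_grouping <- function(x, ...) {
  cat("ICR consensus grouping:", sum(x$labels == "high"), "high /",
      sum(x$labels == "low"), "low samples\n")
  invisible(x)
}

#' Differential expression between high and low ICR groups
#'
#' Per-gene Welch two-sample t-test of log2 expression between the high
#' and low ICR groups; fold change is reported on the linear scale,
#' `2^(mean_high - mean_low)`. A gene is `up` when fold change > 1 at
#' p < alpha, `down` when fold change < 1 at p < alpha, otherwise `ns`.
#'
#' @param m expression matrix.
#' @param grouping an `icr_grouping` covering the matrix samples.
#' @param cfg a [pipeline_config()]; uses `alpha`.
#' @return a `de_table` data.frame with `gene_id`, `mean_high`,
#'   `mean_low`, `fold_change`, `p`, `direction`.
#' @export
differential_expression <- function(m, grouping, cfg = pipeline_config()) {
  stopifnot(inherits(grouping, "icr_grouping"))
  labs <- grouping$labels[colnames(m)]
  if (anyNA(labs)) stop("grouping missing for some samples")
  hi <- which(labs == "high")
  lo <- which(labs == "low")
  if (length(hi) < 2 || length(lo) < 2)
    stop("both ICR groups need >= 2 samples")
  mh <- rowMeans(m[, hi, drop = FALSE])
  ml <- rowMeans(m[, lo, drop = FALSE])
  p <- vapply(seq_len(nrow(m)), function(i) {
    xh <- m[i, hi]; xl <- m[i, lo]
    if (sd(xh) == 0 && sd(xl) == 0) return(if (mh[i] == ml[i]) 1 else 0)
    t.test(xh, xl)$p.value
  }, numeric(1))
  fc <- 2^(mh - ml)
  direction <- ifelse(p < cfg$alpha & fc > 1, "up",
                      ifelse(p < cfg$alpha & fc < 1, "down", "ns"))
  out <- data.frame(gene_id = rownames(m), mean_high = unname(mh),
                    mean_low = unname(ml), fold_change = unname(fc),
                    p = unname(p), direction = unname(direction),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_table", class(out))
  out
}
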