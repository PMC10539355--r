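#' Pearson correlation with two-sided t-test p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3), neither constant.
#' @return list with `r` and `p` (p from t = r * sqrt((n-2)/(1-r^2)) on
#'   n - 2 degrees of freedom, two-sided).
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need n >= 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p)
}

#' Mutual information in bits via equal-frequency binning
#'
#' Plug-in mutual information on a 2-d histogram with equal-frequency
#' (rank-based) bins, B = floor(sqrt(n / 5)) per axis, at least 2. The
#' rank-based binning makes the estimate invariant under strictly
#' monotone transforms of either input. With `binned = TRUE` the inputs
#' are treated as categorical labels and used directly as the joint
#' partition, which lets pre-binned contingency data be scored.
#'
#' @param x,y numeric vectors of equal length (n >= 10 when binning), or
#'   categorical labels when `binned = TRUE`.
#' @param n_bins optional bin count per axis; default floor(sqrt(n/5)),
#'   minimum 2.
#' @param binned treat inputs as already-discrete labels.
#' @return mutual information in bits (>= 0 up to floating-point error).
#' @export
mutual_information <- function(x, y, n_bins = NULL, binned = FALSE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (binned) {
    bx <- as.integer(factor(x)); by <- as.integer(factor(y))
  } else {
    if (n < 10) stop("need n >= 10 observations to bin")
    if (is.null(n_bins)) n_bins <- max(2L, floor(sqrt(n / 5)))
    if (n_bins < 2) stop("need at least 2 bins")
    if (n < 2 * n_bins) stop("too few observations for ", n_bins, " bins")
    bx <- ceiling(n_bins * rank(x, ties.method = "first") / n)
    by <- ceiling(n_bins * rank(y, ties.method = "first") / n)
  }
  mi_from_bins(bx, by)
}

# Plug-in MI (bits) from integer bin labels.
mi_from_bins <- function(bx, by) {
  n <- length(bx)
  bmax_x <- max(bx); bmax_y <- max(by)
  joint <- matrix(tabulate(bx + (by - 1L) * bmax_x, bmax_x * bmax_y),
                  nrow = bmax_x) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

#' Permutation p-value for mutual information
#'
#' Empirical null by permuting `y` and recomputing the MI estimator;
#' p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param x,y numeric vectors.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param n_bins optional bin count passed through.
#' @return list with `mi` (observed, bits) and `p`.
#' @export
mi_permutation_p <- function(x, y, n_perm = 100, seed = 1L, n_bins = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- length(x)
  if (n < 10) stop("need n >= 10 observations")
  if (is.null(n_bins)) n_bins <- max(2L, floor(sqrt(n / 5)))
  # the estimator is rank-binned, so permuting y is equivalent to permuting
  # its bin labels; binning once keeps the null loop cheap
  bx <- ceiling(n_bins * rank(x, ties.method = "first") / n)
  by <- ceiling(n_bins * rank(y, ties.method = "first") / n)
  obs <- mi_from_bins(bx, by)
  exceed <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      if (mi_from_bins(bx, sample(by)) >= obs) exceed <- exceed + 1L
    }
  })
  list(mi = obs, p = (1 + exceed) / (n_perm + 1))
}

#' Extract cooperatively regulated ICP-lncRNA pairs
#'
#' Evaluates every combination of the supplied (differentially expressed,
#' immune-related) ICPs and lncRNAs on two co-expression routes: Pearson
#' correlation (|r| > `pcc_abs_min`, strict, and p < alpha) and mutual
#' information (permutation p < alpha). A pair is accepted when it passes
#' both; accepted pairs carry a `positive`/`negative` sign from the
#' correlation.
#'
#' @param m expression matrix over the cohort samples.
#' @param de_icps,de_lncs character vectors of candidate ICP and lncRNA
#'   gene ids present in `m`.
#' @param cfg a [pipeline_config()]; uses `pcc_abs_min`, `alpha`,
#'   `mi_null_perms`, `bh_adjust`, `rng_seed`.
#' @param cohort cohort label stored in the table.
#' @return a `pair_table` data.frame sorted by cohort then |r|
#'   descending, with columns `cohort`, `icp_id`, `lnc_id`, `r`, `r_p`,
#'   `mi`, `mi_p`, `sign`, `in_pcc_set`, `in_mi_set`, `accepted`.
#' @export
extract_pairs <- function(m, de_icps, de_lncs, cfg = pipeline_config(),
                          cohort = "cohort") {
  if (!length(de_icps) || !length(de_lncs))
    stop("both gene lists must be non-empty")
  miss <- setdiff(c(de_icps, de_lncs), rownames(m))
  if (length(miss))
    stop("gene(s) absent from matrix: ", paste(miss, collapse = ", "))
  combos <- expand.grid(icp_id = de_icps, lnc_id = de_lncs,
                        stringsAsFactors = FALSE)
  n_pair <- nrow(combos)
  r <- r_p <- mi <- mi_p <- numeric(n_pair)
  for (k in seq_len(n_pair)) {
    x <- m[combos$icp_id[k], ]
    y <- m[combos$lnc_id[k], ]
    pc <- pearson_cor(x, y)
    r[k] <- pc$r; r_p[k] <- pc$p
    mp <- mi_permutation_p(x, y, n_perm = cfg$mi_null_perms,
                           seed = stage_seed(cfg$rng_seed,
                                             paste0("mi_", cohort, "_", k)))
    mi[k] <- mp$mi; mi_p[k] <- mp$p
  }
  if (cfg$bh_adjust) {
    r_p_use <- p.adjust(r_p, method = "BH")
    mi_p_use <- p.adjust(mi_p, method = "BH")
  } else {
    r_p_use <- r_p; mi_p_use <- mi_p
  }
  in_pcc <- abs(r) > cfg$pcc_abs_min & r_p_use < cfg$alpha
  in_mi <- mi_p_use < cfg$alpha
  accepted <- in_pcc & in_mi
  out <- data.frame(cohort = cohort, icp_id = combos$icp_id,
                    lnc_id = combos$lnc_id, r = r, r_p = r_p,
                    mi = mi, mi_p = mi_p,
                    sign = ifelse(r > 0, "positive", "negative"),
                    in_pcc_set = in_pcc, in_mi_set = in_mi,
                    accepted = accepted, stringsAsFactors = FALSE)
  out <- out[order(out$cohort, -abs(out$r)), ]
  rownames(out) <- NULL
  class(out) <- c("pair_table", class(out))
  out
}

#' Coincidence rate between the Pearson and MI routes
#'
#' Fraction of Pearson-accepted pairs that are also accepted by the
#' mutual-information criterion.
#'
#' @param pt a `pair_table`.
#' @return a fraction in [0, 1].
#' @export
coincidence_rate <- function(pt) {
  n_pcc <- sum(pt$in_pcc_set)
  if (n_pcc == 0) stop("coincidence rate undefined: PCC set is empty")
  sum(pt$in_pcc_set & pt$in_mi_set) / n_pcc
}

#' @importFrom stats p.adjust var
NULL
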