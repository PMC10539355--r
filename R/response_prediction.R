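#' Per-sample enrichment score of a set of pairs
#'
#' Scores each sample on the union of the member genes of the supplied
#' pairs with the single-sample enrichment statistic, then min-max
#' normalizes across samples to [0, 1] (a degenerate zero range maps to
#' 0). This is the comprehensive pair-level risk score used as the
#' default predictor feature.
#'
#' @param m expression matrix.
#' @param pairs data.frame with `icp` and `lnc` columns (>= 1 row).
#' @param weight rank-weight exponent passed to [ssgsea_score()].
#' @return named numeric vector of scores in [0, 1], one per sample.
#' @export
pair_set_score <- function(m, pairs, weight = 0.25) {
  pairs <- as.data.frame(pairs)
  if (!nrow(pairs)) stop("need >= 1 pair")
  genes <- unique(c(pairs$icp, pairs$lnc))
  genes <- intersect(genes, rownames(m))
  if (!length(genes)) stop("pair genes have no overlap with the matrix")
  raw <- ssgsea_score(m, list(pairset = genes), weight = weight,
                      normalize = TRUE)
  setNames(raw[, "pairset"], rownames(raw))
}

#' Per-pair mean-expression features
#'
#' For each pair, the feature is the mean of the two members' log2
#' expression per sample — the pair-level feature recipe offered
#' alongside the aggregate enrichment score.
#'
#' @param m expression matrix.
#' @param pairs data.frame with `icp` and `lnc` columns.
#' @return numeric matrix, samples x pairs; columns named `icp|lnc`.
#' @export
pair_mean_features <- function(m, pairs) {
  pairs <- as.data.frame(pairs)
  if (!nrow(pairs)) stop("need >= 1 pair")
  miss <- setdiff(c(pairs$icp, pairs$lnc), rownames(m))
  if (length(miss)) stop("gene(s) absent from matrix: ",
                         paste(miss, collapse = ", "))
  feats <- vapply(seq_len(nrow(pairs)), function(k)
    (m[pairs$icp[k], ] + m[pairs$lnc[k], ]) / 2,
    numeric(ncol(m)))
  colnames(feats) <- paste(pairs$icp, pairs$lnc, sep = "|")
  rownames(feats) <- colnames(m)
  feats
}

#' Train a linear SVM response classifier
#'
#' Linear-kernel soft-margin support vector machine on standardized
#' features (training means and standard deviations are frozen into the
#' model, so evaluation data never influences the fit). Responder calls
#' use the sign of the decision value.
#'
#' @param features numeric matrix (samples x features) or vector.
#' @param labels factor or character with two classes
#'   (`responder`/`non_responder`) aligned with rows.
#' @param cost soft-margin cost parameter (1).
#' @param seed integer seed (the fit itself is deterministic; the seed
#'   fixes any internal shuffling).
#' @return a `response_model` of kind `"svm"`.
#' @export
train_svm <- function(features, labels, cost = 1, seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) < 10) stop("need >= 10 training samples")
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("labels must contain exactly two classes")
  center <- colMeans(features)
  scl <- apply(features, 2, sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(features, 2, center), 2, scl, "/")
  fit <- with_seed(seed, e1071::svm(x = z, y = labels, kernel = "linear",
                                    cost = cost, scale = FALSE,
                                    probability = FALSE))
  structure(list(kind = "svm", fit = fit, center = center, scale = scl,
                 feature_names = colnames(features),
                 positive_class = levels(labels)[2],
                 levels = levels(labels)),
            class = "response_model")
}

#' LASSO selection of predictive pairs
#'
#' L1-penalized logistic regression over per-pair features with the
#' penalty chosen by stratified k-fold cross-validated deviance under the
#' one-standard-error rule; the selected pairs are those with nonzero
#' coefficients at that penalty. An all-zero selection is flagged, not an error.
#'
#' @param pair_features numeric matrix (samples x pair features,
#'   >= 2 columns).
#' @param labels two-class factor/character aligned with rows.
#' @param n_folds cross-validation folds (5).
#' @param seed integer seed controlling fold assignment.
#' @param lambda optional fixed penalty overriding cross-validation.
#' @return a `response_model` of kind `"lasso"` with `selected`
#'   (character vector of nonzero features) and `empty_selection` flag.
#' @export
lasso_select <- function(pair_features, labels, n_folds = 5, seed = 1L,
                         lambda = NULL) {
  pair_features <- as.matrix(pair_features)
  if (ncol(pair_features) < 2) stop("need >= 2 candidate pair features")
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must contain exactly two classes")
  y <- as.integer(labels) - 1L
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cl in 0:1) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(pair_features, y, family = "binomial",
                            foldid = foldid, type.measure = "deviance")
    # one-standard-error rule: the sparsest model within one SE of the
    # minimum cross-validated deviance
    co <- coef(cv, s = "lambda.1se")
  } else {
    cv <- glmnet::glmnet(pair_features, y, family = "binomial")
    co <- coef(cv, s = lambda, exact = FALSE)
  }
  beta <- as.numeric(co)[-1]
  names(beta) <- rownames(co)[-1]
  selected <- names(beta)[beta != 0]
  structure(list(kind = "lasso", fit = cv, intercept = as.numeric(co)[1],
                 beta = beta, selected = selected,
                 empty_selection = length(selected) == 0,
                 feature_names = colnames(pair_features),
                 positive_class = levels(labels)[2],
                 levels = levels(labels)),
            class = "response_model")
}

#' Predict response calls and decision scores
#'
#' @param object a `response_model`.
#' @param newdata feature matrix with the training feature columns.
#' @param ... unused.
#' @return data.frame with `score` (decision value or probability) and
#'   `call` (predicted class; sign threshold for SVM, probability 0.5
#'   for LASSO).
#' @export
predict.response_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    if (!all(object$feature_names %in% colnames(newdata)))
      stop("newdata is missing trained feature column(s)")
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  if (object$kind == "svm") {
    z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
    pr <- predict(object$fit, z, decision.values = TRUE)
    dv <- as.numeric(attr(pr, "decision.values"))
    # orient the decision value toward the positive class
    lab <- colnames(attr(pr, "decision.values"))[1]
    if (!startsWith(lab, object$positive_class)) dv <- -dv
    call <- ifelse(dv > 0, object$positive_class,
                   setdiff(object$levels, object$positive_class))
  } else {
    eta <- object$intercept + as.numeric(newdata %*% object$beta)
    dv <- plogis(eta)
    call <- ifelse(dv > 0.5, object$positive_class,
                   setdiff(object$levels, object$positive_class))
  }
  data.frame(sample_id = rownames(newdata) %||% seq_len(nrow(newdata)),
             score = dv, call = call, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps all unique score thresholds to trace the ROC curve; the area
#' equals the Mann-Whitney probability that a positive outranks a
#' negative, with ties credited 0.5.
#'
#' @param scores numeric vector.
#' @param labels two-class vector; the second factor level (or `positive`)
#'   is the positive class.
#' @param positive optional positive class label.
#' @return a `roc_curve` list with `points` (data.frame `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- levels(labels)[2]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t0) {
    c(fpr = sum(scores[!pos] >= t0) / n_neg,
      tpr = sum(scores[pos] >= t0) / n_pos)
  }, numeric(2)))
  # Mann-Whitney with half credit for ties
  rk <- rank(scores)
  auc <- (sum(rk[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(points = as.data.frame(pts), auc = auc,
                 positive = positive),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve (positive = %s): AUC = %.4f\n", x$positive, x$auc))
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' @param tab 2x2 non-negative integer matrix with positive margins.
#' @return list with `odds_ratio` (conditional MLE) and `p` (two-sided,
#'   summing hypergeometric tables at most as probable as the observed).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must hold non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero margin")
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Compare predicted response calls with ICR groups
#'
#' Cross-tabulates predicted responder / non-responder calls against
#' high / low ICR groups over the shared samples and applies the
#' two-sided Fisher exact test.
#'
#' @param predictions data.frame from [predict.response_model()] with
#'   `sample_id` and `call`.
#' @param grouping an `icr_grouping`.
#' @return list with `table` (2x2) and `fisher` (odds ratio + p).
#' @export
compare_predictions_to_icr <- function(predictions, grouping) {
  stopifnot(inherits(grouping, "icr_grouping"))
  shared <- intersect(predictions$sample_id, names(grouping$labels))
  if (!length(shared)) stop("no shared samples between predictions and grouping")
  call <- predictions$call[match(shared, predictions$sample_id)]
  icr <- grouping$labels[shared]
  tab <- table(factor(call, levels = c("responder", "non_responder")),
               factor(icr, levels = c("high", "low")))
  list(table = tab, fisher = fisher_exact_2x2(tab))
}
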