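test_that("pair-set scores are normalized enrichment scores", {
  m <- random_matrix(60, 10, seed = 3)
  pairs <- data.frame(icp = c("g001", "g002"), lnc = c("g010", "g011"))
  sc <- pair_set_score(m, pairs)
  expect_true(all(sc >= 0 & sc <= 1))
  # oracle recomposition: raw enrichment + min-max
  raw <- ssgsea_score(m, list(u = unique(c(pairs$icp, pairs$lnc))))[, "u"]
  mm <- (raw - min(raw)) / (max(raw) - min(raw))
  expect_equal(unname(sc), unname(mm), tolerance = 1e-9)
  # identical samples: degenerate range maps to 0
  flat <- expression_matrix(matrix(rep(seq_len(60), 4), ncol = 4,
                                   dimnames = list(rownames(m),
                                                   paste0("f", 1:4))))
  expect_true(all(pair_set_score(flat, pairs) == 0))
  # a sample with the pair genes top-ranked outscores one with them bottom-ranked
  v <- matrix(5, nrow = 60, ncol = 2,
              dimnames = list(rownames(m), c("top", "bottom")))
  v[, 1] <- seq(1, 2, length.out = 60)
  v[, 2] <- seq(2, 1, length.out = 60)
  genes <- c("g001", "g002", "g010", "g011")
  v[genes, 1] <- 10; v[genes, 2] <- 0
  sc2 <- pair_set_score(expression_matrix(v), pairs)
  expect_gt(sc2[["top"]], sc2[["bottom"]])
})

test_that("the linear SVM separates blobs and is affine-invariant in features", {
  set.seed(7)
  n <- 50
  f <- cbind(a = c(rnorm(n), rnorm(n, 6)), b = c(rnorm(n), rnorm(n, 6)))
  rownames(f) <- sprintf("s%03d", seq_len(2 * n))
  labels <- rep(c("non_responder", "responder"), each = n)
  mod <- train_svm(f, labels, seed = 1)
  pred <- predict(mod, f)
  expect_equal(mean(pred$call == labels), 1.0)
  # responder calls carry positive decision scores
  expect_true(all(pred$score[pred$call == "responder"] > 0))
  # affine rescaling of an input feature changes nothing (standardization)
  f2 <- f; f2[, "a"] <- f2[, "a"] * 1000 - 77
  mod2 <- train_svm(f2, labels, seed = 1)
  expect_equal(predict(mod2, f2)$call, pred$call)
  expect_error(train_svm(f, rep("responder", 2 * n)), "two classes")
})

test_that("shuffled labels yield chance-level held-out AUC", {
  set.seed(8)
  aucs <- replicate(20, {
    n <- 60
    f <- cbind(x = rnorm(2 * n), y = rnorm(2 * n))
    labels <- sample(rep(c("non_responder", "responder"), n))
    tr <- seq_len(n); te <- n + seq_len(n)
    mod <- train_svm(f[tr, ], labels[tr], seed = 1)
    roc_auc(predict(mod, f[te, ])$score, labels[te],
            positive = "responder")$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("LASSO keeps informative pair features and obeys the penalty limit", {
  set.seed(9)
  n <- 300
  p <- 50
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("pair", 1:p)))
  eta <- 1.5 * X[, 1] + 1.5 * X[, 2] + 1.5 * X[, 3]
  y <- ifelse(rbinom(n, 1, plogis(eta)) == 1, "responder", "non_responder")
  mod <- lasso_select(X, y, seed = 2)
  informative <- paste0("pair", 1:3)
  expect_gte(sum(informative %in% mod$selected), 2)
  expect_lte(sum(!mod$selected %in% informative), 5)
  expect_false(mod$empty_selection)
  # an overwhelming penalty shrinks everything away, flagged not errored
  mod_inf <- lasso_select(X, y, seed = 2, lambda = 1e6)
  expect_true(mod_inf$empty_selection)
  expect_length(mod_inf$selected, 0)
  # duplicating an informative feature barely moves prediction
  X2 <- cbind(X, pair_dup = X[, 1])
  mod_dup <- lasso_select(X2, y, seed = 2)
  auc1 <- roc_auc(predict(mod, X)$score, y, positive = "responder")$auc
  auc2 <- roc_auc(predict(mod_dup, X2)$score, y, positive = "responder")$auc
  expect_lt(abs(auc1 - auc2), 0.02)
})

test_that("ROC/AUC equals the exhaustive pair-counting oracle", {
  rc <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), positive = "1")
  expect_equal(rc$auc, 0.75)
  expect_equal(rc$auc, auc_oracle(c(0.1, 0.4, 0.35, 0.8),
                                  c(0, 0, 1, 1), "1"))
  # perfect separation and all-tied scores
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = "1")$auc, 1.0)
  expect_equal(roc_auc(rep(1, 6), rep(c(0, 1), 3), positive = "1")$auc, 0.5)
  # property over random small instances, ties included
  set.seed(10)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    lab <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(sc, lab, positive = "1")$auc,
                 auc_oracle(sc, lab, "1"), tolerance = 1e-12)
  }
  # curve is monotone in both axes and consistent with its AUC
  expect_true(all(diff(rc$points$fpr) >= 0))
  expect_true(all(diff(rc$points$tpr) >= 0))
})

test_that("Fisher exact matches full hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2))$p, 1.0)
  tab <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(fisher_exact_2x2(tab)$p, fisher_oracle(tab), tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(tab)$p, 2 / choose(10, 5), tolerance = 1e-9)
  # transposition symmetry
  t2 <- matrix(c(7, 2, 3, 8), 2)
  expect_equal(fisher_exact_2x2(t2)$p, fisher_exact_2x2(t(t2))$p)
  expect_equal(fisher_exact_2x2(t2)$p, fisher_oracle(t2), tolerance = 1e-9)
  set.seed(11)
  for (i in 1:20) {
    tb <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher_exact_2x2(tb)$p, fisher_oracle(tb), tolerance = 1e-8)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 1), 2)), "zero margin")
})

test_that("prediction vs ICR cross-tabulation recounts correctly", {
  labels <- setNames(rep(c("high", "low"), each = 10), sprintf("s%02d", 1:20))
  grouping <- structure(list(labels = labels, consensus = diag(20), k = 2L),
                        class = "icr_grouping")
  # predictions identical to ICR: off-diagonal zeros, tiny p
  preds <- data.frame(sample_id = names(labels),
                      call = ifelse(labels == "high", "responder",
                                    "non_responder"))
  res <- compare_predictions_to_icr(preds, grouping)
  expect_equal(as.vector(res$table), c(10, 0, 0, 10))
  expect_lt(res$fisher$p, 0.001)
  # brute-force recount on a mixed assignment
  set.seed(12)
  preds2 <- data.frame(sample_id = names(labels),
                       call = sample(c("responder", "non_responder"), 20,
                                     replace = TRUE))
  res2 <- compare_predictions_to_icr(preds2, grouping)
  manual <- sum(preds2$call == "responder" & labels == "high")
  expect_equal(res2$table["responder", "high"], manual)
})
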