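test_that("quantile normalization equalizes column distributions", {
  m <- toy_matrix(genes = c("g1", "g2", "g3"), samples = c("s1", "s2"),
                  values = matrix(c(1, 2, 3, 4, 5, 6), nrow = 3))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "s2"]), c(2.5, 3.5, 4.5))
  # fixed point: already-identical columns are unchanged
  m2 <- toy_matrix(genes = c("g1", "g2"), samples = c("s1", "s2"),
                   values = matrix(c(1, 5, 1, 5), nrow = 2))
  expect_equal(unclass(quantile_normalize(m2)), unclass(m2))
  # defining property on arbitrary input
  m3 <- random_matrix(40, 6, seed = 8)
  qn3 <- quantile_normalize(m3)
  sorted <- apply(qn3, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  expect_error(quantile_normalize(m3[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("batch adjustment removes additive offsets exactly", {
  m <- random_matrix(30, 12, seed = 9)
  ann <- data.frame(sample_id = colnames(m), cell_type = "CT1",
                    batch = rep(c("B1", "B2"), each = 6))
  # single batch: identity
  ann1 <- ann; ann1$batch <- "B1"
  expect_equal(unclass(adjust_batches(m, ann1)), unclass(m),
               tolerance = 1e-12)
  # constant +5 offset on batch 2 vanishes exactly
  shifted <- unclass(m)
  shifted[, 7:12] <- shifted[, 7:12] + 5
  adj <- adjust_batches(expression_matrix(shifted), ann)
  d <- rowMeans(adj[, 1:6]) - rowMeans(adj[, 7:12])
  expect_lt(max(abs(d)), 1e-12)
  # per-cell-type gene means are preserved
  expect_equal(rowMeans(adj), rowMeans(shifted), tolerance = 1e-12)
  expect_error(adjust_batches(m, transform(ann, batch = NA)), "batch")
})

test_that("batch adjustment collapses the between-batch variance component", {
  cfg <- sim_config(seed = 12, samples_per_cell_type = 10, n_batches = 3,
                    batch_shift_sd = 1)
  out <- simulate_immune_panel(cfg)
  ann <- out$annotation
  between_batch_var <- function(m) {
    ct1 <- ann$cell_type == "CT01"
    mean(vapply(rownames(m), function(g) {
      var(tapply(m[g, ct1], ann$batch[ct1], mean))
    }, numeric(1)))
  }
  before <- between_batch_var(out$expr)
  after <- between_batch_var(adjust_batches(out$expr, ann))
  expect_gt(before, 0.5)        # injected component is visible
  expect_lt(after, 1e-20)       # mean-centering removes it exactly
})

test_that("within-class ranking is deterministic and sample-order invariant", {
  m <- toy_matrix(genes = c("hi", "lo"), samples = c("s1", "s2"),
                  values = matrix(c(9, 1, 9, 1), nrow = 2))
  ann <- data.frame(sample_id = c("s1", "s2"), cell_type = "CT1")
  classes <- gene_class_map(lncrna = c("hi", "lo"))
  rt <- rank_by_cell_type(m, ann, classes)
  expect_equal(rt$quantile[rt$gene_id == "hi"], 1.0)
  expect_equal(rt$quantile[rt$gene_id == "lo"], 0.5)
  # ties resolved by lexicographic gene id; quantiles stay a permutation
  mt <- toy_matrix(genes = c("b", "a"), samples = c("s1", "s2"),
                   values = matrix(c(3, 3, 3, 3), nrow = 2))
  rtt <- rank_by_cell_type(mt, ann, gene_class_map(lncrna = c("a", "b")))
  expect_equal(sort(rtt$quantile), c(0.5, 1.0))
  expect_equal(rtt$quantile[rtt$gene_id == "a"], 1.0)
  # permuting samples leaves the table unchanged
  m3 <- random_matrix(20, 10, seed = 5)
  ann3 <- data.frame(sample_id = colnames(m3),
                     cell_type = rep(c("A", "B"), 5))
  cls3 <- gene_class_map(icp = rownames(m3)[1:8],
                         lncrna = rownames(m3)[9:20])
  perm <- sample(ncol(m3))
  r_a <- rank_by_cell_type(m3, ann3, cls3)
  r_b <- rank_by_cell_type(
    expression_matrix(unclass(m3)[, perm]), ann3[perm, ], cls3)
  r_b <- r_b[order(r_b$cell_type, r_b$class, r_b$gene_id), ]
  r_a <- r_a[order(r_a$cell_type, r_a$class, r_a$gene_id), ]
  rownames(r_a) <- rownames(r_b) <- NULL
  expect_equal(r_a, r_b)
})

# rank table with controlled high counts: gene high in `k` of 18 cell types
synthetic_rank_table <- function(counts_lnc, n_ct = 18) {
  rows <- list()
  for (ct in seq_len(n_ct)) {
    for (g in names(counts_lnc)) {
      q <- if (ct <= counts_lnc[[g]]) 1.0 else 0.25
      rows[[paste(ct, g)]] <- data.frame(
        gene_id = g, cell_type = paste0("CT", ct), class = "lncRNA",
        mean_expr = q, rank = 1, quantile = q, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rank_table", class(out))
  out
}

test_that("immune-specific and immune-general lncRNA rules follow the cell-type counts", {
  rt <- synthetic_rank_table(list(gen10 = 10, mid5 = 5, spec1 = 1))
  sel <- select_immune_high(rt)
  expect_identical(sel$immune_general_lncs, "gen10")   # 10 of 18 > 9
  expect_identical(sel$immune_specific_lncs, "spec1")  # exactly one
  expect_false("mid5" %in% sel$selected_lncs)          # rule gap: 2..9
  expect_identical(sel$selected_lncs, c("gen10", "spec1"))
})

test_that("immune screen recovers planted immune-high genes on a seeded panel", {
  cfg <- sim_config(seed = 14, samples_per_cell_type = 50, n_batches = 2,
                    batch_shift_sd = 0.5)
  out <- simulate_immune_panel(cfg)
  adj <- adjust_batches(quantile_normalize(out$expr), out$annotation)
  classes <- sim_gene_annotation(cfg)$classes
  rt <- rank_by_cell_type(adj, out$annotation, classes)
  pcfg <- pipeline_config()
  high <- rt[rt$quantile > pcfg$high_expr_quantile, ]
  recovered <- 0; total <- 0
  for (ct in names(out$truth$immune_high)) {
    planted <- out$truth$immune_high[[ct]]
    total <- total + length(planted)
    recovered <- recovered +
      sum(planted %in% high$gene_id[high$cell_type == ct])
  }
  expect_gte(recovered / total, 0.95)
  # monotonicity: a stricter quantile never adds genes
  sel_05 <- select_immune_high(rt, pipeline_config(high_expr_quantile = 0.5))
  sel_07 <- select_immune_high(rt, pipeline_config(high_expr_quantile = 0.7))
  expect_true(all(sel_07$high_icps %in% sel_05$high_icps))
  # scale invariance: selection depends on the rank table only
  rt2 <- rt; rt2$mean_expr <- rt2$mean_expr * 100
  expect_identical(select_immune_high(rt2)$high_icps, sel_05$high_icps)
})

test_that("with no planted structure the specific fraction matches the binomial null", {
  cfg <- sim_config(seed = 15, n_cell_types = 4, samples_per_cell_type = 5,
                    n_immune_high = 0, n_lnc = 200, n_icp = 2,
                    batch_shift_sd = 0, n_batches = 1)
  out <- simulate_immune_panel(cfg)
  classes <- sim_gene_annotation(cfg)$classes
  rt <- rank_by_cell_type(out$expr, out$annotation, classes)
  sel <- select_immune_high(rt)
  frac_specific <- length(sel$immune_specific_lncs) / cfg$n_lnc
  p_null <- 4 * 0.5^4                      # exactly 1 of 4 types at p = 1/2
  mc_err <- 3 * sqrt(p_null * (1 - p_null) / cfg$n_lnc)
  expect_lt(abs(frac_specific - p_null), mc_err + 0.02)
})
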