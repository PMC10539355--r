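test_that("cohort splitting is balanced, exhaustive, and deterministic", {
  ids <- sprintf("s%02d", 1:40)
  sp <- split_cohort(ids, seed = 5)
  expect_length(sp$train, 20)
  expect_length(sp$heldout, 20)
  expect_setequal(c(sp$train, sp$heldout), ids)
  expect_length(intersect(sp$train, sp$heldout), 0)
  sp41 <- split_cohort(c(ids, "s41"), seed = 5)
  expect_length(sp41$train, 21)
  expect_length(sp41$heldout, 20)
  expect_identical(split_cohort(ids, seed = 5), sp)
  expect_false(identical(split_cohort(ids, seed = 6), sp))
  expect_error(split_cohort(ids[1:10]), ">= 20")
})

# exponential survival with hazard exp(b1 z1 + b2 z2) on standardized genes
cox_sim <- function(n, b1, b2, seed, censor = 0) {
  set.seed(seed)
  x1 <- rnorm(n, 5); x2 <- rnorm(n, 5)
  lp <- b1 * scale(x1)[, 1] + b2 * scale(x2)[, 1]
  t_raw <- rexp(n, exp(lp))
  event <- rep(1L, n)
  if (censor > 0) {
    cp <- quantile(t_raw, 1 - censor)
    event <- as.integer(t_raw <= cp)
    t_raw <- pmin(t_raw, cp)
  }
  ids <- sprintf("p%04d", 1:n)
  vals <- rbind(ICP_A = x1, LNC_B = x2,
                OTHER = rnorm(n, 5))
  colnames(vals) <- ids
  list(m = expression_matrix(vals),
       ann = data.frame(sample_id = ids, os_time = t_raw, os_event = event,
                        age = rnorm(n, 60, 10), sex = rbinom(n, 1, 0.5)))
}

test_that("Cox coefficients recover the generative betas on uncensored data", {
  d <- cox_sim(500, 0.7, 0.5, seed = 21)
  fit <- fit_cox_pair(d$m, d$ann, list(icp = "ICP_A", lnc = "LNC_B"),
                      train = d$ann$sample_id)
  expect_true(fit$converged)
  expect_lt(abs(fit$coef[["icp"]] - 0.7), 0.15)
  expect_lt(abs(fit$coef[["lnc"]] - 0.5), 0.15)
  # constant covariate is rejected
  d2 <- cox_sim(100, 0, 0, seed = 22)
  ann2 <- d2$ann; ann2$sex <- 1
  expect_error(fit_cox_pair(d2$m, ann2, list(icp = "ICP_A", lnc = "LNC_B"),
                            ann2$sample_id), "constant covariate")
})

test_that("null Cox estimates stay within sampling error", {
  hits <- 0
  for (s in 1:40) {
    d <- cox_sim(150, 0, 0, seed = 100 + s)
    fit <- fit_cox_pair(d$m, d$ann, list(icp = "ICP_A", lnc = "LNC_B"),
                        d$ann$sample_id)
    # roughly |beta| < 3 SE with SE ~ 1/sqrt(events)
    if (abs(fit$coef[["icp"]]) < 3 / sqrt(fit$n_events)) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.9)
})

test_that("risk scores are the frozen-standardization linear form", {
  d <- cox_sim(200, 0.7, 0.5, seed = 23)
  sp <- split_cohort(d$ann$sample_id, seed = 1)
  fit <- fit_cox_pair(d$m, d$ann, list(icp = "ICP_A", lnc = "LNC_B"),
                      sp$train)
  sc <- risk_score(d$m, fit, sp$heldout, list(icp = "ICP_A", lnc = "LNC_B"))
  # per-sample loop oracle
  oracle <- vapply(sp$heldout, function(s) {
    fit$coef[["icp"]] * (d$m["ICP_A", s] - fit$center[["icp"]]) /
      fit$scale[["icp"]] +
    fit$coef[["lnc"]] * (d$m["LNC_B", s] - fit$center[["lnc"]]) /
      fit$scale[["lnc"]]
  }, numeric(1))
  expect_equal(sc, oracle, tolerance = 1e-12)
  # zero coefficients give all-zero scores
  fit0 <- fit
  fit0$coef[c("icp", "lnc")] <- 0
  expect_true(all(risk_score(d$m, fit0, sp$heldout,
                             list(icp = "ICP_A", lnc = "LNC_B")) == 0))
})

test_that("log-rank matches the hand-worked table and the fast path matches survdiff", {
  # two groups of six with hand-checkable event pattern
  time <- c(1, 2, 3, 4, 5, 6, 1.5, 2.5, 3.5, 7, 8, 9)
  event <- c(1, 1, 1, 0, 1, 1, 1, 0, 1, 1, 1, 0)
  grp <- rep(c(TRUE, FALSE), each = 6)
  ids <- sprintf("h%02d", 1:12)
  ann <- data.frame(sample_id = ids, os_time = time, os_event = event)
  scores <- setNames(ifelse(grp, 1, -1), ids)
  res <- logrank_by_median(scores, ann)
  expect_equal(res$chi2, logrank_oracle(time, event, grp), tolerance = 1e-9)
  # identical survival in both strata: statistic is zero
  ann2 <- data.frame(sample_id = ids,
                     os_time = rep(c(1, 2, 3, 4, 5, 6), 2),
                     os_event = rep(c(1, 1, 0, 1, 0, 1), 2))
  res2 <- logrank_by_median(scores, ann2)
  expect_equal(res2$chi2, 0, tolerance = 1e-9)
  # internal fast statistic is survdiff's statistic
  set.seed(31)
  for (i in 1:25) {
    n <- sample(12:60, 1)
    tm <- round(rexp(n), 2)
    ev <- rbinom(n, 1, 0.7)
    g <- rbinom(n, 1, 0.5) == 1
    if (sum(g) < 2 || sum(!g) < 2 || sum(ev) < 1) next
    expect_equal(icplnc:::logrank_chi2_fast(tm, ev, g),
                 survival::survdiff(survival::Surv(tm, ev) ~ g)$chisq,
                 tolerance = 1e-9)
  }
})

test_that("a strong planted effect separates held-out risk halves", {
  p_small <- 0
  for (s in 1:10) {
    d <- cox_sim(200, 1.1, 0, seed = 300 + s)
    sp <- split_cohort(d$ann$sample_id, seed = s)
    fit <- fit_cox_pair(d$m, d$ann, list(icp = "ICP_A", lnc = "LNC_B"),
                        sp$train)
    sc <- risk_score(d$m, fit, sp$heldout,
                     list(icp = "ICP_A", lnc = "LNC_B"))
    lr <- logrank_by_median(sc, d$ann)
    if (lr$p < 0.01) p_small <- p_small + 1
    # direction: the high-score stratum dies faster
    ho <- d$ann[match(names(sc), d$ann$sample_id), ]
    expect_lt(median(ho$os_time[lr$high_risk]),
              median(ho$os_time[!lr$high_risk]))
  }
  expect_gte(p_small, 9)
})

test_that("the permutation screen flags planted pairs and reports the add-one p", {
  d <- cox_sim(150, 1.0, 0.6, seed = 41, censor = 0.2)
  cfg <- pipeline_config(n_survival_perms = 99, rng_seed = 2)
  mo <- permutation_screen(d$m, d$ann, list(icp = "ICP_A", lnc = "LNC_B"),
                           cfg, seed = 11)
  expect_true(mo$prognostic)
  expect_equal(mo$perm_p, 1 / (99 - mo$n_failed_perms + 1))
  expect_equal(mo$n_train + mo$n_test, 150)
  # time-unit invariance: rescaling days to months leaves perm_p unchanged
  ann_m <- d$ann; ann_m$os_time <- ann_m$os_time * 30.44
  mo_m <- permutation_screen(d$m, ann_m, list(icp = "ICP_A", lnc = "LNC_B"),
                             cfg, seed = 11)
  expect_equal(mo_m$perm_p, mo$perm_p)
  # a null pair is not flagged here
  d0 <- cox_sim(150, 0, 0, seed = 42)
  mo0 <- permutation_screen(d0$m, d0$ann, list(icp = "ICP_A", lnc = "LNC_B"),
                            cfg, seed = 12)
  expect_gt(mo0$perm_p, 0.05)
})

test_that("cross-cohort summaries recount prognostic flags", {
  mk_model <- function(icp, lnc, cohort, prog) {
    structure(list(cohort = cohort, pair = list(icp = icp, lnc = lnc),
                   prognostic = prog), class = "risk_model")
  }
  models <- list(mk_model("I1", "L1", "BRCA", TRUE),
                 mk_model("I1", "L1", "SKCM", TRUE),
                 mk_model("I1", "L1", "LUSC", TRUE),
                 mk_model("I2", "L2", "BRCA", TRUE),
                 mk_model("I3", "L3", "BRCA", FALSE))
  cs <- cross_cohort_summary(models)
  expect_equal(cs$table$n_cohorts[cs$table$pair == "I1|L1"], 3)
  expect_equal(cs$table$n_cohorts[cs$table$pair == "I2|L2"], 1)
  expect_false("I3|L3" %in% cs$table$pair)
  expect_equal(unname(cs$histogram[c("1", "3")]), c(1L, 1L))
  # no prognostic pairs: empty table with the right columns
  cs0 <- cross_cohort_summary(list(mk_model("I3", "L3", "BRCA", FALSE)))
  expect_equal(nrow(cs0$table), 0)
  expect_named(cs0$table, c("pair", "n_cohorts", "cohorts"))
})
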