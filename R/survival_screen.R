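#' Randomly split a cohort into training and held-out halves
#'
#' 50/50 split; with an odd sample count the training half receives the
#' extra sample. Deterministic for a given seed.
#'
#' @param sample_ids character vector (>= 20 samples).
#' @param seed integer seed.
#' @return list with `train` and `heldout` character vectors (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(sample_ids, seed = 1L) {
  n <- length(sample_ids)
  if (n < 20) stop("need >= 20 samples to split")
  with_seed(seed, {
    perm <- sample(sample_ids)
  })
  n_train <- ceiling(n / 2)
  list(train = perm[seq_len(n_train)], heldout = perm[-seq_len(n_train)])
}

#' Fit a confounder-adjusted Cox model for one pair
#'
#' Multivariate Cox proportional-hazards regression of overall survival on
#' the pair's standardized expression (ICP and lncRNA z-scored with
#' training statistics) plus age and sex as confounders, Efron tie
#' handling. Samples with missing age or sex are dropped with a count.
#'
#' @param m expression matrix.
#' @param ann sample annotation with `os_time`, `os_event`, `age`, `sex`.
#' @param pair list or one-row data.frame with `icp` and `lnc` gene ids.
#' @param train character vector of training sample ids.
#' @return list with `coef` (named: icp, lnc, age, sex), `center`/`scale`
#'   (training standardization of the two genes), `converged`,
#'   `n_dropped`, `n_events`.
#' @export
fit_cox_pair <- function(m, ann, pair, train) {
  pair <- as.list(pair)
  miss <- setdiff(c(pair$icp, pair$lnc), rownames(m))
  if (length(miss)) stop("gene(s) absent from matrix: ",
                         paste(miss, collapse = ", "))
  ann <- ann[match(train, ann$sample_id), ]
  keep <- complete.cases(ann[, c("os_time", "os_event", "age", "sex")])
  n_dropped <- sum(!keep)
  ann <- ann[keep, ]
  if (nrow(ann) < 4) stop("too few usable training samples")
  if (sum(ann$os_event) < 2) stop("need >= 2 events in training data")
  x_icp <- m[pair$icp, ann$sample_id]
  x_lnc <- m[pair$lnc, ann$sample_id]
  center <- c(icp = mean(x_icp), lnc = mean(x_lnc))
  scl <- c(icp = sd(x_icp), lnc = sd(x_lnc))
  df <- data.frame(time = ann$os_time, event = ann$os_event,
                   icp = (x_icp - center["icp"]) / scl["icp"],
                   lnc = (x_lnc - center["lnc"]) / scl["lnc"],
                   age = ann$age, sex = ann$sex)
  const <- vapply(df[, c("icp", "lnc", "age", "sex")],
                  function(v) sd(v) == 0 || !is.finite(sd(v)), logical(1))
  if (any(const))
    stop("constant covariate(s) in training data: ",
         paste(names(const)[const], collapse = ", "))
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ icp + lnc + age + sex,
                    data = df, ties = "efron"),
    warning = function(w) structure(list(bad = TRUE, msg = conditionMessage(w)),
                                    class = "cox_fail"),
    error = function(e) structure(list(bad = TRUE, msg = conditionMessage(e)),
                                  class = "cox_fail"))
  if (inherits(fit, "cox_fail") || anyNA(coef(fit))) {
    return(list(coef = NULL, center = center, scale = scl,
                converged = FALSE, n_dropped = n_dropped,
                n_events = sum(df$event)))
  }
  list(coef = coef(fit), center = center, scale = scl, converged = TRUE,
       n_dropped = n_dropped, n_events = sum(df$event))
}

#' Held-out risk scores from a fitted pair model
#'
#' Risk score = beta_icp * z(x_icp) + beta_lnc * z(x_lnc), with the
#' z-scoring frozen at the training statistics; the confounder
#' coefficients do not enter the score.
#'
#' @param m expression matrix.
#' @param fit result of [fit_cox_pair()] (must have converged).
#' @param heldout character vector of held-out sample ids.
#' @param pair list with `icp` and `lnc` gene ids.
#' @return named numeric vector of risk scores for `heldout`.
#' @export
risk_score <- function(m, fit, heldout, pair) {
  if (!isTRUE(fit$converged)) stop("Cox fit did not converge")
  pair <- as.list(pair)
  miss <- setdiff(c(pair$icp, pair$lnc), rownames(m))
  if (length(miss)) stop("gene(s) absent from matrix: ",
                         paste(miss, collapse = ", "))
  z_icp <- (m[pair$icp, heldout] - fit$center["icp"]) / fit$scale["icp"]
  z_lnc <- (m[pair$lnc, heldout] - fit$center["lnc"]) / fit$scale["lnc"]
  sc <- fit$coef["icp"] * z_icp + fit$coef["lnc"] * z_lnc
  setNames(as.numeric(sc), heldout)
}

#' Log-rank test between high- and low-risk halves
#'
#' Dichotomizes held-out samples at the median risk score and compares
#' survival between the two strata with the standard two-group log-rank
#' test (1 degree of freedom).
#'
#' @param scores named risk scores (held-out samples).
#' @param ann sample annotation with `os_time`, `os_event`.
#' @return list with `chi2`, `p`, and the `high_risk` logical vector.
#' @export
logrank_by_median <- function(scores, ann) {
  ann <- ann[match(names(scores), ann$sample_id), ]
  keep <- !is.na(ann$os_time) & !is.na(ann$os_event)
  scores <- scores[keep]; ann <- ann[keep, ]
  grp <- scores > median(scores)
  if (sum(grp) < 2 || sum(!grp) < 2)
    stop("degenerate risk stratum (fewer than 2 samples)")
  if (sum(ann$os_event) < 1) stop("no events among held-out samples")
  sd_fit <- survival::survdiff(
    survival::Surv(ann$os_time, ann$os_event) ~ grp)
  chi2 <- sd_fit$chisq
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       high_risk = grp)
}

# Two-group log-rank chi-square, vectorized for the permutation null loop.
# Same statistic as the public logrank_by_median() (hypergeometric variance,
# 1 df); equivalence is asserted in the test suite.
logrank_chi2_fast <- function(time, event, g1) {
  o <- order(time)
  time <- time[o]; event <- event[o] == 1; g1 <- g1[o]
  n <- length(time)
  ev_idx <- which(event)
  if (!length(ev_idx)) return(0)
  r1 <- rev(cumsum(rev(as.numeric(g1))))
  et <- time[ev_idx]
  uet <- unique(et)
  f <- factor(et, levels = uet)
  dt <- tabulate(f)
  d1t <- as.numeric(rowsum(as.numeric(g1[ev_idx]), f))
  first <- match(uet, time)
  nt <- n - first + 1
  n1t <- r1[first]
  O1 <- sum(d1t)
  E1 <- sum(dt * n1t / nt)
  ok <- nt > 1
  V <- sum((dt * (n1t / nt) * (1 - n1t / nt) * (nt - dt) / (nt - 1))[ok])
  if (V <= 0) return(0)
  (O1 - E1)^2 / V
}

#' Permutation screen of one pair's prognostic value
#'
#' Runs the full split / Cox-fit / held-out risk-score / log-rank chain
#' once on the observed outcomes, then builds a permutation null by
#' jointly permuting (os_time, os_event) across samples — the split is
#' held fixed — and re-running the chain. The empirical p-value is
#' (1 + #\{null chi2 >= observed\}) / (n_ok + 1); null replicates where
#' the chain fails (e.g. a non-converged Cox fit) are discarded and
#' counted. The pair is flagged prognostic when the p-value is below
#' alpha.
#'
#' @param m expression matrix.
#' @param ann sample annotation with survival and confounders.
#' @param pair list with `icp` and `lnc` gene ids.
#' @param cfg a [pipeline_config()]; uses `n_survival_perms`, `alpha`.
#' @param seed integer seed (split and permutations).
#' @param cohort cohort label.
#' @return a `risk_model` list with the pair, coefficients, held-out
#'   scores, observed log-rank chi2/p, `perm_p`, `prognostic` flag,
#'   `n_failed_perms`, and split sizes.
#' @export
permutation_screen <- function(m, ann, pair, cfg = pipeline_config(),
                               seed = NULL, cohort = "cohort") {
  pair <- as.list(pair)
  if (is.null(seed)) seed <- stage_seed(cfg$rng_seed,
                                        paste0("surv_", cohort, "_",
                                               pair$icp, "_", pair$lnc))
  usable <- ann[complete.cases(ann[, c("os_time", "os_event", "age",
                                       "sex")]), ]
  sp <- split_cohort(usable$sample_id, seed = seed)
  run_chain <- function(a) {
    fit <- fit_cox_pair(m, a, pair, sp$train)
    if (!fit$converged) return(NULL)
    sc <- risk_score(m, fit, sp$heldout, pair)
    lr <- tryCatch(logrank_by_median(sc, a), error = function(e) NULL)
    if (is.null(lr)) return(NULL)
    list(fit = fit, scores = sc, lr = lr)
  }
  obs <- run_chain(usable)
  if (is.null(obs))
    stop("observed survival chain failed for pair ", pair$icp, "-", pair$lnc)
  # Covariates are fixed under outcome permutation, so the training design
  # matrix and held-out z-scores can be built once; each null replicate
  # refits the Cox model (survival's fitter, Efron ties) on permuted
  # outcomes and recomputes the held-out log-rank statistic.
  tr_idx <- match(sp$train, usable$sample_id)
  ho_idx <- match(sp$heldout, usable$sample_id)
  x_icp <- m[pair$icp, usable$sample_id]
  x_lnc <- m[pair$lnc, usable$sample_id]
  ctr <- c(mean(x_icp[tr_idx]), mean(x_lnc[tr_idx]))
  scl <- c(sd(x_icp[tr_idx]), sd(x_lnc[tr_idx]))
  X_train <- cbind(icp = (x_icp[tr_idx] - ctr[1]) / scl[1],
                   lnc = (x_lnc[tr_idx] - ctr[2]) / scl[2],
                   age = usable$age[tr_idx], sex = usable$sex[tr_idx])
  z_ho <- cbind((x_icp[ho_idx] - ctr[1]) / scl[1],
                (x_lnc[ho_idx] - ctr[2]) / scl[2])
  n_perm <- cfg$n_survival_perms
  null_chi2 <- rep(NA_real_, n_perm)
  ctl <- survival::coxph.control()
  with_seed(stage_seed(seed, "perm_null"), {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(nrow(usable))
      pt_time <- usable$os_time[idx]
      pt_event <- usable$os_event[idx]
      null_chi2[b] <- tryCatch({
        cf <- suppressWarnings(survival::coxph.fit(
          X_train, survival::Surv(pt_time[tr_idx], pt_event[tr_idx]),
          strata = NULL, offset = NULL, init = NULL, control = ctl,
          weights = NULL, method = "efron", rownames = NULL))
        beta <- cf$coefficients
        if (anyNA(beta)) NA_real_ else {
          sc <- z_ho %*% beta[1:2]
          grp <- as.vector(sc > median(sc))
          if (sum(grp) < 2 || sum(!grp) < 2 ||
              sum(pt_event[ho_idx]) < 1) NA_real_ else
            logrank_chi2_fast(pt_time[ho_idx], pt_event[ho_idx], grp)
        }
      }, error = function(e) NA_real_)
    }
  })
  ok <- !is.na(null_chi2)
  perm_p <- (1 + sum(null_chi2[ok] >= obs$lr$chi2)) / (sum(ok) + 1)
  structure(list(cohort = cohort, pair = pair,
                 beta_icp = unname(obs$fit$coef["icp"]),
                 beta_lnc = unname(obs$fit$coef["lnc"]),
                 beta_age = unname(obs$fit$coef["age"]),
                 beta_sex = unname(obs$fit$coef["sex"]),
                 heldout_scores = obs$scores,
                 logrank_chi2 = obs$lr$chi2, logrank_p = obs$lr$p,
                 perm_p = perm_p, prognostic = perm_p < cfg$alpha,
                 n_failed_perms = sum(!ok),
                 n_train = length(sp$train), n_test = length(sp$heldout)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Pair %s-%s (%s): beta = (%.3f, %.3f), log-rank chi2 = %.2f, perm p = %.4g%s\n",
              x$pair$icp, x$pair$lnc, x$cohort, x$beta_icp, x$beta_lnc,
              x$logrank_chi2, x$perm_p,
              if (x$prognostic) " [prognostic]" else ""))
  invisible(x)
}

#' Summarize prognostic pairs across cohorts
#'
#' @param models list of `risk_model`s (any cohorts).
#' @return list with `table` (pair x cohorts where prognostic, with
#'   counts) and `histogram` (named count of pairs prognostic in 1, 2,
#'   ... cohorts).
#' @export
cross_cohort_summary <- function(models) {
  if (!length(models)) stop("need >= 1 screened model")
  rows <- lapply(models, function(mo)
    data.frame(pair = paste(mo$pair$icp, mo$pair$lnc, sep = "|"),
               cohort = mo$cohort, prognostic = mo$prognostic,
               stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  prog <- df[df$prognostic, , drop = FALSE]
  if (!nrow(prog)) {
    tab <- data.frame(pair = character(), n_cohorts = integer(),
                      cohorts = character(), stringsAsFactors = FALSE)
    return(list(table = tab, histogram = integer()))
  }
  agg <- lapply(split(prog, prog$pair), function(d)
    data.frame(pair = d$pair[1], n_cohorts = nrow(d),
               cohorts = paste(sort(d$cohort), collapse = ","),
               stringsAsFactors = FALSE))
  tab <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  hist <- table(tab$n_cohorts)
  list(table = tab, histogram = setNames(as.integer(hist), names(hist)))
}
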