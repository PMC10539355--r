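# Shared fixture builders: everything is generated in code at test time.

toy_matrix <- function(genes = c("g1", "g2"), samples = c("s1", "s2"),
                       values = NULL) {
  if (is.null(values))
    values <- matrix(seq_len(length(genes) * length(samples)),
                     nrow = length(genes))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values)
}

random_matrix <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 5, 1), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  expression_matrix(m)
}

# Minimal planted-pair tumor simulation used by several modules.
small_tumor_sim <- function(n = 100, rho = 0.6, n_pairs = 3, beta = NULL,
                            weight = NULL, seed = 11,
                            infiltration_effect = 1) {
  pp <- data.frame(icp = sprintf("ICP%03d", seq_len(n_pairs)),
                   lnc = sprintf("LNC%03d", seq_len(n_pairs)), rho = rho)
  prog <- if (is.null(beta)) NULL else
    data.frame(icp = pp$icp, lnc = pp$lnc, beta = beta)
  resp <- if (is.null(weight)) NULL else
    data.frame(icp = pp$icp, lnc = pp$lnc, weight = weight)
  cfg <- sim_config(samples_per_cohort = n, planted_pairs = pp,
                    prognostic_pairs = prog, response_pairs = resp,
                    infiltration_effect = infiltration_effect, seed = seed)
  list(cfg = cfg, sim = simulate_tumor_cohort(cfg, "T1"),
       ann = sim_gene_annotation(cfg))
}

# Literal transcription of the single-sample enrichment running sum,
# written independently of the package implementation: explicit loop over
# the descending rank walk.
ssgsea_oracle <- function(x, set_genes, weight = 0.25) {
  genes <- names(x)
  r <- rank(x, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  in_set <- genes[ord] %in% set_genes
  n <- length(x)
  n_out <- sum(!in_set)
  denom_in <- sum(abs(r[ord][in_set])^weight)
  p_in <- 0; p_out <- 0; es <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) p_in <- p_in + abs(r[ord][i])^weight / denom_in
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# Textbook Pearson correlation from raw sums.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Exhaustive pairwise-comparison AUC.
auc_oracle <- function(scores, labels, positive) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Full hypergeometric enumeration of the two-sided Fisher exact p-value.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_vals <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(a_vals, function(a)
    exp(lchoose(c1, a) + lchoose(n - c1, r1 - a) - lchoose(n, r1)),
    numeric(1))
  p_obs <- probs[a_vals == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand aggregation of the two-group log-rank table: loop over distinct
# event times accumulating observed/expected events and the
# hypergeometric variance.
logrank_oracle <- function(time, event, group1) {
  ev_times <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t0 in ev_times) {
    at_risk <- time >= t0
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & group1)
    d_t <- sum(time == t0 & event == 1)
    d1_t <- sum(time == t0 & event == 1 & group1)
    O1 <- O1 + d1_t
    E1 <- E1 + d_t * n1_t / n_t
    if (n_t > 1)
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
  }
  (O1 - E1)^2 / V
}
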