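#' Run the per-cohort discovery pipeline
#'
#' Chains the tumor-cohort stages: immune scoring of every sample,
#' retention of the high-infiltration fraction, consensus clustering of
#' the retained samples on the ICR panel, differential expression between
#' high and low ICR groups, and pair extraction over the differential
#' ICPs and lncRNAs, followed by network construction.
#'
#' @param expr expression matrix of the cohort.
#' @param classes gene class map covering the matrix genes.
#' @param sets gene-set catalog; must contain `icr_set` and `immune_set`.
#' @param cfg a [pipeline_config()].
#' @param cohort cohort label.
#' @param icr_set,immune_set names of the ICR panel and immune-signature
#'   sets within `sets`.
#' @return a list with `scores`, `high_infiltration` (sample ids),
#'   `grouping`, `de`, `de_icps`, `de_lncs`, `pairs`, `network`, `hubs`,
#'   and `coincidence` (NA when the Pearson set is empty).
#' @export
run_cohort_analysis <- function(expr, classes, sets, cfg = pipeline_config(),
                                cohort = "cohort", icr_set = "ICR",
                                immune_set = "IMMUNE_SIG") {
  stopifnot(all(c(icr_set, immune_set) %in% names(sets)))
  scores <- ssgsea_score(expr, sets[c(icr_set, immune_set)],
                         weight = cfg$ssgsea_weight)
  keep <- select_high_infiltration(scores, immune_set, cfg)
  sub <- expression_matrix(unclass(expr)[, keep, drop = FALSE])
  icr_genes <- intersect(sets[[icr_set]], rownames(sub))
  grouping <- consensus_cluster_icr(
    expression_matrix(unclass(sub)[icr_genes, , drop = FALSE]), cfg,
    seed = stage_seed(cfg$rng_seed, paste0("consensus_", cohort)))
  de <- differential_expression(sub, grouping, cfg)
  cls <- gene_class(classes, de$gene_id)
  de_icps <- de$gene_id[cls == "ICP" & de$direction != "ns"]
  de_lncs <- de$gene_id[cls == "lncRNA" & de$direction != "ns"]
  pairs <- NULL; network <- NULL; hubs <- character(); coin <- NA_real_
  if (length(de_icps) && length(de_lncs)) {
    pairs <- extract_pairs(sub, de_icps, de_lncs, cfg, cohort = cohort)
    network <- build_network(pairs, cohort)
    if (nrow(network$nodes)) hubs <- extract_hubs(network, cfg)
    if (sum(pairs$in_pcc_set) > 0) coin <- coincidence_rate(pairs)
  }
  list(cohort = cohort, scores = scores, high_infiltration = keep,
       grouping = grouping, de = de, de_icps = de_icps, de_lncs = de_lncs,
       pairs = pairs, network = network, hubs = hubs, coincidence = coin)
}

#' Screen accepted pairs for prognostic value in one cohort
#'
#' Applies [permutation_screen()] to every accepted pair of a cohort's
#' pair table.
#'
#' @param expr expression matrix of the cohort.
#' @param ann sample annotation with survival and confounders.
#' @param pairs a `pair_table` (accepted rows are screened).
#' @param cfg a [pipeline_config()].
#' @param cohort cohort label.
#' @return list of `risk_model`s, one per accepted pair.
#' @export
screen_pairs_survival <- function(expr, ann, pairs,
                                  cfg = pipeline_config(),
                                  cohort = "cohort") {
  acc <- pairs[pairs$accepted, , drop = FALSE]
  models <- vector("list", nrow(acc))
  for (k in seq_len(nrow(acc))) {
    models[[k]] <- permutation_screen(
      expr, ann, list(icp = acc$icp_id[k], lnc = acc$lnc_id[k]),
      cfg, cohort = cohort)
  }
  models
}
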