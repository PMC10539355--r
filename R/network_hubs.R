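#' Build the bipartite ICP-lncRNA network of a cohort
#'
#' One node per distinct gene appearing in an accepted pair, one edge per
#' accepted pair; edges only connect the ICP side to the lncRNA side.
#'
#' @param pt a `pair_table` (only `accepted` rows are used).
#' @param cohort cohort to build; default uses all rows.
#' @return a `cancer_network` list: `cohort`, `nodes` (data.frame `id`,
#'   `side`), `edges` (data.frame `icp_id`, `lnc_id`, `sign`), `degree`
#'   (named integer vector).
#' @export
build_network <- function(pt, cohort = NULL) {
  rows <- pt[pt$accepted, , drop = FALSE]
  if (!is.null(cohort)) rows <- rows[rows$cohort == cohort, , drop = FALSE]
  else cohort <- if (nrow(rows)) rows$cohort[1] else NA_character_
  icps <- unique(rows$icp_id)
  lncs <- unique(rows$lnc_id)
  nodes <- data.frame(id = c(icps, lncs),
                      side = c(rep("ICP", length(icps)),
                               rep("lncRNA", length(lncs))),
                      stringsAsFactors = FALSE)
  deg <- integer(nrow(nodes))
  names(deg) <- nodes$id
  if (nrow(rows)) {
    tab <- table(c(rows$icp_id, rows$lnc_id))
    deg[names(tab)] <- as.integer(tab)
  }
  structure(list(cohort = cohort, nodes = nodes,
                 edges = rows[, c("icp_id", "lnc_id", "sign")],
                 degree = deg),
            class = "cancer_network")
}

#' @export
print.cancer_network <- function(x, ...) {
  cat("Bipartite ICP-lncRNA network (", x$cohort, "): ",
      nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Convert a cancer network to an igraph object
#' @param net a `cancer_network`.
#' @return an igraph bipartite graph (`type` FALSE = ICP, TRUE = lncRNA).
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("icp_id", "lnc_id")], directed = FALSE,
    vertices = net$nodes)
  igraph::V(g)$type <- net$nodes$side[match(igraph::V(g)$name,
                                            net$nodes$id)] == "lncRNA"
  g
}

#' Write a network as edge-list TSV and GraphML
#' @param net a `cancer_network`.
#' @param path base output path; `.tsv` and `.graphml` suffixes are added.
#' @return invisible character vector of written files.
#' @export
write_network <- function(net, path) {
  tsv <- paste0(path, ".tsv")
  write.table(cbind(cohort = net$cohort, net$edges), tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  gml <- paste0(path, ".graphml")
  igraph::write_graph(as_igraph(net), gml, format = "graphml")
  invisible(c(tsv, gml))
}

#' Goodness of a power-law fit to the degree distribution
#'
#' Ordinary least squares of log10(frequency) on log10(degree) over the
#' observed degree values; the returned R-squared measures how closely
#' the degree distribution follows a power law (scale-free behaviour).
#'
#' @param net a `cancer_network` with >= 3 distinct positive degrees.
#' @return R-squared in [0, 1].
#' @export
powerlaw_fit_r2 <- function(net) {
  deg <- net$degree[net$degree > 0]
  tab <- table(deg)
  if (length(tab) < 3)
    stop("need >= 3 distinct degree values to fit a power law")
  k <- as.numeric(names(tab))
  f <- as.numeric(tab)
  x <- log10(k); y <- log10(f)
  # simple-regression R^2; a flat frequency profile has no trend to explain
  if (sd(y) == 0) return(0)
  cor(x, y)^2
}

#' Extract hub nodes by degree
#'
#' Hubs are the top 5% of nodes by degree (configurable): with
#' k = ceiling((1 - hub_quantile) * n_nodes), every node whose degree
#' reaches the k-th largest degree is a hub, so boundary ties are
#' included.
#'
#' @param net a `cancer_network` with >= 1 node.
#' @param cfg a [pipeline_config()]; uses `hub_quantile`.
#' @return character vector of hub node ids.
#' @export
extract_hubs <- function(net, cfg = pipeline_config()) {
  n <- nrow(net$nodes)
  if (n < 1) stop("network has no nodes")
  k <- max(1L, n - as.integer(floor(cfg$hub_quantile * n + 1e-9)))
  cutoff <- sort(net$degree, decreasing = TRUE)[k]
  names(net$degree)[net$degree >= cutoff]
}

#' Classify hubs as common, specific, or other across cohorts
#'
#' A hub appearing in `common_hub_min_cancers` or more cohorts (more than
#' five, by default) is `common`; a hub of exactly one cohort is
#' `specific`; everything else is `other`. Max and mean degree are
#' aggregated over the cohorts where the node is a hub.
#'
#' @param hubs_by_cohort named list: cohort -> character vector of hub ids.
#' @param networks optional named list of `cancer_network`s (same names)
#'   supplying degrees; without it degree columns are NA.
#' @param cfg a [pipeline_config()].
#' @return a `hub_classification` data.frame with `node`, `side`,
#'   `class`, `n_cohorts_hub`, `cohorts`, `max_degree`, `mean_degree`.
#' @export
classify_hubs <- function(hubs_by_cohort, networks = NULL,
                          cfg = pipeline_config()) {
  if (!length(hubs_by_cohort)) stop("need >= 1 cohort")
  all_hubs <- sort(unique(unlist(hubs_by_cohort)))
  rows <- lapply(all_hubs, function(node) {
    in_cohorts <- names(hubs_by_cohort)[vapply(hubs_by_cohort,
                                               function(h) node %in% h,
                                               logical(1))]
    n_hub <- length(in_cohorts)
    cls <- if (n_hub >= cfg$common_hub_min_cancers) "common"
           else if (n_hub == 1) "specific" else "other"
    side <- NA_character_
    degs <- NA_real_
    if (!is.null(networks)) {
      degs <- vapply(in_cohorts, function(co)
        as.numeric(networks[[co]]$degree[node]), numeric(1))
      sides <- unlist(lapply(in_cohorts, function(co) {
        nn <- networks[[co]]$nodes
        nn$side[nn$id == node]
      }))
      if (length(sides)) side <- sides[1]
    }
    data.frame(node = node, side = side, class = cls,
               n_cohorts_hub = n_hub,
               cohorts = paste(in_cohorts, collapse = ","),
               max_degree = suppressWarnings(max(degs)),
               mean_degree = mean(degs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("hub_classification", class(out))
  out
}

#' Cross-cohort similarity matrices of shared entities
#'
#' For each entity kind — ICPs, lncRNAs, and accepted pairs — builds the
#' cohort x cohort matrix S(a, b) = |A intersect B| / min(|A|, |B|)
#' (or Jaccard when configured). Diagonal is 1 for non-empty cohorts.
#'
#' @param pair_tables named list of `pair_table`s, one per cohort
#'   (>= 2 cohorts), or a single table with a `cohort` column.
#' @param cfg a [pipeline_config()]; uses `similarity`.
#' @return list of three matrices: `icp`, `lncrna`, `pair`.
#' @export
similarity_matrices <- function(pair_tables, cfg = pipeline_config()) {
  if (is.data.frame(pair_tables))
    pair_tables <- split(pair_tables, pair_tables$cohort)
  if (length(pair_tables) < 2) stop("need >= 2 cohorts")
  cohorts <- names(pair_tables)
  sets <- lapply(pair_tables, function(pt) {
    acc <- pt[pt$accepted, , drop = FALSE]
    list(icp = unique(acc$icp_id), lncrna = unique(acc$lnc_id),
         pair = unique(paste(acc$icp_id, acc$lnc_id, sep = "|")))
  })
  one <- function(kind) {
    S <- matrix(0, length(cohorts), length(cohorts),
                dimnames = list(cohorts, cohorts))
    for (i in seq_along(cohorts)) {
      for (j in seq_along(cohorts)) {
        A <- sets[[i]][[kind]]; B <- sets[[j]][[kind]]
        inter <- length(intersect(A, B))
        denom <- if (cfg$similarity == "min") min(length(A), length(B))
                 else length(union(A, B))
        S[i, j] <- if (denom == 0) 0 else inter / denom
      }
    }
    S
  }
  list(icp = one("icp"), lncrna = one("lncrna"), pair = one("pair"))
}
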