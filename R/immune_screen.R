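#' Quantile normalization across samples
#'
#' Forces every sample (column) to share the same empirical distribution —
#' the per-rank mean of the input columns — the standard normalization for
#' cross-array comparability of log2 expression.
#'
#' @param m expression matrix (genes x samples), >= 2 samples.
#' @return normalized `expr_matrix` with identical dimnames.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2) stop("quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(unclass(m))
  dimnames(out) <- dimnames(m)
  expression_matrix(out)
}

#' Remove additive batch effects within cell types
#'
#' For every gene and cell type, each batch's samples are mean-shifted so
#' that all batch means coincide with that cell type's grand mean — the
#' minimal location adjustment for additive batch offsets. The per-gene
#' mean within each cell type is preserved.
#'
#' @param m expression matrix.
#' @param ann sample annotation with `cell_type` and `batch` for every
#'   sample in `m`.
#' @return adjusted `expr_matrix`.
#' @export
adjust_batches <- function(m, ann) {
  ann <- ann[match(colnames(m), ann$sample_id), ]
  if (anyNA(ann$sample_id))
    stop("annotation missing for sample(s): ",
         paste(setdiff(colnames(m), ann$sample_id), collapse = ", "))
  if (is.null(ann$batch) || anyNA(ann$batch))
    stop("batch label missing for sample(s): ",
         paste(ann$sample_id[is.na(ann$batch)], collapse = ", "))
  if (is.null(ann$cell_type) || anyNA(ann$cell_type))
    stop("cell_type label missing for sample(s): ",
         paste(ann$sample_id[is.na(ann$cell_type)], collapse = ", "))
  out <- unclass(m)
  for (ct in unique(ann$cell_type)) {
    cols <- which(ann$cell_type == ct)
    batches <- unique(ann$batch[cols])
    sizes <- table(ann$batch[cols])
    if (any(sizes < 2))
      stop("cell type '", ct, "' has batch(es) with < 2 samples: ",
           paste(names(sizes)[sizes < 2], collapse = ", "))
    grand <- rowMeans(out[, cols, drop = FALSE])
    for (b in batches) {
      bc <- cols[ann$batch[cols] == b]
      bmean <- rowMeans(out[, bc, drop = FALSE])
      out[, bc] <- out[, bc] - bmean + grand
    }
  }
  expression_matrix(out)
}

#' Rank genes within each cell type and gene class
#'
#' Within every cell type, genes of each class (ICPs against ICPs, lncRNAs
#' against lncRNAs, others against others) are ranked by their mean
#' expression across that cell type's samples; the rank is expressed as a
#' quantile in (0, 1], 1 being the most highly expressed gene of its class.
#' Ties in mean expression are broken by lexicographic gene id so the
#' ranking is deterministic.
#'
#' @param m expression matrix.
#' @param ann sample annotation with `cell_type`.
#' @param classes gene class map covering all genes in `m`.
#' @return a `rank_table` data.frame with columns `gene_id`, `cell_type`,
#'   `class`, `mean_expr`, `rank`, `quantile`.
#' @export
rank_by_cell_type <- function(m, ann, classes) {
  ann <- ann[match(colnames(m), ann$sample_id), ]
  if (anyNA(ann$sample_id) || is.null(ann$cell_type) || anyNA(ann$cell_type))
    stop("every sample needs a cell_type annotation")
  cls <- gene_class(classes, rownames(m))
  cell_types <- unique(ann$cell_type)
  res <- list()
  for (ct in cell_types) {
    cols <- which(ann$cell_type == ct)
    if (!length(cols)) stop("cell type '", ct, "' has no samples")
    mu <- rowMeans(m[, cols, drop = FALSE])
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      k <- length(idx)
      # order by mean descending, gene id ascending on ties; rank k = top
      ord <- order(-mu[idx], rownames(m)[idx])
      rk <- integer(k)
      rk[ord] <- k:1
      res[[paste(ct, cl)]] <- data.frame(
        gene_id = rownames(m)[idx], cell_type = ct, class = cl,
        mean_expr = unname(mu[idx]), rank = rk, quantile = rk / k,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  class(out) <- c("rank_table", class(out))
  out
}

#' Select highly expressed ICPs and immune-specific/general lncRNAs
#'
#' A gene counts as highly expressed in a cell type when its within-class
#' rank quantile exceeds `high_expr_quantile` (0.5 = top 50% by default;
#' raising the threshold can only shrink the selection).
#' ICPs are kept when highly expressed in at least one cell type. lncRNAs
#' are labelled immune-specific when highly expressed in exactly one cell
#' type and immune-general when highly expressed in more than half of the
#' cell types (more than nine of the 18 canonical immune cell types).
#'
#' @param rt a `rank_table` from [rank_by_cell_type()].
#' @param cfg a [pipeline_config()].
#' @return an `immune_high_sets` list: `high_icps`,
#'   `immune_specific_lncs`, `immune_general_lncs`, `selected_lncs`, and
#'   `counts` (per-gene number of cell types where high).
#' @export
select_immune_high <- function(rt, cfg = pipeline_config()) {
  stopifnot(inherits(rt, "rank_table"))
  n_ct <- length(unique(rt$cell_type))
  if (n_ct < 1) stop("rank table covers no cell types")
  general_min <- if (n_ct == 18) 9L else as.integer(ceiling(n_ct / 2))
  cut <- cfg$high_expr_quantile
  high <- rt[rt$quantile > cut, , drop = FALSE]
  count_high <- function(cl) {
    sub <- high[high$class == cl, , drop = FALSE]
    if (!nrow(sub)) return(integer())
    tab <- table(sub$gene_id)
    setNames(as.integer(tab), names(tab))
  }
  icp_counts <- count_high("ICP")
  lnc_counts <- count_high("lncRNA")
  specific <- names(lnc_counts)[lnc_counts == 1]
  general <- names(lnc_counts)[lnc_counts > general_min]
  counts <- data.frame(
    gene_id = c(names(icp_counts), names(lnc_counts)),
    class = c(rep("ICP", length(icp_counts)),
              rep("lncRNA", length(lnc_counts))),
    n_cell_types_high = c(unname(icp_counts), unname(lnc_counts)),
    stringsAsFactors = FALSE)
  structure(list(high_icps = sort(names(icp_counts)),
                 immune_specific_lncs = sort(specific),
                 immune_general_lncs = sort(general),
                 selected_lncs = sort(union(specific, general)),
                 counts = counts,
                 n_cell_types = n_ct,
                 general_min = general_min),
            class = "immune_high_sets")
}

#' @export
print.immune_high_sets <- function(x, ...) {
  cat("Immune-high selection over", x$n_cell_types, "cell types\n")
  cat("  high ICPs:            ", length(x$high_icps), "\n")
  cat("  immune-specific lncRNAs:", length(x$immune_specific_lncs), "\n")
  cat(sprintf("  immune-general lncRNAs (> %d cell types): %d\n",
              x$general_min, length(x$immune_general_lncs)))
  invisible(x)
}
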