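#' Construct and validate an expression matrix
#'
#' The pipeline's central container is a plain numeric matrix of log2-scale
#' expression values with genes as rows and samples as columns. This
#' constructor enforces the invariants every stage relies on: unique gene and
#' sample identifiers, all values finite.
#'
#' @param values numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @return the validated matrix, invisibly classed as `expr_matrix`.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g))
    stop("duplicated gene id(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at gene '", rownames(values)[bad[1]],
         "', sample '", colnames(values)[bad[2]], "'")
  }
  class(values) <- c("expr_matrix", class(values))
  values
}

#' Read a gene x sample expression matrix from TSV
#'
#' Expects the common TCGA/GEO export dialect: tab-separated, first column
#' gene identifiers (header cell ignored), remaining columns one per sample.
#'
#' @param path file path.
#' @return a validated `expr_matrix`.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", blank.lines.skip = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus >=1 sample")
  genes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("non-numeric value '", vals[bad[1, 1], bad[1, 2]],
           "' at gene '", genes[bad[1, 1]], "', column '",
           colnames(vals)[bad[1, 2]], "'")
    }
    bad <- which(is.na(num), arr.ind = TRUE)
    stop("missing value at gene '", genes[bad[1, 1]], "', column '",
         colnames(vals)[bad[1, 2]], "'")
  }
  rownames(num) <- genes
  expression_matrix(num)
}

#' Write an expression matrix to TSV
#'
#' @param m expression matrix (genes x samples).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table from TSV
#'
#' One row per sample. Recognised columns: `sample_id` (required), `cohort`,
#' `cell_type`, `batch`, `age`, `sex` (0/1), `os_time` (non-negative days),
#' `os_event` (0/1), `ici_response` (`responder`/`non_responder`). Extra
#' columns pass through untouched.
#'
#' @param path file path.
#' @return a validated annotation `data.frame`.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_annotation(df)
}

#' Validate a sample annotation data frame
#'
#' @param ann data.frame with at least a `sample_id` column.
#' @return `ann` unchanged if valid; otherwise an error.
#' @export
validate_annotation <- function(ann) {
  if (!"sample_id" %in% names(ann)) stop("annotation needs a sample_id column")
  if (anyDuplicated(ann$sample_id))
    stop("duplicated sample_id(s): ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "))
  has_time <- "os_time" %in% names(ann)
  has_event <- "os_event" %in% names(ann)
  if (has_time != has_event)
    stop("os_time and os_event must be present together")
  if (has_time) {
    ok <- is.na(ann$os_time) == is.na(ann$os_event)
    if (!all(ok)) stop("os_event must be present iff os_time is present")
    if (any(ann$os_time < 0, na.rm = TRUE)) stop("negative os_time")
    if (!all(ann$os_event %in% c(0, 1, NA))) stop("os_event must be 0/1")
  }
  if ("sex" %in% names(ann) && !all(ann$sex %in% c(0, 1, NA)))
    stop("sex must be coded 0/1")
  if ("ici_response" %in% names(ann) &&
      !all(ann$ici_response %in% c("responder", "non_responder", NA)))
    stop("ici_response must be 'responder' or 'non_responder'")
  ann
}

#' Write a sample annotation table to TSV
#' @param ann annotation data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set catalog from a GMT file
#'
#' Standard GMT: one set per line — name, description (discarded), then
#' member gene ids, tab-separated. Duplicate members within a set are
#' removed with a warning; empty sets are an error.
#'
#' @param path file path.
#' @return named list of character vectors (set name -> member gene ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3 || !any(nzchar(parts[-(1:2)])))
      stop("gene set '", parts[1], "' has no members")
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", parts[1], "' were removed")
      members <- unique(members)
    }
    sets[[parts[1]]] <- members
  }
  validate_gene_sets(sets)
}

#' Validate a gene-set catalog
#' @param sets named list of character vectors.
#' @return `sets` if valid.
#' @export
validate_gene_sets <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  for (nm in names(sets)) {
    if (!length(sets[[nm]])) stop("gene set '", nm, "' is empty")
    if (anyDuplicated(sets[[nm]]))
      stop("gene set '", nm, "' contains duplicate members")
  }
  sets
}

#' Write a gene-set catalog to GMT
#' @param sets named list of character vectors.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a gene class map
#'
#' Maps gene ids to one of the three classes the pipeline distinguishes:
#' immune checkpoint genes (`ICP`), long non-coding RNAs (`lncRNA`), and
#' everything else (`other`). Lookup of a gene absent from the map is an
#' explicit error, never a silent `other`.
#'
#' @param icp,lncrna,other character vectors of gene ids per class.
#' @return named character vector gene id -> class.
#' @export
gene_class_map <- function(icp = character(), lncrna = character(),
                           other = character()) {
  map <- c(setNames(rep("ICP", length(icp)), icp),
           setNames(rep("lncRNA", length(lncrna)), lncrna),
           setNames(rep("other", length(other)), other))
  if (anyDuplicated(names(map)))
    stop("gene(s) assigned to multiple classes: ",
         paste(unique(names(map)[duplicated(names(map))]), collapse = ", "))
  map
}

#' Read a gene class map from a two-column TSV (gene_id, class)
#' @param path file path.
#' @return a gene class map as from [gene_class_map()].
#' @export
read_gene_classes <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("gene_id", "class") %in% names(df)))
    stop("gene class TSV needs gene_id and class columns")
  bad <- setdiff(unique(df$class), c("ICP", "lncRNA", "other"))
  if (length(bad))
    stop("unknown gene class(es): ", paste(bad, collapse = ", "))
  gene_class_map(icp = df$gene_id[df$class == "ICP"],
                 lncrna = df$gene_id[df$class == "lncRNA"],
                 other = df$gene_id[df$class == "other"])
}

#' Write a gene class map to TSV
#' @param map a gene class map.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_classes <- function(map, path) {
  write.table(data.frame(gene_id = names(map), class = unname(map)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up gene classes, erroring on unknown genes
#' @param map a gene class map from [gene_class_map()].
#' @param genes character vector of gene ids.
#' @return character vector of classes, same length as `genes`.
#' @export
gene_class <- function(map, genes) {
  miss <- setdiff(genes, names(map))
  if (length(miss))
    stop("gene(s) absent from class map: ", paste(head(miss, 5), collapse = ", "))
  unname(map[genes])
}

#' Pipeline configuration with validated defaults
#'
#' Central container for every tunable threshold of the pipeline. Defaults
#' are the screening rules the method prescribes: genes count as highly
#' expressed in the top 50% of their class within a cell type; tumor samples
#' in the top 75% of immune scores are retained; a pair needs |r| > 0.3 at
#' p < 0.05 on both the Pearson and mutual-information routes; hubs are the
#' top 5% of nodes by degree; common hubs are hubs in more than five
#' cohorts; the survival screen uses 1000 outcome permutations.
#'
#' @param high_expr_quantile within-class rank quantile a gene must exceed
#'   to count as highly expressed in a cell type (default 0.5 = top 50%).
#' @param immune_score_quantile fraction of tumor samples retained by immune
#'   score (default 0.75 = top 75%).
#' @param pcc_abs_min minimum |Pearson r| for pair acceptance (strict, 0.3).
#' @param alpha significance level for all screens (0.05, strict).
#' @param hub_quantile degree quantile above which a node is a hub (0.95).
#' @param common_hub_min_cancers minimum cohorts for a common hub (6,
#'   i.e. "more than five").
#' @param n_survival_perms outcome permutations in the survival screen (1000).
#' @param mi_null_perms permutations for the mutual-information null (100).
#' @param consensus_reps,consensus_frac resampling rounds and subsample
#'   fraction for consensus clustering (100, 0.8).
#' @param ssgsea_weight rank-weight exponent of the enrichment statistic (0.25).
#' @param ssgsea_normalize min-max normalize scores across samples (FALSE).
#' @param similarity cross-cohort similarity normalizer: `"min"` (shared
#'   count over the smaller set) or `"jaccard"`.
#' @param bh_adjust apply Benjamini-Hochberg adjustment to pair p-values
#'   (FALSE; the screening rules use raw cutoffs).
#' @param rng_seed master seed for all stochastic stages.
#' @return a classed list of settings.
#' @export
pipeline_config <- function(high_expr_quantile = 0.5,
                            immune_score_quantile = 0.75,
                            pcc_abs_min = 0.3,
                            alpha = 0.05,
                            hub_quantile = 0.95,
                            common_hub_min_cancers = 6,
                            n_survival_perms = 1000,
                            mi_null_perms = 100,
                            consensus_reps = 100,
                            consensus_frac = 0.8,
                            ssgsea_weight = 0.25,
                            ssgsea_normalize = FALSE,
                            similarity = c("min", "jaccard"),
                            bh_adjust = FALSE,
                            rng_seed = 1L) {
  cfg <- list(high_expr_quantile = high_expr_quantile,
              immune_score_quantile = immune_score_quantile,
              pcc_abs_min = pcc_abs_min,
              alpha = alpha,
              hub_quantile = hub_quantile,
              common_hub_min_cancers = as.integer(common_hub_min_cancers),
              n_survival_perms = as.integer(n_survival_perms),
              mi_null_perms = as.integer(mi_null_perms),
              consensus_reps = as.integer(consensus_reps),
              consensus_frac = consensus_frac,
              ssgsea_weight = ssgsea_weight,
              ssgsea_normalize = isTRUE(ssgsea_normalize),
              similarity = match.arg(similarity),
              bh_adjust = isTRUE(bh_adjust),
              rng_seed = as.integer(rng_seed))
  for (q in c("high_expr_quantile", "immune_score_quantile", "hub_quantile",
              "alpha", "consensus_frac")) {
    if (!is.numeric(cfg[[q]]) || cfg[[q]] <= 0 || cfg[[q]] >= 1)
      stop(q, " must lie strictly in (0, 1), got ", cfg[[q]])
  }
  if (cfg$pcc_abs_min < 0 || cfg$pcc_abs_min >= 1)
    stop("pcc_abs_min must lie in [0, 1), got ", cfg$pcc_abs_min)
  for (p in c("n_survival_perms", "mi_null_perms", "consensus_reps")) {
    if (cfg[[p]] < 1) stop(p, " must be >= 1")
  }
  class(cfg) <- "icplnc_config"
  cfg
}

#' Load pipeline configuration from a JSON file
#'
#' Any key absent from the file keeps its documented default. Unknown keys
#' are an error (catching typos early). Loading the file written by
#' [write_config()] reproduces the configuration exactly.
#'
#' @param path JSON file path; a flat object of settings, optionally with a
#'   `sim` sub-object holding [sim_config()] settings.
#' @return a list with elements `config` (an `icplnc_config`) and `sim`
#'   (a `sim_config` or `NULL`).
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(raw[["sim"]])) {
    sim <- do.call(sim_config, raw[["sim"]])
    raw[["sim"]] <- NULL
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- do.call(pipeline_config, raw)
  list(config = cfg, sim = sim)
}

#' Write pipeline configuration to JSON
#' @param cfg an `icplnc_config`.
#' @param path output path.
#' @param sim optional `sim_config` stored under the `sim` key.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path, sim = NULL) {
  out <- unclass(cfg)
  if (!is.null(sim)) out$sim <- unclass(sim)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.icplnc_config <- function(x, ...) {
  cat("icplnc pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write a pair table as an edge-list TSV
#' @param pt a pair table from [extract_pairs()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pt, path) {
  write.table(pt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
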