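#' Configuration for synthetic immune panels and tumor cohorts
#'
#' Defines the generative model used to validate the pipeline: Gaussian
#' log2-scale expression (baseline mean 5, sd `noise_sd`), immune-cell
#' panels with designated immune-high genes (+2 log2 shift) and additive
#' batch offsets, and tumor cohorts with a latent infiltration gradient
#' that drives the immunologic-constant-of-rejection (ICR) and immune
#' signature genes, planted ICP-lncRNA pairs with bivariate-normal
#' residual correlation, exponential survival whose log-hazard is a linear
#' combination of designated pair means, and Bernoulli immunotherapy
#' response driven by pair-level scores.
#'
#' @param n_icp,n_lnc,n_background gene counts per class.
#' @param n_icr,n_immune_sig counts of dedicated ICR-panel and immune
#'   signature genes (class `other`).
#' @param n_cell_types number of immune cell types in the panel (18,
#'   matching the breadth of purified immune-cell compendia).
#' @param samples_per_cell_type samples per cell type.
#' @param n_batches,batch_shift_sd batch structure of the panel: per
#'   (gene, batch) additive offsets drawn Normal(0, `batch_shift_sd`).
#' @param n_immune_high designated immune-high genes per cell type, drawn
#'   from the ICP and lncRNA genes.
#' @param samples_per_cohort tumor cohort size.
#' @param planted_pairs data.frame with columns `icp`, `lnc`, `rho`
#'   (|rho| < 1): pairs given correlated residuals on top of the shared
#'   infiltration loading, so `rho` is the partial correlation given
#'   infiltration.
#' @param infiltration_effect loading of ICR/immune-signature genes and
#'   planted pair members on the latent infiltration score.
#' @param prognostic_pairs data.frame with columns `icp`, `lnc`, `beta`:
#'   log-hazard per unit of the pair mean expression (centered).
#' @param censor_rate fraction of samples administratively censored,
#'   in [0, 1).
#' @param response_pairs data.frame with columns `icp`, `lnc`, `weight`:
#'   logit weights of standardized pair means in the response model.
#' @param noise_sd residual sd of log2 expression.
#' @param seed master seed for the generator.
#' @return a classed list of settings.
#' @export
sim_config <- function(n_icp = 20, n_lnc = 40, n_background = 200,
                       n_icr = 20, n_immune_sig = 50,
                       n_cell_types = 18, samples_per_cell_type = 10,
                       n_batches = 3, batch_shift_sd = 0.5,
                       n_immune_high = 10,
                       samples_per_cohort = 300,
                       planted_pairs = NULL,
                       infiltration_effect = 1,
                       prognostic_pairs = NULL,
                       censor_rate = 0.3,
                       response_pairs = NULL,
                       noise_sd = 1,
                       seed = 1L) {
  cfg <- list(n_icp = n_icp, n_lnc = n_lnc, n_background = n_background,
              n_icr = n_icr, n_immune_sig = n_immune_sig,
              n_cell_types = n_cell_types,
              samples_per_cell_type = samples_per_cell_type,
              n_batches = n_batches, batch_shift_sd = batch_shift_sd,
              n_immune_high = n_immune_high,
              samples_per_cohort = samples_per_cohort,
              planted_pairs = as_pair_df(planted_pairs, "rho"),
              infiltration_effect = infiltration_effect,
              prognostic_pairs = as_pair_df(prognostic_pairs, "beta"),
              censor_rate = censor_rate,
              response_pairs = as_pair_df(response_pairs, "weight"),
              noise_sd = noise_sd, seed = as.integer(seed))
  genes <- sim_gene_ids(cfg)
  if (nrow(cfg$planted_pairs)) {
    if (any(abs(cfg$planted_pairs$rho) >= 1))
      stop("planted pair |rho| must be < 1")
    check_pair_genes(cfg$planted_pairs, genes)
  }
  if (nrow(cfg$prognostic_pairs)) check_pair_genes(cfg$prognostic_pairs, genes)
  if (nrow(cfg$response_pairs)) check_pair_genes(cfg$response_pairs, genes)
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  if (cfg$n_immune_high > cfg$n_icp + cfg$n_lnc)
    stop("n_immune_high exceeds the number of ICP and lncRNA genes")
  class(cfg) <- "sim_config"
  cfg
}

as_pair_df <- function(x, value_col) {
  if (is.null(x))
    return(setNames(data.frame(character(), character(), numeric()),
                    c("icp", "lnc", value_col)))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  stopifnot(all(c("icp", "lnc", value_col) %in% names(x)))
  x[, c("icp", "lnc", value_col)]
}

check_pair_genes <- function(pairs, genes) {
  miss <- setdiff(c(pairs$icp, pairs$lnc), genes$gene_id)
  if (length(miss))
    stop("pair gene(s) not in the simulated gene universe: ",
         paste(miss, collapse = ", "))
  bad_icp <- pairs$icp[genes$class[match(pairs$icp, genes$gene_id)] != "ICP"]
  bad_lnc <- pairs$lnc[genes$class[match(pairs$lnc, genes$gene_id)] != "lncRNA"]
  if (length(bad_icp) || length(bad_lnc))
    stop("pair members must be ICP x lncRNA; offending: ",
         paste(c(bad_icp, bad_lnc), collapse = ", "))
  invisible(TRUE)
}

#' Gene universe of a simulation configuration
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `gene_id`, `class`
#'   (`ICP`/`lncRNA`/`other`) and `role`
#'   (`icp`/`lnc`/`icr`/`immune_sig`/`background`).
#' @export
sim_gene_ids <- function(cfg) {
  ids <- c(sprintf("ICP%03d", seq_len(cfg$n_icp)),
           sprintf("LNC%03d", seq_len(cfg$n_lnc)),
           sprintf("ICR%02d", seq_len(cfg$n_icr)),
           sprintf("IMM%03d", seq_len(cfg$n_immune_sig)),
           sprintf("BG%04d", seq_len(cfg$n_background)))
  cls <- c(rep("ICP", cfg$n_icp), rep("lncRNA", cfg$n_lnc),
           rep("other", cfg$n_icr + cfg$n_immune_sig + cfg$n_background))
  role <- c(rep("icp", cfg$n_icp), rep("lnc", cfg$n_lnc),
            rep("icr", cfg$n_icr), rep("immune_sig", cfg$n_immune_sig),
            rep("background", cfg$n_background))
  data.frame(gene_id = ids, class = cls, role = role,
             stringsAsFactors = FALSE)
}

#' Gene class map and gene-set catalog implied by a simulation config
#' @param cfg a [sim_config()].
#' @return list with `classes` (a gene class map) and `sets` (named list
#'   with the ICR panel and the immune signature).
#' @export
sim_gene_annotation <- function(cfg) {
  g <- sim_gene_ids(cfg)
  list(classes = gene_class_map(icp = g$gene_id[g$class == "ICP"],
                                lncrna = g$gene_id[g$class == "lncRNA"],
                                other = g$gene_id[g$class == "other"]),
       sets = list(ICR = g$gene_id[g$role == "icr"],
                   IMMUNE_SIG = g$gene_id[g$role == "immune_sig"]))
}

#' Simulate a multi-batch purified immune-cell expression panel
#'
#' Each cell type receives a designated immune-high subset of the ICP and
#' lncRNA genes whose mean is shifted +2 log2 units above the
#' Normal(5, `noise_sd`) baseline; every (gene, batch) combination receives
#' an additive Normal(0, `batch_shift_sd`) offset. The returned truth
#' records which genes are immune-high in which cell types, which is what
#' the immune screen must recover.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` (an `expr_matrix`), `annotation` (sample
#'   annotation data.frame with `cell_type` and `batch`), and `truth`
#'   (a `sim_truth` list).
#' @export
simulate_immune_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_cell_types < 2 || cfg$samples_per_cell_type < 2)
    stop("need >= 2 cell types and >= 2 samples per cell type")
  genes <- sim_gene_ids(cfg)
  candidates <- genes$gene_id[genes$class %in% c("ICP", "lncRNA")]
  if (cfg$n_immune_high > length(candidates))
    stop("n_immune_high exceeds available ICP/lncRNA genes")
  n_genes <- nrow(genes)
  cell_types <- sprintf("CT%02d", seq_len(cfg$n_cell_types))
  n_samples <- cfg$n_cell_types * cfg$samples_per_cell_type
  with_seed(stage_seed(cfg$seed, "immune_panel"), {
    high_by_type <- lapply(cell_types, function(ct)
      sort(sample(candidates, cfg$n_immune_high)))
    names(high_by_type) <- cell_types
    ann <- data.frame(
      sample_id = sprintf("IM%04d", seq_len(n_samples)),
      cohort = "immune_panel",
      cell_type = rep(cell_types, each = cfg$samples_per_cell_type),
      batch = sprintf("B%02d", rep_len(seq_len(cfg$n_batches), n_samples)),
      stringsAsFactors = FALSE)
    vals <- matrix(rnorm(n_genes * n_samples, mean = 5, sd = cfg$noise_sd),
                   nrow = n_genes,
                   dimnames = list(genes$gene_id, ann$sample_id))
    for (ct in cell_types) {
      cols <- ann$cell_type == ct
      vals[high_by_type[[ct]], cols] <- vals[high_by_type[[ct]], cols] + 2
    }
    batches <- unique(ann$batch)
    batch_shift <- matrix(rnorm(n_genes * length(batches), 0,
                                cfg$batch_shift_sd),
                          nrow = n_genes,
                          dimnames = list(genes$gene_id, batches))
    for (b in batches) {
      cols <- ann$batch == b
      vals[, cols] <- vals[, cols] + batch_shift[, b]
    }
  })
  truth <- structure(list(kind = "immune_panel",
                          immune_high = high_by_type,
                          batch_shift = batch_shift),
                     class = "sim_truth")
  list(expr = expression_matrix(vals), annotation = validate_annotation(ann),
       truth = truth)
}

#' Simulate a tumor cohort with planted structure
#'
#' Generates `samples_per_cohort` tumors with: a latent infiltration score
#' u ~ Normal(0,1); ICR-panel and immune-signature genes (and planted pair
#' members) loaded on u with slope `infiltration_effect`; planted
#' ICP-lncRNA pairs whose residuals are bivariate normal with correlation
#' rho; exponential survival with log-hazard equal to the sum of
#' `beta * (centered pair mean)` over prognostic pairs, administratively
#' censored at the empirical quantile matching `censor_rate`; binary
#' immunotherapy response Bernoulli(plogis(sum of weight * standardized
#' pair mean)); age Normal(60, 10) and sex Bernoulli(0.5).
#'
#' @param cfg a [sim_config()].
#' @param cohort_id cohort label stored in the annotation.
#' @return list with `expr`, `annotation`, and `truth` (per-sample
#'   infiltration, linear hazard predictor, response probabilities, and the
#'   planted pair tables).
#' @export
simulate_tumor_cohort <- function(cfg, cohort_id = "cohort1") {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$samples_per_cohort < 20)
    stop("samples_per_cohort must be >= 20")
  genes <- sim_gene_ids(cfg)
  n_genes <- nrow(genes)
  n <- cfg$samples_per_cohort
  sample_ids <- sprintf("%s_S%04d", cohort_id, seq_len(n))
  with_seed(stage_seed(cfg$seed, paste0("tumor_", cohort_id)), {
    u <- rnorm(n)
    vals <- matrix(rnorm(n_genes * n, mean = 5, sd = cfg$noise_sd),
                   nrow = n_genes,
                   dimnames = list(genes$gene_id, sample_ids))
    loaded <- genes$gene_id[genes$role %in% c("icr", "immune_sig")]
    vals[loaded, ] <- vals[loaded, ] +
      rep(cfg$infiltration_effect * u, each = length(loaded))
    if (nrow(cfg$planted_pairs)) {
      for (k in seq_len(nrow(cfg$planted_pairs))) {
        p <- cfg$planted_pairs[k, ]
        e1 <- rnorm(n, 0, cfg$noise_sd)
        e2 <- p$rho * e1 + sqrt(1 - p$rho^2) * rnorm(n, 0, cfg$noise_sd)
        vals[p$icp, ] <- 5 + cfg$infiltration_effect * u + e1
        vals[p$lnc, ] <- 5 + cfg$infiltration_effect * u + e2
      }
    }
    lp <- rep(0, n)
    if (nrow(cfg$prognostic_pairs)) {
      for (k in seq_len(nrow(cfg$prognostic_pairs))) {
        p <- cfg$prognostic_pairs[k, ]
        pm <- (vals[p$icp, ] + vals[p$lnc, ]) / 2
        lp <- lp + p$beta * (pm - mean(pm))
      }
    }
    t_raw <- rexp(n, rate = exp(lp) / 1000)
    if (cfg$censor_rate > 0) {
      cpoint <- quantile(t_raw, probs = 1 - cfg$censor_rate, type = 1)
      os_event <- as.integer(t_raw <= cpoint)
      os_time <- pmin(t_raw, cpoint)
    } else {
      os_event <- rep(1L, n)
      os_time <- t_raw
    }
    resp_lp <- rep(0, n)
    if (nrow(cfg$response_pairs)) {
      for (k in seq_len(nrow(cfg$response_pairs))) {
        p <- cfg$response_pairs[k, ]
        pm <- (vals[p$icp, ] + vals[p$lnc, ]) / 2
        resp_lp <- resp_lp + p$weight * as.numeric(scale(pm))
      }
    }
    resp_prob <- plogis(resp_lp)
    ici <- ifelse(rbinom(n, 1, resp_prob) == 1, "responder", "non_responder")
    ann <- data.frame(
      sample_id = sample_ids,
      cohort = cohort_id,
      age = rnorm(n, 60, 10),
      sex = rbinom(n, 1, 0.5),
      os_time = os_time,
      os_event = os_event,
      ici_response = ici,
      stringsAsFactors = FALSE)
  })
  truth <- structure(list(kind = "tumor_cohort", cohort = cohort_id,
                          infiltration = setNames(u, sample_ids),
                          hazard_lp = setNames(lp, sample_ids),
                          response_prob = setNames(resp_prob, sample_ids),
                          planted_pairs = cfg$planted_pairs,
                          prognostic_pairs = cfg$prognostic_pairs,
                          response_pairs = cfg$response_pairs),
                     class = "sim_truth")
  list(expr = expression_matrix(vals), annotation = validate_annotation(ann),
       truth = truth)
}

#' Flatten simulation ground truth to a table
#'
#' @param truth a `sim_truth` from either simulator.
#' @return data.frame with columns `entity`, `id`, `partner`, `value` —
#'   one row per planted fact (planted pair rho, prognostic beta, response
#'   weight, per-cell-type immune-high gene).
#' @export
truth_report <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  rows <- list()
  empty <- data.frame(entity = character(), id = character(),
                      partner = character(), value = numeric(),
                      stringsAsFactors = FALSE)
  if (truth$kind == "immune_panel") {
    for (ct in names(truth$immune_high)) {
      g <- truth$immune_high[[ct]]
      if (length(g))
        rows[[ct]] <- data.frame(entity = "immune_high", id = g,
                                 partner = ct, value = 2,
                                 stringsAsFactors = FALSE)
    }
  } else {
    add_pairs <- function(df, entity, col) {
      if (nrow(df))
        data.frame(entity = entity, id = df$icp, partner = df$lnc,
                   value = df[[col]], stringsAsFactors = FALSE)
    }
    rows <- list(add_pairs(truth$planted_pairs, "planted_pair", "rho"),
                 add_pairs(truth$prognostic_pairs, "prognostic_pair", "beta"),
                 add_pairs(truth$response_pairs, "response_pair", "weight"))
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a truth report to TSV
#' @param truth a `sim_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth_report(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
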