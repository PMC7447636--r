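#' Configuration of the replicated differential-expression procedure
#'
#' @param n_reps number of replicate runs per fusion pair (each with a fresh
#'   random control draw); the full-scale procedure uses 1000.
#' @param q_threshold FDR threshold for calling a gene significant in a run.
#' @param significance_rule fraction of runs (among those where the gene was
#'   tested) in which a gene must be significant to be reported.
#' @param seed integer master seed; per-replicate streams are derived from
#'   it with the replicate index mixed in.
#' @return object of class `fs_de_config`.
#' @export
de_config <- function(n_reps = 1000L, q_threshold = 0.05,
                      significance_rule = 0.5, seed = 1L) {
  if (n_reps < 1L) stop("config error: n_reps must be >= 1")
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("config error: q_threshold must lie in (0, 1)")
  if (significance_rule <= 0 || significance_rule > 1)
    stop("config error: significance_rule must lie in (0, 1]")
  structure(list(n_reps = as.integer(n_reps), q_threshold = q_threshold,
                 significance_rule = significance_rule,
                 seed = as.integer(seed)),
            class = "fs_de_config")
}

#' Build fusion-pair case groups and the shared control pool
#'
#' Case samples of a pair are samples carrying a protein-producing fusion of
#' that pair with at least one intact PK-/TF-specific domain. The control
#' pool consists of samples whose protein-producing fusions are all
#' non-PK/TF ("other" category); a sample with any PK/TF protein-producing
#' fusion is excluded from the pool. Only samples with an expression file
#' count; pairs with fewer than two such case samples are dropped with a
#' logged count. An empty control pool is a hard error — the procedure is
#' undefined without controls.
#'
#' @param fusions annotated per-call fusion data.frame (all calls, with
#'   `sample_barcode`, `pair`, `category`, `protein_producing`,
#'   `fusion_key`).
#' @param domain_calls domain-call table from [map_domains()].
#' @param specificity specificity table from [classify_specificity()].
#' @param count_barcodes barcodes for which expression files exist.
#' @return list of `fs_pair_group` objects, each with `pair`,
#'   `case_samples`, `control_pool`.
#' @export
build_groups <- function(fusions, domain_calls, specificity,
                         count_barcodes) {
  spec_acc <- specificity$accession[
    specificity$class %in% c("PK-specific", "TF-specific")]
  intact_spec_keys <- unique(domain_calls$fusion_key[
    domain_calls$intact & domain_calls$accession %in% spec_acc])

  pp <- fusions[fusions$protein_producing, , drop = FALSE]
  is_pktf <- pp$category %in% c("PK", "TF", "PK-TF")

  # control pool: protein-producing fusions present, none of them PK/TF
  pool_all <- setdiff(unique(pp$sample_barcode),
                      unique(pp$sample_barcode[is_pktf]))
  pool <- intersect(pool_all, count_barcodes)
  if (!length(pool))
    stop("build_groups: empty control pool — no samples whose ",
         "protein-producing fusions are all non-PK/TF")

  case_rows <- pp[pp$fusion_key %in% intact_spec_keys, , drop = FALSE]
  groups <- list(); dropped <- 0L
  for (pr in unique(case_rows$pair)) {
    cases <- intersect(
      unique(case_rows$sample_barcode[case_rows$pair == pr]),
      count_barcodes)
    if (length(cases) < 2L) { dropped <- dropped + 1L; next }
    groups[[length(groups) + 1L]] <- structure(
      list(pair = pr, case_samples = sort(cases),
           control_pool = sort(setdiff(pool, cases))),
      class = "fs_pair_group")
  }
  if (dropped)
    message("build_groups: dropped ", dropped,
            " pair(s) with fewer than 2 expression files")
  groups
}

#' Draw a control sample set for one replicate
#'
#' `k` distinct barcodes drawn uniformly without replacement from the
#' group's control pool; reproducible given the seed.
#'
#' @param group an `fs_pair_group` object.
#' @param k number of controls (equal to the number of case samples).
#' @param seed integer seed for this draw.
#' @return character vector of barcodes, or `NULL` (with a warning) when the
#'   pool is smaller than `k` — the caller skips the group.
#' @export
sample_controls <- function(group, k, seed) {
  if (length(group$control_pool) < k) {
    warning("sample_controls: control pool smaller than ", k,
            " for pair ", group$pair, "; group skipped")
    return(NULL)
  }
  set.seed(seed)
  sample(group$control_pool, k)
}

#' Negative-binomial differential-expression test for one case/control split
#'
#' NB generalized linear model per gene with RLE size-factor normalization,
#' dispersion shrinkage toward a mean trend (edgeR's `estimateDisp`), a
#' quasi-likelihood F-test of the case-vs-control coefficient (the
#' small-sample-calibrated variant of the NB GLM test), and
#' Benjamini-Hochberg adjustment. Genes with zero counts across all selected
#' samples are excluded from testing and from the multiple-testing
#' denominator. `basemean` and the per-condition means ("expected values")
#' are normalized mean counts.
#'
#' @param counts integer matrix, genes x samples.
#' @param case_samples,control_samples column names of the two sides
#'   (>= 2 each).
#' @return data.frame: `gene_id`, `basemean`, `case_mean`, `control_mean`,
#'   `log2fc` (case over control), `p`, `q`.
#' @export
de_test <- function(counts, case_samples, control_samples) {
  stopifnot(length(case_samples) >= 2L, length(control_samples) >= 2L)
  sub <- counts[, c(control_samples, case_samples), drop = FALSE]
  keep <- rowSums(sub) > 0L
  sub <- sub[keep, , drop = FALSE]
  grp <- factor(rep(c("control", "case"),
                    c(length(control_samples), length(case_samples))),
                levels = c("control", "case"))
  y <- edgeR::DGEList(counts = sub, group = grp)
  y <- edgeR::calcNormFactors(y, method = "RLE")
  design <- stats::model.matrix(~grp)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  lrt <- edgeR::glmQLFTest(fit, coef = 2L)
  eff_lib <- y$samples$lib.size * y$samples$norm.factors
  norm <- sweep(sub, 2L, eff_lib / mean(eff_lib), "/")
  data.frame(
    gene_id = rownames(sub),
    basemean = rowMeans(norm),
    case_mean = rowMeans(norm[, grp == "case", drop = FALSE]),
    control_mean = rowMeans(norm[, grp == "control", drop = FALSE]),
    log2fc = lrt$table$logFC,
    p = lrt$table$PValue,
    q = p.adjust(lrt$table$PValue, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Replicated random-control differential expression for one pair group
#'
#' Runs [de_test()] `n_reps` times with a fresh control draw per replicate,
#' then averages basemean and the per-condition means across the replicates
#' in which each gene was tested. A gene is reported when it was significant
#' (`q < q_threshold`) in at least `significance_rule` of those replicates.
#' The reported fold change is computed from the averaged condition means
#' with a pseudocount of 0.5.
#'
#' @param group an `fs_pair_group` object.
#' @param counts integer matrix, genes x samples.
#' @param config an [de_config()] object.
#' @param report_all diagnostic switch: report every tested gene regardless
#'   of the significance rule (used to inspect averaging behavior).
#' @return data.frame: `pair`, `gene_id`, `avg_basemean`, `avg_case_mean`,
#'   `avg_control_mean`, `log2fc`, `q` (median across replicates),
#'   `n_runs_significant`, `n_runs_tested`, `direction`; `NULL` when the
#'   control pool is too small.
#' @export
replicate_and_average <- function(group, counts, config,
                                  report_all = FALSE) {
  stopifnot(inherits(config, "fs_de_config"))
  k <- length(group$case_samples)
  genes <- rownames(counts)
  n_tested <- n_sig <- sum_base <- sum_case <- sum_ctrl <-
    setNames(numeric(length(genes)), genes)
  qs <- list()
  pair_hash <- sum(utf8ToInt(group$pair))
  for (rep_i in seq_len(config$n_reps)) {
    ctrl <- sample_controls(group, k,
                            derive_seed(config$seed + pair_hash, rep_i))
    if (is.null(ctrl)) return(NULL)
    res <- de_test(counts, group$case_samples, ctrl)
    n_tested[res$gene_id] <- n_tested[res$gene_id] + 1
    n_sig[res$gene_id] <- n_sig[res$gene_id] +
      (res$q < config$q_threshold)
    sum_base[res$gene_id] <- sum_base[res$gene_id] + res$basemean
    sum_case[res$gene_id] <- sum_case[res$gene_id] + res$case_mean
    sum_ctrl[res$gene_id] <- sum_ctrl[res$gene_id] + res$control_mean
    qs[[rep_i]] <- setNames(res$q, res$gene_id)
  }
  tested <- n_tested > 0
  report <- if (report_all) tested else
    tested & (n_sig / pmax(n_tested, 1)) >= config$significance_rule
  if (!any(report))
    return(data.frame(pair = character(0), gene_id = character(0),
                      avg_basemean = numeric(0), avg_case_mean = numeric(0),
                      avg_control_mean = numeric(0), log2fc = numeric(0),
                      q = numeric(0), n_runs_significant = integer(0),
                      n_runs_tested = integer(0), direction = character(0),
                      stringsAsFactors = FALSE))
  g <- genes[report]
  avg_case <- sum_case[g] / n_tested[g]
  avg_ctrl <- sum_ctrl[g] / n_tested[g]
  med_q <- vapply(g, function(gg)
    median(unlist(lapply(qs, function(q) q[[gg]] %||% NULL)), na.rm = TRUE),
    numeric(1))
  lfc <- log2((avg_case + 0.5) / (avg_ctrl + 0.5))
  data.frame(
    pair = group$pair, gene_id = g,
    avg_basemean = unname(sum_base[g] / n_tested[g]),
    avg_case_mean = unname(avg_case), avg_control_mean = unname(avg_ctrl),
    log2fc = unname(lfc), q = unname(med_q),
    n_runs_significant = as.integer(unname(n_sig[g])),
    n_runs_tested = as.integer(unname(n_tested[g])),
    direction = ifelse(lfc > 0, "over", "under"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Pathway over/under-expression z-scores
#'
#' Restricted to lowest-level hierarchy terms. Per pathway, the z-score is
#' the number of overexpressed minus underexpressed significant genes
#' annotated to it, divided by the square root of their total:
#' `z = (n_up - n_down) / sqrt(n_up + n_down)`. Pathways with no significant
#' genes are omitted; pathways with `|z| > z_highlight` are flagged.
#'
#' @param degenes reported gene table from [replicate_and_average()]
#'   (columns `gene_id`, `direction`), possibly concatenated over pairs.
#' @param dag an `fs_pathway_dag` object (its leaf terms are used).
#' @param z_highlight highlight threshold (default 7.5).
#' @return data.frame: `pathway_id`, `n_up`, `n_down`, `z`, `highlight`.
#' @export
pathway_zscores <- function(degenes, dag, z_highlight = 7.5) {
  ann <- dag$annotations
  ann <- ann[ann$pathway_id %in% dag$leaves, , drop = FALSE]
  out <- do.call(rbind, lapply(unique(ann$pathway_id), function(pw) {
    genes <- ann$gene_id[ann$pathway_id == pw]
    sel <- degenes$gene_id %in% genes
    n_up <- sum(sel & degenes$direction == "over")
    n_down <- sum(sel & degenes$direction == "under")
    if (n_up + n_down == 0L) return(NULL)
    data.frame(pathway_id = pw, n_up = n_up, n_down = n_down,
               z = (n_up - n_down) / sqrt(n_up + n_down),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(pathway_id = character(0), n_up = integer(0),
                      n_down = integer(0), z = numeric(0),
                      highlight = logical(0), stringsAsFactors = FALSE))
  out$highlight <- abs(out$z) > z_highlight
  out
}
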