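#' Pipeline configuration
#'
#' Collects every input path and threshold of the end-to-end workflow and
#' validates them before any stage runs: thresholds must be in range and
#' every referenced path must exist.
#'
#' @param gtf,fasta gene models and genome.
#' @param calls fusion breakpoint calls TSV.
#' @param pk,tf PK / TF gene-list TSVs.
#' @param domains domain instance TSV.
#' @param clinical clinical TSV.
#' @param interactions PSI-MITAB-subset TSV.
#' @param pathway_edges,pathway_annotations pathway hierarchy TSVs.
#' @param census census gene-list TSV (optional, `NULL` to skip enrichment).
#' @param counts_dir directory of HTSeq-count files.
#' @param out_dir output directory.
#' @param aa_min minimum per-partner amino-acid contribution (exclusive) for
#'   a protein-producing call.
#' @param specificity domain-specificity threshold.
#' @param q FDR threshold.
#' @param z_highlight pathway z-score highlight threshold.
#' @param n_reps differential-expression replicates per pair.
#' @param significance_rule run-fraction rule for reporting a gene.
#' @param seed integer master seed.
#' @return validated `fs_pipeline_config` object.
#' @export
pipeline_config <- function(gtf, fasta, calls, pk, tf, domains, clinical,
                            interactions, pathway_edges,
                            pathway_annotations, census = NULL, counts_dir,
                            out_dir, aa_min = 30L, specificity = 0.95,
                            q = 0.05, z_highlight = 7.5, n_reps = 20L,
                            significance_rule = 0.5, seed = 1L) {
  cfg <- list(gtf = gtf, fasta = fasta, calls = calls, pk = pk, tf = tf,
              domains = domains, clinical = clinical,
              interactions = interactions, pathway_edges = pathway_edges,
              pathway_annotations = pathway_annotations, census = census,
              counts_dir = counts_dir, out_dir = out_dir,
              aa_min = as.integer(aa_min), specificity = specificity,
              q = q, z_highlight = z_highlight, n_reps = as.integer(n_reps),
              significance_rule = significance_rule, seed = as.integer(seed))
  if (cfg$q <= 0 || cfg$q >= 1)
    stop("pipeline config: q must lie in (0, 1)")
  if (cfg$specificity <= 0 || cfg$specificity > 1)
    stop("pipeline config: specificity must lie in (0, 1]")
  if (cfg$aa_min < 0L) stop("pipeline config: aa_min must be >= 0")
  if (cfg$z_highlight <= 0) stop("pipeline config: z_highlight must be > 0")
  if (cfg$n_reps < 1L) stop("pipeline config: n_reps must be >= 1")
  paths <- c(cfg$gtf, cfg$fasta, cfg$calls, cfg$pk, cfg$tf, cfg$domains,
             cfg$clinical, cfg$interactions, cfg$pathway_edges,
             cfg$pathway_annotations, cfg$census, cfg$counts_dir)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("pipeline config: missing input path(s): ",
         paste(missing, collapse = ", "))
  structure(cfg, class = "fs_pipeline_config")
}

#' Run the full fusion-characterization pipeline
#'
#' Executes the stages in order — annotate, cohort, domains, network,
#' differential expression — writing each stage's tables under
#' `config$out_dir` and returning a run manifest (stage row counts, input
#' checksums, seed). Reruns with an identical config and seed are
#' bit-identical.
#'
#' @param config an [pipeline_config()] object.
#' @return the manifest, invisibly (also written to `manifest.tsv`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fs_pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  stage_rows <- c()

  # --- annotate ---
  models <- read_gene_models(config$gtf, config$fasta)
  pk <- read_gene_list(config$pk); tf <- read_gene_list(config$tf)
  models <- label_gene_classes(models, pk, tf)
  calls <- read_fusion_calls(config$calls)
  ann <- annotate_fusions(calls, models, pk, tf)
  ann$protein_producing <- ann$protein_producing &
    ann$aa5 > config$aa_min & ann$aa3 > config$aa_min
  uni <- deduplicate(ann, "full")
  write_tsv(ann, file.path(out, "fusions_all_calls.tsv"))
  write_tsv(uni, file.path(out, "fusions_unique.tsv"))
  prots <- uni$protein[uni$protein_producing]
  names(prots) <- uni$fusion_key[uni$protein_producing]
  if (length(prots))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(prots),
                                file.path(out, "fusion_proteins.fa"))
  stage_rows["annotate"] <- nrow(uni)

  # --- cohort ---
  clinical <- read_clinical(config$clinical)
  per_sample <- ann[!duplicated(paste(ann$fusion_key, ann$sample_barcode)), ,
                    drop = FALSE]
  joined <- join_clinical(per_sample, clinical)
  summaries <- summarize_by_project_stage(joined, clinical)
  write_tsv(summaries$stage_summary, file.path(out, "stage_summary.tsv"))
  write_tsv(summaries$project_summary, file.path(out, "project_summary.tsv"))
  contig_lengths <- setNames(Biostrings::width(models$genome),
                             names(models$genome))
  bins <- bin_breakpoints(c(calls$contig5, calls$contig3),
                          c(calls$pos5, calls$pos3), contig_lengths)
  write_tsv(bins, file.path(out, "breakpoint_bins.tsv"))
  stage_rows["cohort"] <- nrow(summaries$stage_summary)

  # --- domains ---
  domains <- read_domain_table(config$domains, models)
  dom_fusions <- deduplicate(uni, "pair_protein")
  dom_fusions <- join_clinical(dom_fusions, clinical)
  dcalls <- map_domains(dom_fusions, domains)
  specificity <- classify_specificity(dcalls, dom_fusions, pk, tf,
                                      threshold = config$specificity)
  dsum <- summarize_domains(dcalls, dom_fusions, specificity)
  write_tsv(dcalls, file.path(out, "domain_calls.tsv"))
  write_tsv(specificity, file.path(out, "domain_specificity.tsv"))
  write_tsv(dsum$overall, file.path(out, "domain_summary.tsv"))
  if (!is.null(dsum$per_project))
    write_tsv(dsum$per_project, file.path(out, "domain_by_project.tsv"))
  stage_rows["domains"] <- nrow(dcalls)

  # --- network ---
  edges <- read_interactions(config$interactions)
  dag <- pathway_dag(read_pathway_edges(config$pathway_edges),
                     read_pathway_annotations(config$pathway_annotations))
  dist <- root_distances(dag)
  write_tsv(data.frame(pathway_id = names(dist), root_distance = dist),
            file.path(out, "pathway_root_distances.tsv"))
  pp_uni <- join_clinical(uni[uni$protein_producing, , drop = FALSE],
                          clinical)
  sets <- interactor_sets(pp_uni, edges)
  pktf_keys <- pp_uni$fusion_key[pp_uni$category %in%
                                   c("PK", "TF", "PK-TF")]
  loads <- pathway_loads(sets[names(sets) %in% pktf_keys], dag, pp_uni)
  write_tsv(loads, file.path(out, "pathway_loads.tsv"))
  if (!is.null(config$census)) {
    census <- read_gene_list(config$census)
    enr <- census_enrichment(sets, census, fusions = pp_uni)
    enr_df <- data.frame(
      subset = c("all", names(enr$top_k), names(enr$by_category)),
      proportion = c(enr$overall, enr$top_k, enr$by_category),
      stringsAsFactors = FALSE)
    write_tsv(enr_df, file.path(out, "census_enrichment.tsv"))
  }
  stage_rows["network"] <- length(sets)

  # --- differential expression ---
  count_files <- sort(list.files(config$counts_dir,
                                 pattern = "\\.counts\\.tsv$",
                                 full.names = TRUE))
  counts <- read_htseq_counts(count_files)
  groups <- build_groups(ann, dcalls, specificity, colnames(counts))
  cfgde <- de_config(n_reps = config$n_reps, q_threshold = config$q,
                     significance_rule = config$significance_rule,
                     seed = config$seed)
  de_tables <- list()
  for (g in groups) {
    res <- replicate_and_average(g, counts, cfgde)
    if (!is.null(res)) de_tables[[g$pair]] <- res
  }
  degenes <- if (length(de_tables)) do.call(rbind, de_tables) else
    data.frame(pair = character(0), gene_id = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  rownames(degenes) <- NULL
  write_tsv(degenes, file.path(out, "de_genes.tsv"))
  zt <- pathway_zscores(degenes, dag, z_highlight = config$z_highlight)
  write_tsv(zt, file.path(out, "pathway_zscores.tsv"))
  stage_rows["de"] <- nrow(degenes)

  inputs <- c(config$gtf, config$fasta, config$calls, config$pk, config$tf,
              config$domains, config$clinical, config$interactions,
              config$pathway_edges, config$pathway_annotations,
              config$census)
  manifest <- data.frame(
    key = c(paste0("rows_", names(stage_rows)), "seed",
            paste0("md5_", basename(inputs))),
    value = c(as.character(stage_rows), as.character(config$seed),
              unname(tools::md5sum(inputs))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out, "manifest.tsv"))
  invisible(manifest)
}

#' Write a complete set of synthetic pipeline inputs
#'
#' Generates gene models, domains, fusion calls, gene lists, clinical data,
#' interactions, pathway hierarchy, census list and HTSeq-count files under
#' `dir/`, with planted differential-expression effects attached to the
#' cohort's recurrent fusion pairs (half of each planted gene set up, half
#' down at the given magnitude).
#'
#' @param spec an [cohort_spec()] object.
#' @param dir output directory.
#' @param n_planted_genes planted genes per recurrent pair.
#' @param planted_lfc planted |log2 fold change|.
#' @return list with the generated objects (`models`, `domains`, `cohort`,
#'   `network`, `counts`, `planted`) and `paths`.
#' @export
write_synthetic_inputs <- function(spec, dir, n_planted_genes = 20L,
                                   planted_lfc = 2) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  models <- generate_gene_models(spec)
  dom <- generate_domains(models, spec)
  cohort <- generate_fusion_cohort(models, spec, dom$domains)
  network <- generate_network_and_pathways(models, spec, cohort$samples)

  # attach planted expression effects to the recurrent pairs
  rec <- unique(cohort$truth[cohort$truth$recurrent,
                             c("pair", "sample_barcode")])
  assignment <- data.frame(barcode = cohort$samples$barcode,
                           pair = NA_character_, stringsAsFactors = FALSE)
  planted <- list()
  if (nrow(rec)) {
    set.seed(derive_seed(spec$seed, 9L))
    pairs <- unique(rec$pair)
    pool <- sample(models$genes$gene_id)
    offset <- 0L
    for (pr in pairs) {
      genes <- pool[offset + seq_len(min(n_planted_genes,
                                         length(pool) - offset))]
      offset <- offset + length(genes)
      if (length(genes) < 2L) next
      half <- seq_len(length(genes) %/% 2L)
      planted[[length(planted) + 1L]] <-
        list(pair = pr, genes = genes[half], log2fc = planted_lfc)
      planted[[length(planted) + 1L]] <-
        list(pair = pr, genes = genes[-half], log2fc = -planted_lfc)
      assignment$pair[assignment$barcode %in%
                        rec$sample_barcode[rec$pair == pr]] <- pr
    }
  }
  counts <- generate_counts(spec, models, assignment,
                            planted_pairs = planted)

  paths <- list(
    gtf = file.path(dir, "genes.gtf"), fasta = file.path(dir, "genome.fa"),
    calls = file.path(dir, "fusion_calls.tsv"),
    pk = file.path(dir, "pk_genes.tsv"), tf = file.path(dir, "tf_genes.tsv"),
    domains = file.path(dir, "domains.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    interactions = file.path(dir, "interactions.mitab.tsv"),
    pathway_edges = file.path(dir, "pathway_edges.tsv"),
    pathway_annotations = file.path(dir, "pathway_annotations.tsv"),
    census = file.path(dir, "census.tsv"),
    counts_dir = file.path(dir, "counts"))
  write_gene_models(models, paths$gtf, paths$fasta)
  write_fusion_calls(cohort$calls, paths$calls)
  write_gene_list(models$genes$gene_id[models$genes$is_pk], paths$pk)
  write_gene_list(models$genes$gene_id[models$genes$is_tf], paths$tf)
  write_domain_table(dom$domains, paths$domains)
  write_clinical(network$clinical, paths$clinical)
  write_interactions(network$interactions, paths$interactions)
  write_pathway_edges(network$pathways$edges, paths$pathway_edges)
  write_pathway_annotations(network$pathways$annotations,
                            paths$pathway_annotations)
  write_gene_list(network$census, paths$census)
  write_htseq_counts(counts$counts, paths$counts_dir)

  list(models = models, domains = dom, cohort = cohort, network = network,
       counts = counts, planted = planted, paths = paths)
}

#' Generate synthetic inputs and run the whole pipeline
#'
#' The demo entry point: writes a synthetic cohort under `out_dir/inputs`,
#' then runs every stage with outputs under `out_dir/results`. Identical
#' seeds yield byte-identical outputs.
#'
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @param spec cohort specification (defaults to [cohort_spec()] with the
#'   given seed).
#' @param n_reps differential-expression replicates per pair.
#' @return the run manifest, invisibly.
#' @export
run_demo <- function(seed, out_dir, spec = cohort_spec(seed = seed),
                     n_reps = 20L) {
  inputs_dir <- file.path(out_dir, "inputs")
  gen <- write_synthetic_inputs(spec, inputs_dir)
  cfg <- do.call(pipeline_config, c(
    gen$paths,
    list(out_dir = file.path(out_dir, "results"), n_reps = n_reps,
         seed = seed)))
  run_pipeline(cfg)
}
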