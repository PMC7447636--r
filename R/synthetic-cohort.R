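# Candidate junctions of a gene pair. The 5' junction sits at the end of an
# exon, strictly inside the coding region and upstream of the stop codon (so
# the 5' contribution carries coding sequence and no stop); the 3' junction
# sits at the start of a non-first exon inside the 3' partner's coding region.
junction_candidates <- function(models, gene5, gene3) {
  g5 <- gene_row(models, gene5); g3 <- gene_row(models, gene3)
  ex5 <- gene_exons(models, gene5); ex3 <- gene_exons(models, gene3)
  j5 <- ex5$tx_end[ex5$tx_end >= g5$cds_tx_start &
                   ex5$tx_end <= g5$cds_tx_end - 3L]
  j3 <- ex3$tx_start[ex3$exon_rank > 1L &
                     ex3$tx_start >= g3$cds_tx_start &
                     ex3$tx_start <= g3$cds_tx_end - 3L]
  if (!length(j5) || !length(j3)) return(NULL)
  cand <- expand.grid(j5 = j5, j3 = j3)
  nt5 <- cand$j5 - g5$cds_tx_start + 1L
  o3 <- cand$j3 - g3$cds_tx_start
  phase <- nt5 %% 3L
  inframe <- (o3 %% 3L) == phase
  # a junction-spanning codon that happens to be a stop truncates the protein
  # at the junction; such junctions are not in-frame products
  tx5 <- models$tx_seq[[gene5]]; tx3 <- models$tx_seq[[gene3]]
  for (i in which(inframe & phase > 0L)) {
    hybrid <- paste0(substr(tx5, cand$j5[i] - phase[i] + 1L, cand$j5[i]),
                     substr(tx3, cand$j3[i], cand$j3[i] + 3L - phase[i] - 1L))
    if (hybrid %in% STOP_CODONS) inframe[i] <- FALSE
  }
  cand$nt5 <- nt5; cand$o3 <- o3; cand$inframe <- inframe
  cand
}

# Assemble + translate a synthetic junction; used to record ground truth.
realize_fusion <- function(models, gene5, gene3, j5, j3) {
  g5 <- gene_row(models, gene5)
  tx5 <- models$tx_seq[[gene5]]; tx3 <- models$tx_seq[[gene3]]
  fused <- paste0(substr(tx5, 1L, j5), substr(tx3, j3, nchar(tx3)))
  tr <- translate_to_stop(substr(fused, g5$cds_tx_start, nchar(fused)))
  aa5 <- (j5 - g5$cds_tx_start + 1L) %/% 3L
  aa5 <- min(aa5, nchar(tr$aa))
  list(protein = tr$aa, aa5 = aa5, aa3 = nchar(tr$aa) - aa5)
}

#' Generate a synthetic fusion-call cohort with ground truth
#'
#' Draws `n_fusions` breakpoint calls over the synthetic genome. Breakpoints
#' always fall on annotated exon boundaries (the 5' breakpoint is the last
#' base of an exon of the 5' partner, the 3' breakpoint the first base of an
#' exon of the 3' partner). Each fusion's frame effect is targeted with a
#' Bernoulli draw at `frac_inframe`, so the realized in-frame fraction is
#' binomially distributed around it. Additionally, `n_recurrent` in-frame
#' fusion pairs involving a PK or TF partner are planted in
#' `recurrent_depth` distinct samples each, with junctions chosen so each
#' partner contributes more than 30 amino acids and (when `domains` is given)
#' so that a PK-/TF-planted domain of the PK/TF partner survives intact.
#'
#' @param models an `fs_gene_models` object.
#' @param spec an [cohort_spec()] object.
#' @param domains optional domain table from [generate_domains()], used to
#'   guarantee the planted recurrent fusions retain an intact PK/TF domain.
#' @return list with `calls` (fusion-call table: `sample_barcode`, `gene5`,
#'   `gene3`, `contig5`, `pos5`, `contig3`, `pos3`), `truth` (per-fusion true
#'   effect, amino-acid contributions and protein), and `samples` (barcode /
#'   project table).
#' @export
generate_fusion_cohort <- function(models, spec, domains = NULL) {
  validate_cohort_spec(spec)
  set.seed(derive_seed(spec$seed, 5L))
  samples <- synth_samples(spec)
  empty_calls <- data.frame(
    sample_barcode = character(0), gene5 = character(0), gene3 = character(0),
    contig5 = character(0), pos5 = integer(0), contig3 = character(0),
    pos3 = integer(0), stringsAsFactors = FALSE)
  if (spec$n_fusions == 0L) {
    return(list(calls = empty_calls,
                truth = data.frame(fusion_id = character(0)),
                samples = samples))
  }

  gids <- models$genes$gene_id
  pk_tf <- gids[models$genes$is_pk | models$genes$is_tf]
  calls <- list(); truth <- list()
  fid <- 0L
  emit <- function(barcode, gene5, gene3, j5, j3, effect, recurrent) {
    fid <<- fid + 1L
    g5 <- gene_row(models, gene5); g3 <- gene_row(models, gene3)
    rz <- realize_fusion(models, gene5, gene3, j5, j3)
    calls[[fid]] <<- data.frame(
      sample_barcode = barcode, gene5 = gene5, gene3 = gene3,
      contig5 = g5$contig, pos5 = tx_to_genomic(models, gene5, j5),
      contig3 = g3$contig, pos3 = tx_to_genomic(models, gene3, j3),
      stringsAsFactors = FALSE)
    truth[[fid]] <<- data.frame(
      fusion_id = sprintf("SF%05d", fid), sample_barcode = barcode,
      gene5 = gene5, gene3 = gene3, effect = effect,
      aa5 = rz$aa5, aa3 = rz$aa3, protein = rz$protein,
      pair = paste(sort(c(gene5, gene3)), collapse = "-"),
      recurrent = recurrent, stringsAsFactors = FALSE)
  }

  # planted recurrent in-frame PK/TF pairs (multi-sample, domain-retaining)
  n_rec <- min(spec$n_recurrent,
               if (length(pk_tf)) spec$n_recurrent else 0L)
  planted <- 0L; guard <- 0L
  while (planted < n_rec && guard < 500L) {
    guard <- guard + 1L
    gene3 <- sample(pk_tf, 1L)
    gene5 <- sample(setdiff(gids, gene3), 1L)
    cand <- junction_candidates(models, gene5, gene3)
    if (is.null(cand)) next
    cand <- cand[cand$inframe & cand$nt5 > 93L, , drop = FALSE]
    if (!nrow(cand)) next
    cand <- cand[order(cand$o3), , drop = FALSE]
    ok <- NULL
    for (i in seq_len(nrow(cand))) {
      rz <- realize_fusion(models, gene5, gene3, cand$j5[i], cand$j3[i])
      if (rz$aa5 <= 30L || rz$aa3 <= 30L) next
      if (!is.null(domains)) {
        dom <- domains[domains$protein == gene3 &
                       grepl("^PF(PK|TF)", domains$accession), , drop = FALSE]
        if (!nrow(dom)) break
        if (!any(vapply(dom$sequence, grepl, logical(1),
                        x = rz$protein, fixed = TRUE))) next
      }
      ok <- i; break
    }
    if (is.null(ok)) next
    barcodes <- sample(samples$barcode,
                       min(spec$recurrent_depth, nrow(samples)))
    for (b in barcodes)
      emit(b, gene5, gene3, cand$j5[ok], cand$j3[ok], "in-frame", TRUE)
    planted <- planted + 1L
  }

  # remaining fusions: random pairs, frame class targeted per fusion
  n_left <- spec$n_fusions - fid
  for (f in seq_len(max(0L, n_left))) {
    want_inframe <- runif(1) < spec$frac_inframe
    repeat {
      pair <- sample(gids, 2L)
      cand <- junction_candidates(models, pair[1L], pair[2L])
      if (is.null(cand)) next
      pool <- cand[cand$inframe == want_inframe, , drop = FALSE]
      if (!nrow(pool)) next
      i <- sample(nrow(pool), 1L)
      emit(sample(samples$barcode, 1L), pair[1L], pair[2L],
           pool$j5[i], pool$j3[i],
           if (want_inframe) "in-frame" else "out-of-frame", FALSE)
      break
    }
  }

  list(calls = do.call(rbind, calls), truth = do.call(rbind, truth),
       samples = samples)
}

synth_samples <- function(spec) {
  set.seed(derive_seed(spec$seed, 6L))
  projects <- sprintf("PROJ%d", seq_len(spec$n_projects))
  sites <- vapply(seq_len(spec$n_projects), function(i)
    paste(sample(LETTERS, 2L, replace = TRUE), collapse = ""), character(1))
  proj <- sample(projects, spec$n_samples, replace = TRUE)
  part <- character(spec$n_samples)
  repeat {
    part <- vapply(seq_len(spec$n_samples), function(i)
      paste(sample(c(LETTERS, 0:9), 4L, replace = TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(part)) break
  }
  data.frame(
    barcode = sprintf("TCGA-%s-%s", sites[match(proj, projects)], part),
    project = proj, stringsAsFactors = FALSE)
}

#' Generate a negative-binomial counts matrix with planted fold changes
#'
#' Counts follow `NB(mu, d)` with `var = mu + d * mu^2`: per-gene baseline
#' means are drawn log-uniformly within `spec$nb_mean_log_range` and the
#' dispersion `d = spec$nb_dispersion` is shared. For every planted pair, the
#' planted genes' means are multiplied by `2^log2fc` in that pair's samples.
#'
#' @param spec an [cohort_spec()] object.
#' @param models an `fs_gene_models` object (defines the gene universe).
#' @param assignment data.frame with columns `barcode` and `pair` (`NA` for
#'   samples not assigned to any planted pair); one row per sample.
#' @param planted_pairs list of planted effects (see [cohort_spec()]);
#'   defaults to `spec$planted_pairs`.
#' @return list with `counts` (integer matrix, genes x samples), `base_mu`
#'   (named baseline means) and `truth` (data.frame `pair`, `gene_id`,
#'   `log2fc` covering every planted gene exactly once per pair).
#' @export
generate_counts <- function(spec, models, assignment,
                            planted_pairs = spec$planted_pairs) {
  validate_cohort_spec(spec)
  stopifnot(all(c("barcode", "pair") %in% names(assignment)))
  gids <- models$genes$gene_id
  for (pp in planted_pairs) {
    if (!all(pp$genes %in% gids))
      stop("invalid spec: planted genes outside the gene universe")
    n_assigned <- sum(!is.na(assignment$pair) & assignment$pair == pp$pair)
    if (n_assigned < 2L)
      stop("invalid spec: planted pair ", pp$pair,
           " has fewer than 2 assigned samples")
  }
  set.seed(derive_seed(spec$seed, 7L))
  n_g <- length(gids); n_s <- nrow(assignment)
  base_mu <- setNames(
    exp(runif(n_g, spec$nb_mean_log_range[1], spec$nb_mean_log_range[2])),
    gids)
  mu <- matrix(base_mu, nrow = n_g, ncol = n_s,
               dimnames = list(gids, assignment$barcode))
  truth <- list()
  for (pp in planted_pairs) {
    cols <- which(!is.na(assignment$pair) & assignment$pair == pp$pair)
    mu[pp$genes, cols] <- mu[pp$genes, cols] * 2^pp$log2fc
    truth[[length(truth) + 1L]] <- data.frame(
      pair = pp$pair, gene_id = pp$genes, log2fc = pp$log2fc,
      stringsAsFactors = FALSE)
  }
  counts <- matrix(rnbinom(n_g * n_s, mu = as.vector(mu),
                           size = 1 / spec$nb_dispersion),
                   nrow = n_g, dimnames = dimnames(mu))
  list(counts = counts, base_mu = base_mu,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(pair = character(0), gene_id = character(0),
                    log2fc = numeric(0)))
}

#' Generate the interaction network, pathway hierarchy, clinical table and
#' census list
#'
#' The interaction network is grown by preferential attachment over the gene
#' universe plus a pool of interactor-only proteins, giving a scale-free-ish
#' degree distribution; a `frac_nonphysical` fraction of edges is stamped
#' with non-physical interaction types and/or non-experimental detection
#' methods to exercise downstream filtering. The pathway hierarchy is a
#' rooted DAG of depth `dag_depth` with unit-weight parent->child edges and
#' gene annotations at all levels. The clinical table carries deliberately
#' dirty stage strings ("Stage IIA", "Stage 0", "Stage X", "I/II NOS") and
#' dotted ICD-O-3 topography codes.
#'
#' @param models an `fs_gene_models` object.
#' @param spec an [cohort_spec()] object.
#' @param samples sample table (`barcode`, `project`), e.g. from
#'   [generate_fusion_cohort()].
#' @param n_extra_proteins interactor-only proteins added to the network.
#' @return list with `interactions`, `pathways` (list: `nodes`, `edges`,
#'   `annotations`), `clinical`, `census`.
#' @export
generate_network_and_pathways <- function(models, spec, samples,
                                          n_extra_proteins = 40L) {
  validate_cohort_spec(spec)
  set.seed(derive_seed(spec$seed, 8L))
  proteins <- c(models$genes$gene_id,
                sprintf("INTP%03d", seq_len(n_extra_proteins)))
  g <- igraph::sample_pa(length(proteins), m = 2, directed = FALSE)
  em <- igraph::as_edgelist(g, names = FALSE)
  perm <- sample(proteins)
  a <- perm[em[, 1L]]; b <- perm[em[, 2L]]
  swap <- a > b; tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  keep <- !duplicated(paste(a, b)) & a != b
  a <- a[keep]; b <- b[keep]
  n_e <- length(a)
  bad <- runif(n_e) < spec$frac_nonphysical
  mode <- sample(c("type", "method", "both"), n_e, replace = TRUE)
  itype <- ifelse(bad & mode != "method",
                  sample(c("genetic interaction", "colocalization"), n_e,
                         replace = TRUE),
                  sample(c("physical association", "direct interaction"), n_e,
                         replace = TRUE))
  imeth <- ifelse(bad & mode != "type",
                  sample(c("inference", "predictive text mining"), n_e,
                         replace = TRUE),
                  sample(c("two hybrid", "pull down",
                           "affinity chromatography technology"), n_e,
                         replace = TRUE))
  interactions <- data.frame(
    protein_a = a, protein_b = b, interaction_type = itype,
    detection_method = imeth, stringsAsFactors = FALSE)

  # rooted pathway DAG: level 0 = roots, every level-l node has 1-2 parents
  # in level l-1, so its shortest distance to a root is exactly l
  nodes <- list(); edges <- list(); level_ids <- list()
  nid <- 0L
  for (lvl in 0:spec$dag_depth) {
    n_lvl <- if (lvl == 0L) 2L else 3L + lvl
    ids <- sprintf("PW%03d", nid + seq_len(n_lvl)); nid <- nid + n_lvl
    level_ids[[lvl + 1L]] <- ids
    nodes[[lvl + 1L]] <- data.frame(
      pathway_id = ids, name = paste0("pathway_", tolower(ids)),
      level = lvl, stringsAsFactors = FALSE)
    if (lvl > 0L) {
      for (id in ids) {
        parents <- sample(level_ids[[lvl]], sample(1:2, 1L))
        edges[[length(edges) + 1L]] <- data.frame(
          parent = unique(parents), child = id, stringsAsFactors = FALSE)
      }
    }
  }
  nodes <- do.call(rbind, nodes); edges <- do.call(rbind, edges)
  ann <- do.call(rbind, lapply(proteins, function(p) data.frame(
    gene_id = p,
    pathway_id = sample(nodes$pathway_id, sample(1:3, 1L)),
    stringsAsFactors = FALSE)))

  stage_pool <- c("Stage I", "Stage IA", "Stage IB", "Stage II", "Stage IIA",
                  "Stage IIB", "Stage III", "Stage IIIA", "Stage IIIC1",
                  "Stage IV", "Stage IVA", "Stage 0", "Stage X", "I/II NOS")
  topo_pool <- c("C56.9", "C50.1", "C50.9", "C34.2", "C18.0", "C61", "C16.9",
                 "C71.9")
  clinical <- data.frame(
    barcode = samples$barcode, project = samples$project,
    stage_raw = sample(stage_pool, nrow(samples), replace = TRUE),
    topography_raw = sample(topo_pool, nrow(samples), replace = TRUE),
    stringsAsFactors = FALSE)

  census <- sort(sample(proteins, round(spec$census_rate * length(proteins))))
  list(interactions = interactions,
       pathways = list(nodes = nodes, edges = edges, annotations = ann),
       clinical = clinical, census = census)
}
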