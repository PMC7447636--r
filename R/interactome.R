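#' Pathway hierarchy container
#'
#' A rooted DAG of pathway terms with unit-weight parent->child edges and
#' gene annotations at all hierarchy levels. Roots are nodes with no parent;
#' lowest-level terms are nodes with no children. Construction validates
#' acyclicity and the existence of at least one root.
#'
#' @param edges data.frame with `parent`, `child`.
#' @param annotations data.frame with `gene_id`, `pathway_id`.
#' @param nodes optional data.frame with `pathway_id`, `name` (node universe;
#'   defaults to the union of the edge endpoints and annotated pathways).
#' @return object of class `fs_pathway_dag` with elements `nodes`, `edges`,
#'   `annotations`, `roots`, `leaves`.
#' @export
pathway_dag <- function(edges, annotations, nodes = NULL) {
  ids <- unique(c(edges$parent, edges$child, annotations$pathway_id,
                  nodes$pathway_id))
  if (is.null(nodes))
    nodes <- data.frame(pathway_id = ids, name = ids,
                        stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("parent", "child")], directed = TRUE,
    vertices = data.frame(name = ids))
  if (!igraph::is_dag(g))
    stop("pathway hierarchy validation: graph contains a cycle")
  roots <- setdiff(ids, edges$child)
  if (!length(roots))
    stop("pathway hierarchy validation: no root node (every node has a ",
         "parent)")
  leaves <- setdiff(ids, edges$parent)
  structure(list(nodes = nodes, edges = edges, annotations = annotations,
                 roots = roots, leaves = leaves, graph = g),
            class = "fs_pathway_dag")
}

#' Shortest distance from every pathway node to a hierarchy root
#'
#' Dijkstra's algorithm over the parent->child hierarchy with a weight of 1
#' on every edge: each node's distance is the minimum number of parent links
#' to any root (roots are at distance 0). Nodes that reach no root violate
#' the rooted-DAG invariant and are flagged with an absent distance and a
#' warning.
#'
#' @param dag an `fs_pathway_dag` object.
#' @return named numeric vector of distances (NA for unreachable nodes).
#' @export
root_distances <- function(dag) {
  d <- igraph::distances(dag$graph, v = dag$roots,
                         mode = "out",
                         weights = rep(1, nrow(dag$edges)),
                         algorithm = "dijkstra")
  out <- apply(d, 2L, min)
  unreachable <- !is.finite(out)
  if (any(unreachable)) {
    warning("root_distances: ", sum(unreachable),
            " node(s) cannot reach a root; distance set to NA")
    out[unreachable] <- NA_real_
  }
  out
}

#' Maximal foreseeable interactor set of a fusion
#'
#' The union of both wild-type partners' neighbors over edges that are both
#' physical and experimentally supported, minus the fusion partners
#' themselves. A partner absent from the network contributes nothing.
#'
#' @param gene5,gene3 partner gene ids.
#' @param edges canonical interaction-edge data.frame (see
#'   [read_interactions()]).
#' @return character vector of interactor ids (sorted).
#' @export
build_interactor_set <- function(gene5, gene3, edges) {
  ok <- edges$is_physical & edges$is_experimental
  e <- edges[ok, , drop = FALSE]
  partners <- c(gene5, gene3)
  nb <- c(e$protein_b[e$protein_a %in% partners],
          e$protein_a[e$protein_b %in% partners])
  sort(setdiff(unique(nb), partners))
}

#' Interactor sets for a table of unique fusions
#'
#' @param fusions fusion data.frame with `fusion_key`, `gene5`, `gene3`.
#' @param edges canonical interaction-edge data.frame.
#' @return named list, fusion key -> interactor character vector.
#' @export
interactor_sets <- function(fusions, edges) {
  out <- lapply(seq_len(nrow(fusions)), function(i)
    build_interactor_set(fusions$gene5[i], fusions$gene3[i], edges))
  names(out) <- fusions$fusion_key
  out
}

#' Per-pathway interactor loads
#'
#' For each pathway two statistics are emitted: `n_interacting_fusions`, the
#' number of fusions with at least one interactor annotated to the pathway,
#' and `summed_load`, the sum over the pathway's annotated proteins of the
#' number of fusions each protein interacts with. When fusions carry a
#' project, loads are additionally normalized within each project to
#' `[0, 1]` (1 for the pathway with most interacting fusions; ties all 1).
#'
#' @param sets named list from [interactor_sets()].
#' @param dag an `fs_pathway_dag` object.
#' @param fusions optional fusion data.frame with `fusion_key` and `project`
#'   for per-project normalization.
#' @return data.frame: `pathway_id`, `n_interacting_fusions`, `summed_load`,
#'   and per-project rows with `normalized_frequency` when `fusions` is
#'   given (project `NA` rows are the cohort-wide loads).
#' @export
pathway_loads <- function(sets, dag, fusions = NULL) {
  ann <- dag$annotations
  load_table <- function(keys) {
    sub <- sets[keys]
    gene_fusions <- list()
    for (k in names(sub)) for (p in sub[[k]])
      gene_fusions[[p]] <- c(gene_fusions[[p]], k)
    do.call(rbind, lapply(unique(dag$nodes$pathway_id), function(pw) {
      prots <- ann$gene_id[ann$pathway_id == pw]
      hits <- gene_fusions[intersect(prots, names(gene_fusions))]
      data.frame(pathway_id = pw,
                 n_interacting_fusions = length(unique(unlist(hits))),
                 summed_load = sum(lengths(hits)),
                 stringsAsFactors = FALSE)
    }))
  }
  overall <- load_table(names(sets))
  overall$project <- NA_character_
  mx <- max(overall$n_interacting_fusions)
  overall$normalized_frequency <-
    if (mx > 0) overall$n_interacting_fusions / mx else 0
  if (is.null(fusions) || !"project" %in% names(fusions)) return(overall)

  proj <- fusions$project[match(names(sets), fusions$fusion_key)]
  per <- do.call(rbind, lapply(unique(proj[!is.na(proj)]), function(pr) {
    lt <- load_table(names(sets)[!is.na(proj) & proj == pr])
    lt$project <- pr
    mx <- max(lt$n_interacting_fusions)
    lt$normalized_frequency <-
      if (mx > 0) lt$n_interacting_fusions / mx else 0
    lt
  }))
  rbind(overall, per)
}

#' Cancer-gene-census enrichment of interactors
#'
#' Fraction of unique interactors found on the census list: overall, for the
#' top-k most-interacting fusions (fusions ranked by interactor-set size),
#' and per fusion category.
#'
#' @param sets named list from [interactor_sets()].
#' @param census character vector of census gene ids.
#' @param top_k integer vector of top-k cuts.
#' @param fusions optional fusion data.frame with `fusion_key`, `category`
#'   for the per-category split.
#' @return list with `overall` (proportion or NA for an empty universe),
#'   `top_k` (named numeric) and `by_category` (named numeric or NULL).
#' @export
census_enrichment <- function(sets, census, top_k = c(100L, 10L),
                              fusions = NULL) {
  prop <- function(keys) {
    u <- unique(unlist(sets[keys]))
    if (!length(u)) return(NA_real_)
    mean(u %in% census)
  }
  overall <- prop(names(sets))
  ord <- names(sets)[order(lengths(sets), decreasing = TRUE)]
  tk <- vapply(top_k, function(k) prop(head(ord, k)), numeric(1))
  names(tk) <- paste0("top_", top_k)
  by_cat <- NULL
  if (!is.null(fusions) && "category" %in% names(fusions)) {
    cat <- fusions$category[match(names(sets), fusions$fusion_key)]
    by_cat <- vapply(unique(cat[!is.na(cat)]), function(cc)
      prop(names(sets)[!is.na(cat) & cat == cc]), numeric(1))
  }
  list(overall = overall, top_k = tk, by_category = by_cat)
}
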