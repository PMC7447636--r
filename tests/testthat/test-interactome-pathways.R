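edge_df <- function(a, b, physical = TRUE, experimental = TRUE) {
  sw <- a > b; tmp <- a[sw]; a[sw] <- b[sw]; b[sw] <- tmp
  data.frame(protein_a = a, protein_b = b,
             interaction_type = ifelse(physical, "physical association",
                                       "genetic interaction"),
             detection_method = ifelse(experimental, "two hybrid",
                                       "inference"),
             is_physical = physical, is_experimental = experimental,
             stringsAsFactors = FALSE)
}

test_that("interactor sets are partner-neighborhood unions minus the partners", {
  e <- edge_df(c("A", "A", "B", "B"), c("B", "C", "C", "D"))
  expect_identical(build_interactor_set("A", "B", e), c("C", "D"))
  # non-physical edges contribute nothing
  e2 <- edge_df("A", "C", physical = FALSE)
  expect_identical(build_interactor_set("A", "B", e2), character(0))
  e3 <- edge_df("A", "C", experimental = FALSE)
  expect_identical(build_interactor_set("A", "B", e3), character(0))
  # absent partner contributes nothing (not an error)
  expect_identical(build_interactor_set("Q", "R", e), character(0))
})

test_that("interactor sets equal a brute-force adjacency-scan oracle", {
  spec <- shared_spec()
  m <- shared_models()
  co <- generate_fusion_cohort(m, spec)
  net <- generate_network_and_pathways(m, spec, co$samples)
  dir <- withr::local_tempdir()
  write_interactions(net$interactions, file.path(dir, "i.tsv"))
  edges <- read_interactions(file.path(dir, "i.tsv"))
  ann <- annotate_fusions(co$calls, m)
  uni <- suppressMessages(deduplicate(ann, "full"))[1:100, ]
  sets <- interactor_sets(uni, edges)
  ok_edges <- edges[edges$is_physical & edges$is_experimental, ]
  for (i in seq_len(nrow(uni))) {
    partners <- c(uni$gene5[i], uni$gene3[i])
    nb <- character(0)
    for (k in seq_len(nrow(ok_edges))) {
      if (ok_edges$protein_a[k] %in% partners)
        nb <- c(nb, ok_edges$protein_b[k])
      if (ok_edges$protein_b[k] %in% partners)
        nb <- c(nb, ok_edges$protein_a[k])
    }
    expect_identical(sets[[i]], sort(setdiff(unique(nb), partners)))
  }
  # monotonicity: adding edges never shrinks a set
  extra <- rbind(ok_edges, edge_df(uni$gene5[1], "ZZZNEW"))
  bigger <- build_interactor_set(uni$gene5[1], uni$gene3[1], extra)
  expect_true(all(sets[[1]] %in% bigger))
})

test_that("root distances equal unit-weight BFS", {
  # 3-node chain: root -> P1 -> P2
  chain <- pathway_dag(
    data.frame(parent = c("R", "P1"), child = c("P1", "P2")),
    data.frame(gene_id = character(0), pathway_id = character(0)))
  d <- root_distances(chain)
  expect_equal(d[["R"]], 0)
  expect_equal(d[["P2"]], 2)
  # 50 random DAGs up to 200 nodes, every node, exact equivalence
  set.seed(33)
  for (rep_i in 1:50) {
    n <- sample(20:200, 1)
    ids <- sprintf("N%03d", seq_len(n))
    parent_of <- function(i) {
      pool <- seq(max(1, i - 10), i - 1)
      take <- min(sample(1:3, 1), length(pool))
      ids[pool[sample.int(length(pool), take)]]
    }
    edges <- do.call(rbind, lapply(3:n, function(i)
      data.frame(parent = parent_of(i), child = ids[i],
                 stringsAsFactors = FALSE)))
    dag <- pathway_dag(edges,
                       data.frame(gene_id = character(0),
                                  pathway_id = character(0)),
                       nodes = data.frame(pathway_id = ids, name = ids,
                                          stringsAsFactors = FALSE))
    got <- root_distances(dag)
    want <- oracle_bfs_root_distances(edges, ids, dag$roots)
    expect_equal(got[ids], want[ids])
  }
  # a cycle is rejected at construction
  expect_error(
    pathway_dag(data.frame(parent = c("A", "B"), child = c("B", "A")),
                data.frame(gene_id = character(0),
                           pathway_id = character(0))),
    "cycle")
})

test_that("pathway loads match planted annotation bookkeeping", {
  dag <- pathway_dag(
    data.frame(parent = "R", child = c("P1", "P2")),
    data.frame(gene_id = c("X", "X", "Y"),
               pathway_id = c("P1", "P2", "P2")))
  fus <- data.frame(fusion_key = c("f1", "f2", "f3"),
                    project = c("A", "A", "B"), stringsAsFactors = FALSE)
  # X interacts with all 3 fusions, Y with none
  sets <- list(f1 = "X", f2 = "X", f3 = c("X", "Q"))
  loads <- pathway_loads(sets, dag, fus)
  all_rows <- loads[is.na(loads$project), ]
  expect_identical(
    all_rows$summed_load[all_rows$pathway_id == "P1"], 3L)
  expect_identical(
    all_rows$n_interacting_fusions[all_rows$pathway_id == "P1"], 3L)
  # pathway with no annotated interactors: load 0, normalized 0
  expect_identical(all_rows$summed_load[all_rows$pathway_id == "R"], 0L)
  expect_equal(all_rows$normalized_frequency[all_rows$pathway_id == "R"], 0)
  # normalization attains 1 exactly at the argmax pathway(s) per project
  for (pr in c("A", "B")) {
    sub <- loads[!is.na(loads$project) & loads$project == pr, ]
    expect_true(all(sub$normalized_frequency[
      sub$n_interacting_fusions == max(sub$n_interacting_fusions)] == 1))
    expect_true(all(sub$normalized_frequency <= 1))
  }
})

test_that("census enrichment proportions are exact on planted membership", {
  sets <- list(f1 = c("A", "B"), f2 = c("B", "C"), f3 = "D")
  expect_equal(census_enrichment(sets, c("A", "B", "C", "D"))$overall, 1.0)
  expect_equal(census_enrichment(sets, "ZZ")$overall, 0.0)
  # planted membership at rate 0.2 over a 500-interactor universe
  set.seed(4)
  universe <- sprintf("P%04d", 1:500)
  census <- sample(universe, 100)
  sets2 <- lapply(1:80, function(i) sample(universe, sample(5:30, 1)))
  names(sets2) <- sprintf("f%02d", 1:80)
  enr <- census_enrichment(sets2, census, top_k = c(10L))
  expect_gte(enr$overall, 0.15)
  expect_lte(enr$overall, 0.25)
  expect_gte(enr$top_k[["top_10"]], 0.1)
  # empty universe -> absent
  expect_true(is.na(census_enrichment(list(f1 = character(0)), census)$overall))
})
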