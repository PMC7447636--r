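test_that("spec validation rejects inconsistent parameters", {
  expect_error(cohort_spec(n_genes = 1L), "n_genes")
  expect_error(cohort_spec(frac_inframe = 1.2), "frac_inframe")
  expect_error(cohort_spec(frac_pk = 0.6, frac_tf = 0.6), "frac_pk")
  expect_error(cohort_spec(nb_dispersion = 0), "nb_dispersion")
})

test_that("generated gene models satisfy the construction contract", {
  m <- shared_models()
  expect_equal(nrow(m$genes), 30L)
  expect_true(validate_gene_models(m) |> inherits("fs_gene_models"))
  for (i in seq_len(nrow(m$genes))) {
    g <- m$genes[i, ]
    cds <- substr(m$tx_seq[[g$gene_id]], g$cds_tx_start, g$cds_tx_end)
    expect_identical(nchar(cds) %% 3L, 0L)
    expect_identical(substr(cds, 1, 3), "ATG")
    # independent codon-table oracle: no internal stops, one terminal stop
    tr <- oracle_translate(cds)
    expect_true(tr$stopped)
    expect_equal(nchar(tr$aa), nchar(cds) / 3 - 1)
    expect_identical(tr$aa, g$protein)
    expect_gte(nrow(gene_exons(m, g$gene_id)), 2L)
  }
  # labeled fractions
  expect_equal(sum(m$genes$is_pk), round(0.1 * 30))
  expect_equal(sum(m$genes$is_tf), round(0.1 * 30))
})

test_that("generators are pure functions of (spec, seed)", {
  s <- shared_spec(seed = 99L)
  m1 <- generate_gene_models(s); m2 <- generate_gene_models(s)
  expect_identical(m1$genes, m2$genes)
  expect_identical(as.character(m1$genome), as.character(m2$genome))
  c1 <- generate_fusion_cohort(m1, s); c2 <- generate_fusion_cohort(m2, s)
  expect_identical(c1$calls, c2$calls)
  expect_identical(c1$truth, c2$truth)
  n1 <- generate_network_and_pathways(m1, s, c1$samples)
  n2 <- generate_network_and_pathways(m2, s, c2$samples)
  expect_identical(n1$interactions, n2$interactions)
  a <- data.frame(barcode = c1$samples$barcode, pair = NA_character_)
  k1 <- generate_counts(s, m1, a); k2 <- generate_counts(s, m2, a)
  expect_identical(k1$counts, k2$counts)
})

test_that("fusion cohort: boundary fractions, exon-boundary breakpoints and barcodes", {
  m <- shared_models()
  all_if <- generate_fusion_cohort(
    m, shared_spec(frac_inframe = 1, n_fusions = 50L, n_recurrent = 0L))
  expect_identical(unique(all_if$truth$effect), "in-frame")
  empty <- generate_fusion_cohort(m, shared_spec(n_fusions = 0L))
  expect_identical(nrow(empty$calls), 0L)
  co <- generate_fusion_cohort(m, shared_spec())
  expect_true(all(grepl("^TCGA-[A-Z]{2}-[A-Z0-9]{4}$", co$calls$sample_barcode)))
  for (i in seq_len(nrow(co$calls))) {
    j5 <- genomic_to_tx(m, co$calls$gene5[i], co$calls$contig5[i],
                        co$calls$pos5[i])
    j3 <- genomic_to_tx(m, co$calls$gene3[i], co$calls$contig3[i],
                        co$calls$pos3[i])
    ex5 <- gene_exons(m, co$calls$gene5[i])
    ex3 <- gene_exons(m, co$calls$gene3[i])
    expect_true(j5 %in% ex5$tx_end)
    expect_true(j3 %in% ex3$tx_start)
  }
  # ground truth covers every fusion exactly once
  expect_identical(nrow(co$truth), nrow(co$calls))
  expect_false(anyDuplicated(co$truth$fusion_id) > 0)
})

test_that("realized in-frame fraction stays within binomial sampling error", {
  spec <- cohort_spec(n_genes = 30L, n_samples = 30L, n_fusions = 2000L,
                      frac_inframe = 0.5, n_recurrent = 0L, seed = 5L)
  co <- generate_fusion_cohort(generate_gene_models(spec), spec)
  frac <- mean(co$truth$effect == "in-frame")
  expect_gte(frac, 0.46)
  expect_lte(frac, 0.54)
})

test_that("counts follow the stated NB model", {
  m <- shared_models()
  # no planted effect: per-gene group-mean ratios center at 1
  barcodes <- sprintf("TCGA-AA-%04d", 1:100)
  a <- data.frame(barcode = barcodes,
                  pair = rep(c("P", NA_character_), each = 50))
  spec <- shared_spec(n_samples = 100L)
  k <- generate_counts(spec, m, a,
                       planted_pairs = list(list(pair = "P",
                                                 genes = m$genes$gene_id[1:5],
                                                 log2fc = 0)))
  ratio <- rowMeans(k$counts[, 1:50]) / rowMeans(k$counts[, 51:100])
  expect_gte(median(ratio), 0.9)
  expect_lte(median(ratio), 1.1)
  # dispersion -> 0 approaches the Poisson limit var/mean -> 1
  spec0 <- cohort_spec(n_genes = 2L, n_samples = 10000L, seed = 3L,
                       nb_dispersion = 1e-8,
                       nb_mean_log_range = c(log(100), log(100)))
  m2 <- generate_gene_models(cohort_spec(n_genes = 2L, seed = 3L))
  a2 <- data.frame(barcode = sprintf("TCGA-AA-%04X", 1:10000),
                   pair = NA_character_)
  k2 <- generate_counts(spec0, m2, a2)
  vm <- var(as.numeric(k2$counts[1, ])) / mean(k2$counts[1, ])
  expect_gte(vm, 0.8)
  expect_lte(vm, 1.2)
  # planted pair with < 2 samples is an invalid spec
  expect_error(
    generate_counts(spec, m,
                    data.frame(barcode = barcodes,
                               pair = c("P", rep(NA_character_, 99))),
                    planted_pairs = list(list(pair = "P", genes = "SYNG00001",
                                              log2fc = 2))),
    "fewer than 2")
  # planted genes outside the universe are rejected
  expect_error(
    generate_counts(spec, m, a,
                    planted_pairs = list(list(pair = "P", genes = "NOPE",
                                              log2fc = 2))),
    "universe")
})

test_that("network, pathway DAG and clinical generators meet their contracts", {
  m <- shared_models()
  spec <- shared_spec(frac_nonphysical = 0.3)
  co <- generate_fusion_cohort(m, spec)
  net <- generate_network_and_pathways(m, spec, co$samples,
                                       n_extra_proteins = 600L)
  # acyclicity by Kahn's algorithm oracle
  nodes <- net$pathways$nodes$pathway_id
  expect_true(oracle_is_dag(net$pathways$edges, nodes))
  # at least one root; every node within dag_depth of a root
  roots <- setdiff(nodes, net$pathways$edges$child)
  expect_gte(length(roots), 1L)
  d <- oracle_bfs_root_distances(net$pathways$edges, nodes, roots)
  expect_true(all(!is.na(d) & d <= spec$dag_depth))
  # realized non-physical fraction within binomial sampling error
  vocab <- mitab_vocab()
  nonphys <- !(net$interactions$interaction_type %in% vocab$physical_types) |
    !(net$interactions$detection_method %in% vocab$experimental_methods)
  expect_gte(nrow(net$interactions), 1000L)
  expect_gte(mean(nonphys), 0.25)
  expect_lte(mean(nonphys), 0.35)
  # dirty clinical strings are present
  expect_true(any(net$clinical$stage_raw %in%
                    c("Stage 0", "Stage X", "I/II NOS")))
  expect_true(any(grepl("\\.", net$clinical$topography_raw)))
})
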