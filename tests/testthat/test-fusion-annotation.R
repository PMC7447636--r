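make_call <- function(models, gene5, gene3, j5, j3) {
  data.frame(
    sample_barcode = "TCGA-AA-0001", gene5 = gene5, gene3 = gene3,
    contig5 = gene_row(models, gene5)$contig,
    pos5 = tx_to_genomic(models, gene5, j5),
    contig3 = gene_row(models, gene3)$contig,
    pos3 = tx_to_genomic(models, gene3, j3),
    stringsAsFactors = FALSE)
}

test_that("fusion transcript assembly concatenates at exon boundaries", {
  # 5' portion 120 nt + 3' remainder -> junction offset 120, length additive
  a <- toy_coding_gene("GA", 60L, utr5 = 6L, splits = c(120L), seed = 2L)
  b <- toy_coding_gene("GB", 60L, utr5 = 6L, splits = c(60L), seed = 3L)
  m <- merge_models(a, b)
  asm <- assemble_fusion_transcript(make_call(m, "GA", "GB", 120L, 61L), m)
  expect_identical(asm$junction_offset, 120L)
  expect_identical(nchar(asm$sequence),
                   120L + (b$genes$tx_len - 61L + 1L))
  expect_identical(asm$sequence,
                   paste0(substr(m$tx_seq[["GA"]], 1, 120),
                          substr(m$tx_seq[["GB"]], 61, b$genes$tx_len)))
  # boundary case: 5' transcript end + 3' transcript start = full concatenation
  asm2 <- assemble_fusion_transcript(
    make_call(m, "GA", "GB", a$genes$tx_len, 61L), m)
  asm2b <- assemble_fusion_transcript(make_call(m, "GA", "GB", 120L, 1L), m)
  expect_identical(asm2b$sequence,
                   paste0(substr(m$tx_seq[["GA"]], 1, 120), m$tx_seq[["GB"]]))
  expect_identical(nchar(asm2$sequence),
                   a$genes$tx_len + b$genes$tx_len - 60L)
  # off-boundary breakpoint is unresolvable
  expect_error(
    assemble_fusion_transcript(make_call(m, "GA", "GB", 119L, 61L), m),
    "exon boundary")
})

test_that("minus-strand 3' portion equals the reverse complement of the genomic slice", {
  a <- toy_coding_gene("GA", 60L, splits = c(120L), seed = 2L)
  g3 <- toy_gene("-", "GM")
  m <- merge_models(a, g3)
  asm <- assemble_fusion_transcript(make_call(m, "GA", "GM", 120L, 22L), m)
  ex <- gene_exons(m, "GM")
  slice <- substr(as.character(m$genome[["ctg_GM"]]),
                  ex$start[2], ex$end[2])
  expect_identical(substr(asm$sequence, 121, nchar(asm$sequence)),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(slice))))
})

test_that("frame determination matches the worked amino-acid arithmetic", {
  # gene A: utr5 = 6, so junction at tx 306 leaves 300 coding nt (phase 0)
  a <- toy_coding_gene("GA", 150L, utr5 = 6L, splits = c(306L, 307L),
                       seed = 4L)
  # gene B: 150 codons + stop; exon starting 96+3 nt before the stop
  b_len <- 150L
  j3_off <- (3L * (b_len + 1L)) - 99L   # 96 coding nt + stop remain
  b <- toy_coding_gene("GB", b_len, utr5 = 6L, splits = c(6L + j3_off),
                       seed = 5L)
  m <- merge_models(a, b)
  j3 <- 6L + j3_off + 1L
  asm <- assemble_fusion_transcript(make_call(m, "GA", "GB", 306L, j3), m)
  fr <- determine_frame_and_translate(asm$sequence, asm$junction_offset, m,
                                      "GA", "GB", asm$j3)
  expect_identical(fr$effect, "in-frame")
  expect_identical(fr$aa5, 100L)
  expect_identical(fr$aa3, 32L)
  expect_identical(nchar(fr$sequence), fr$aa5 + fr$aa3)
  expect_false(grepl("*", fr$sequence, fixed = TRUE))
  expect_true(fr$protein_producing)
  # 301 nt of 5' coding sequence shifts the phase: out-of-frame by the
  # three-frame translation oracle
  asm2 <- assemble_fusion_transcript(make_call(m, "GA", "GB", 307L, j3), m)
  fr2 <- determine_frame_and_translate(asm2$sequence, asm2$junction_offset,
                                       m, "GA", "GB", asm2$j3)
  expect_identical(fr2$effect, "out-of-frame")
  expect_identical(oracle_frame_effect(m, "GA", "GB", 307L, j3),
                   "out-of-frame")
  expect_false(fr2$protein_producing)
  # a stop 60 nt after an in-frame junction: aa3 = 20, not protein-producing
  c_len <- 100L
  jc_off <- (3L * (c_len + 1L)) - 63L   # 60 coding nt + stop remain
  cc <- toy_coding_gene("GC", c_len, utr5 = 6L, splits = c(6L + jc_off),
                        seed = 6L)
  m2 <- merge_models(a, cc)
  jc <- 6L + jc_off + 1L
  asm3 <- assemble_fusion_transcript(make_call(m2, "GA", "GC", 306L, jc), m2)
  fr3 <- determine_frame_and_translate(asm3$sequence, asm3$junction_offset,
                                       m2, "GA", "GC", asm3$j3)
  expect_identical(fr3$effect, "in-frame")
  expect_identical(fr3$aa3, 20L)
  expect_false(fr3$protein_producing)
})

test_that("junction upstream of the 5' CDS start is a promoter swap", {
  a <- toy_coding_gene("GA", 60L, utr5 = 30L, splits = c(12L), seed = 7L)
  b <- toy_coding_gene("GB", 60L, utr5 = 6L, splits = c(60L), seed = 8L)
  m <- merge_models(a, b)
  asm <- assemble_fusion_transcript(make_call(m, "GA", "GB", 12L, 61L), m)
  fr <- determine_frame_and_translate(asm$sequence, asm$junction_offset, m,
                                      "GA", "GB", asm$j3)
  expect_identical(fr$effect, "promoter-swap")
  expect_false(fr$protein_producing)
})

test_that("protein-producing rule is strict at the 30-amino-acid boundary", {
  expect_true(classify_protein_producing("in-frame", 31L, 31L))
  expect_false(classify_protein_producing("in-frame", 30L, 31L))
  expect_false(classify_protein_producing("in-frame", 30L, 500L))
  expect_false(classify_protein_producing("out-of-frame", 200L, 45L))
  # monotonicity: extending the 3' contribution never revokes the call
  for (aa3 in 31:60)
    expect_true(classify_protein_producing("in-frame", 31L, aa3))
})

test_that("gene pairs are reported in alphabetical order", {
  expect_identical(canonical_pair("TMPRSS2", "ERG"), c("ERG", "TMPRSS2"))
  expect_identical(canonical_pair("ABL1", "BCR"), c("ABL1", "BCR"))
})

test_that("PK/TF categories follow list membership", {
  pk <- c("ABL1", "BRAF"); tf <- c("ERG", "RUNX1")
  expect_identical(classify_category("BCR", "ABL1", pk, tf), "PK")
  expect_identical(classify_category("ERG", "TMPRSS2", pk, tf), "TF")
  expect_identical(classify_category("ABL1", "ERG", pk, tf), "PK-TF")
  expect_identical(classify_category("X", "Y", pk, tf), "other")
})

test_that("annotation rejects same-gene calls and flags unresolved breakpoints", {
  m <- shared_models()
  spec <- shared_spec()
  co <- generate_fusion_cohort(m, spec)
  calls <- co$calls[1:3, ]
  calls$gene3[1] <- calls$gene5[1]
  calls$pos5[2] <- calls$pos5[2] + 1L   # off the exon boundary (or intronic)
  suppressMessages(ann <- annotate_fusions(calls, m))
  expect_identical(ann$status[1], "same-gene")
  expect_identical(ann$status[2], "unresolved")
  expect_identical(ann$status[3], "ok")
  expect_false(any(ann$protein_producing[ann$status != "ok"]))
})

test_that("frame classification agrees with the translation oracle on random fusions", {
  spec <- cohort_spec(n_genes = 40L, n_samples = 30L, n_fusions = 500L,
                      frac_inframe = 0.5, n_recurrent = 0L, seed = 11L)
  m <- generate_gene_models(spec)
  co <- generate_fusion_cohort(m, spec)
  ann <- annotate_fusions(co$calls, m)
  oracle <- vapply(seq_len(nrow(ann)), function(i) {
    j5 <- genomic_to_tx(m, ann$gene5[i], ann$contig5[i], ann$pos5[i])
    j3 <- genomic_to_tx(m, ann$gene3[i], ann$contig3[i], ann$pos3[i])
    oracle_frame_effect(m, ann$gene5[i], ann$gene3[i], j5, j3)
  }, character(1))
  expect_identical(mean(ann$effect == oracle), 1)
  # aa bookkeeping invariant on every product
  expect_true(all(ann$aa5 + ann$aa3 == nchar(ann$protein)))
})

test_that("deduplication is idempotent, order-independent and key-faithful", {
  spec <- cohort_spec(n_genes = 25L, n_samples = 20L, n_fusions = 250L,
                      seed = 13L)
  m <- generate_gene_models(spec)
  co <- generate_fusion_cohort(m, spec)
  # duplicate every call under a different sample: sample identity is not
  # part of the fusion key
  dup <- co$calls
  dup$sample_barcode <- rev(dup$sample_barcode)
  calls <- rbind(co$calls, dup)
  ann <- annotate_fusions(calls, m)
  u1 <- suppressMessages(deduplicate(ann, "full"))
  expect_lte(nrow(u1), nrow(co$calls))
  u2 <- suppressMessages(deduplicate(u1, "full"))
  expect_identical(u1, u2)
  set.seed(1)
  shuffled <- ann[sample(nrow(ann)), , drop = FALSE]
  u3 <- suppressMessages(deduplicate(shuffled, "full"))
  expect_setequal(u3$fusion_key, u1$fusion_key)
  # same pair at different breakpoints stays distinct
  k <- paste(ann$pair, ann$pos5, ann$pos3)
  expect_gte(nrow(u1), length(unique(ann$pair)))
  # pair+protein pass collapses at least as much as the full pass
  expect_lte(nrow(suppressMessages(deduplicate(u1, "pair_protein"))),
             nrow(u1))
})
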