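# Independent oracles and tiny fixtures used across the suite. These are
# deliberately naive re-derivations (hand-coded codon table, sliding-window
# scans, queue-based BFS) so they share no code path with the package.

# hand-coded standard codon table
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# direct three-letter sliding translation; stops at the first stop codon
oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3
  aa <- character(0)
  for (i in seq_len(n)) {
    codon <- substr(nt, 3 * i - 2, 3 * i)
    sym <- CODON_TABLE[[codon]]
    if (sym == "*") return(list(aa = paste(aa, collapse = ""), stopped = TRUE))
    aa <- c(aa, sym)
  }
  list(aa = paste(aa, collapse = ""), stopped = FALSE)
}

# Frame oracle: translate the fused transcript in the 5' partner's CDS frame
# and test whether the product is exactly the 5' wild-type prefix followed by
# the (possibly hybrid-codon-led) 3' wild-type peptide suffix, terminating at
# the 3' partner's own stop.
oracle_frame_effect <- function(models, gene5, gene3, j5, j3) {
  g5 <- models$genes[models$genes$gene_id == gene5, ]
  g3 <- models$genes[models$genes$gene_id == gene3, ]
  tx5 <- models$tx_seq[[gene5]]; tx3 <- models$tx_seq[[gene3]]
  fused <- paste0(substr(tx5, 1, j5), substr(tx3, j3, nchar(tx3)))
  if (j5 < g5$cds_tx_start) return("promoter-swap")
  tr <- oracle_translate(substr(fused, g5$cds_tx_start, nchar(fused)))
  pep <- tr$aa
  o3 <- j3 - g3$cds_tx_start
  if (o3 < 0) return("out-of-frame")
  nt5 <- j5 - g5$cds_tx_start + 1
  phase <- nt5 %% 3
  aa5 <- nt5 %/% 3
  p3 <- g3$protein
  first_wt <- if (phase == 0) o3 / 3 + 1 else floor(o3 / 3) + 2
  # a junction inside the last coding codon leaves an empty wild-type
  # suffix: the product then ends with the hybrid codon at the WT stop
  suffix <- if (first_wt > nchar(p3)) "" else
    substr(p3, first_wt, nchar(p3))
  if (phase == 0 && !nzchar(suffix)) return("out-of-frame")
  expected_len <- aa5 + (phase > 0) + nchar(suffix)
  prefix5 <- substr(g5$protein, 1, aa5)
  ok <- tr$stopped && nchar(pep) == expected_len &&
    startsWith(pep, prefix5) && endsWith(pep, suffix)
  if (ok) "in-frame" else "out-of-frame"
}

# naive full-length substring scan (character-by-character)
oracle_substring_present <- function(needle, haystack) {
  n <- nchar(needle); m <- nchar(haystack)
  if (n == 0 || n > m) return(FALSE)
  for (pos in 1:(m - n + 1)) {
    if (substr(haystack, pos, pos + n - 1) == needle) return(TRUE)
  }
  FALSE
}

# queue-based unit-weight BFS from a set of roots over parent->child edges
oracle_bfs_root_distances <- function(edges, nodes, roots) {
  dist <- setNames(rep(NA_real_, length(nodes)), nodes)
  dist[roots] <- 0
  queue <- roots
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    children <- edges$child[edges$parent == u]
    for (v in children) {
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  dist
}

# Kahn's algorithm: returns TRUE when the edge list is acyclic
oracle_is_dag <- function(edges, nodes) {
  indeg <- setNames(rep(0L, length(nodes)), nodes)
  for (v in edges$child) indeg[v] <- indeg[v] + 1L
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (v in edges$child[edges$parent == u]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) queue <- c(queue, v)
    }
  }
  seen == length(nodes)
}

unrowname <- function(d) { rownames(d) <- NULL; d }

# plus-strand toy gene with a fully controlled CDS and exon splits
# (`splits` = transcript positions of internal exon ends)
toy_coding_gene <- function(gene_id, n_codons, utr5 = 6L, utr3 = 6L,
                            splits = integer(0), seed = 1L) {
  set.seed(seed)
  nsc <- setdiff(names(CODON_TABLE), names(CODON_TABLE[CODON_TABLE == "*"]))
  body <- paste(sample(nsc[nsc != "ATG"], n_codons - 1L, replace = TRUE),
                collapse = "")
  cds <- paste0("ATG", body, "TAA")
  tx <- paste0(paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE),
                     collapse = ""),
               cds,
               paste(sample(c("A", "C", "G", "T"), utr3, replace = TRUE),
                     collapse = ""))
  tx_len <- nchar(tx)
  bounds <- c(0L, sort(as.integer(splits)), tx_len)
  n_ex <- length(bounds) - 1L
  tx_start <- head(bounds, -1L) + 1L
  tx_end <- bounds[-1L]
  # genomic layout: 5 nt pad, exons separated by 10 nt introns
  g_start <- integer(n_ex); g_end <- integer(n_ex)
  pieces <- "AAAAA"; off <- 5L
  for (k in seq_len(n_ex)) {
    g_start[k] <- off + 1L
    g_end[k] <- off + (tx_end[k] - tx_start[k] + 1L)
    off <- g_end[k]
    pieces <- c(pieces, substr(tx, tx_start[k], tx_end[k]))
    if (k < n_ex) { pieces <- c(pieces, "GGGGGGGGGG"); off <- off + 10L }
  }
  contig <- paste0("ctg_", gene_id)
  genes <- data.frame(
    gene_id = gene_id, symbol = gene_id, biotype = "protein_coding",
    contig = contig, strand = "+", transcript_id = paste0("T", gene_id),
    tx_len = tx_len, cds_tx_start = utr5 + 1L,
    cds_tx_end = utr5 + nchar(cds),
    protein = oracle_translate(cds)$aa, is_pk = FALSE, is_tf = FALSE,
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = gene_id, transcript_id = paste0("T", gene_id),
    exon_rank = seq_len(n_ex), contig = contig, strand = "+",
    start = g_start, end = g_end, tx_start = tx_start, tx_end = tx_end,
    stringsAsFactors = FALSE)
  gene_models(genes, exons,
              Biostrings::DNAStringSet(
                setNames(paste(c(pieces, "CCCCC"), collapse = ""), contig)),
              setNames(tx, gene_id))
}

merge_models <- function(a, b) {
  gene_models(rbind(a$genes, b$genes), rbind(a$exons, b$exons),
              c(a$genome, b$genome), c(a$tx_seq, b$tx_seq))
}

# small shared cohort built once per test run
shared_spec <- function(seed = 42L, n_genes = 30L, n_samples = 30L,
                        n_fusions = 80L, ...) {
  cohort_spec(n_genes = n_genes, n_samples = n_samples,
              n_fusions = n_fusions, seed = seed, ...)
}

shared_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_gene_models(shared_spec())
    cache
  }
})

# hand-built two-exon toy gene for coordinate edge cases:
# transcript = UTR5(6) + ATG + 10 codons + TAA + UTR3(6); exon1 = first 21 nt
toy_gene <- function(strand = "+", gene_id = "TOYG1") {
  cds <- paste0("ATG", paste(rep("GCT", 10), collapse = ""), "TAA")
  tx <- paste0("ACACAC", cds, "GTGTGT")
  e1 <- substr(tx, 1, 21); e2 <- substr(tx, 22, nchar(tx))
  intron <- "GGGGGGGGGGGGGGGGGGGG"
  layout <- paste0("AAAAA", e1, intron, e2, "CCCCC")
  L <- nchar(layout)
  if (strand == "+") {
    contig_seq <- layout
    s1 <- 6; e1g <- 5 + nchar(e1)
    s2 <- e1g + nchar(intron) + 1; e2g <- s2 + nchar(e2) - 1
  } else {
    contig_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(layout)))
    e1g <- L - 6 + 1; s1 <- L - (5 + nchar(e1)) + 1
    e2g <- s1 - nchar(intron) - 1; s2 <- e2g - nchar(e2) + 1
  }
  genes <- data.frame(
    gene_id = gene_id, symbol = gene_id, biotype = "protein_coding",
    contig = paste0("ctg_", gene_id), strand = strand,
    transcript_id = paste0("T", gene_id), tx_len = nchar(tx),
    cds_tx_start = 7L, cds_tx_end = 6L + nchar(cds),
    protein = paste0("M", strrep("A", 10)),
    is_pk = FALSE, is_tf = FALSE, stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = gene_id, transcript_id = paste0("T", gene_id),
    exon_rank = 1:2, contig = paste0("ctg_", gene_id), strand = strand,
    start = c(s1, s2), end = c(e1g, e2g),
    tx_start = c(1L, 22L), tx_end = c(21L, nchar(tx)),
    stringsAsFactors = FALSE)
  gene_models(genes, exons,
              Biostrings::DNAStringSet(setNames(contig_seq,
                                                paste0("ctg_", gene_id))),
              setNames(tx, gene_id))
}

# NB counts for DE tests: genes x samples, optional planted fold changes
nb_counts <- function(n_genes, samples, dispersion = 0.1, seed = 1L,
                      planted = NULL, mu_range = c(log(20), log(2000))) {
  set.seed(seed)
  gids <- sprintf("G%04d", seq_len(n_genes))
  mu <- matrix(exp(runif(n_genes, mu_range[1], mu_range[2])),
               nrow = n_genes, ncol = length(samples),
               dimnames = list(gids, samples))
  if (!is.null(planted))
    mu[planted$genes, planted$samples] <-
      mu[planted$genes, planted$samples] * 2^planted$log2fc
  matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
         nrow = n_genes, dimnames = dimnames(mu))
}
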