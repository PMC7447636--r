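#' Generate a synthetic genome with valid gene models
#'
#' Builds `n_genes` genes, each on its own contig, with one canonical
#' transcript per gene: a 5' UTR, a CDS that begins with ATG, contains no
#' internal stop codon and ends in exactly one stop codon (CDS length
#' divisible by 3), a 3' UTR, and 2-6 exons separated by short introns.
#' Strands are drawn at random; minus-strand genes are laid out so that the
#' transcript sequence is the reverse complement of the genomic slice. PK and
#' TF labels are assigned to `frac_pk` / `frac_tf` of the genes.
#'
#' @param spec an [cohort_spec()] object.
#' @return an `fs_gene_models` object (see [gene_models()]).
#' @export
generate_gene_models <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(derive_seed(spec$seed, 1L))
  n <- spec$n_genes
  nsc <- non_stop_codons()

  n_pk <- round(spec$frac_pk * n)
  n_tf <- round(spec$frac_tf * n)
  labels <- sample(c(rep("PK", n_pk), rep("TF", n_tf),
                     rep("other", n - n_pk - n_tf)))

  genes <- list(); exons <- list()
  genome <- character(n); tx_seq <- character(n)
  gene_ids <- sprintf("SYNG%05d", seq_len(n))
  contigs <- paste0("ctg_", gene_ids)

  for (i in seq_len(n)) {
    p_len <- sample(80:400, 1L)
    utr5 <- sample(15:60, 1L); utr3 <- sample(15:60, 1L)
    cds <- paste0("ATG",
                  paste(sample(nsc, p_len - 1L, replace = TRUE),
                        collapse = ""),
                  sample(STOP_CODONS, 1L))
    tx <- paste0(random_dna(utr5), cds, random_dna(utr3))
    tx_len <- nchar(tx)
    n_ex <- sample(2:6, 1L)
    # cut the transcript into n_ex pieces, each at least 8 nt
    repeat {
      cuts <- sort(sample(seq_len(tx_len - 1L), n_ex - 1L))
      lens <- diff(c(0L, cuts, tx_len))
      if (min(lens) >= 8L) break
    }
    ex_tx_start <- c(1L, cuts + 1L)
    ex_tx_end <- c(cuts, tx_len)
    introns <- vapply(seq_len(n_ex - 1L),
                      function(k) random_dna(sample(20:100, 1L)),
                      character(1))
    strand <- sample(c("+", "-"), 1L)
    pad5 <- random_dna(30L); pad3 <- random_dna(30L)

    # genomic layout in transcript orientation
    pieces <- character(0)
    layout_start <- integer(n_ex); layout_end <- integer(n_ex)
    off <- nchar(pad5)
    pieces <- pad5
    for (k in seq_len(n_ex)) {
      ex_seq <- substr(tx, ex_tx_start[k], ex_tx_end[k])
      layout_start[k] <- off + 1L
      layout_end[k] <- off + nchar(ex_seq)
      off <- layout_end[k]
      pieces <- c(pieces, ex_seq)
      if (k < n_ex) {
        pieces <- c(pieces, introns[k])
        off <- off + nchar(introns[k])
      }
    }
    pieces <- c(pieces, pad3)
    seq_plus <- paste(pieces, collapse = "")
    L <- nchar(seq_plus)
    if (strand == "+") {
      genome[i] <- seq_plus
      g_start <- layout_start; g_end <- layout_end
    } else {
      genome[i] <- reverse_complement(seq_plus)
      g_start <- L - layout_end + 1L
      g_end <- L - layout_start + 1L
    }

    genes[[i]] <- data.frame(
      gene_id = gene_ids[i], symbol = sprintf("SGN%d", i),
      biotype = "protein_coding", contig = contigs[i], strand = strand,
      transcript_id = sprintf("SYNT%05d", i), tx_len = tx_len,
      cds_tx_start = utr5 + 1L, cds_tx_end = utr5 + nchar(cds),
      protein = translate_to_stop(cds)$aa,
      is_pk = labels[i] == "PK", is_tf = labels[i] == "TF",
      stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(
      gene_id = gene_ids[i], transcript_id = sprintf("SYNT%05d", i),
      exon_rank = seq_len(n_ex), contig = contigs[i], strand = strand,
      start = g_start, end = g_end,
      tx_start = ex_tx_start, tx_end = ex_tx_end,
      stringsAsFactors = FALSE)
    tx_seq[i] <- tx
  }

  gene_models(do.call(rbind, genes), do.call(rbind, exons),
              Biostrings::DNAStringSet(setNames(genome, contigs)),
              setNames(tx_seq, gene_ids))
}

#' Generate domain instances with controlled PK/TF specificity
#'
#' Places Pfam-style domain instances on the wild-type proteins. A small pool
#' of accessions is planted exclusively on PK genes, another exclusively on TF
#' genes (so these accessions are unanimously PK-/TF-borne), and a third pool
#' is spread across all genes (so it is expected to classify as neither).
#' Each instance records its amino-acid interval and the substring it spans.
#'
#' @param models an `fs_gene_models` object.
#' @param spec an [cohort_spec()] object.
#' @param min_len,max_len bounds on domain length in amino acids
#'   (`min_len >= 5`).
#' @return list with `domains` (data.frame: `accession`, `name`, `protein`,
#'   `start`, `end`, `sequence`) and `truth` (data.frame: `accession`,
#'   `planted_class` in PK-specific/TF-specific/neither).
#' @export
generate_domains <- function(models, spec, min_len = 8L, max_len = 40L) {
  stopifnot(min_len >= 5L, max_len >= min_len)
  set.seed(derive_seed(spec$seed, 2L))
  g <- models$genes
  pk_accs <- sprintf("PFPK%03d", 1:3)
  tf_accs <- sprintf("PFTF%03d", 1:4)
  common_accs <- sprintf("PFCM%03d", 1:6)
  acc_name <- function(a) paste0("dom_", tolower(a))

  rows <- list()
  add_instance <- function(acc, i) {
    p_len <- nchar(g$protein[i])
    len <- sample(min_len:min(max_len, p_len), 1L)
    start <- sample(seq_len(p_len - len + 1L), 1L)
    rows[[length(rows) + 1L]] <<- data.frame(
      accession = acc, name = acc_name(acc), protein = g$gene_id[i],
      start = start, end = start + len - 1L,
      sequence = substr(g$protein[i], start, start + len - 1L),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(g))) {
    if (g$is_pk[i]) add_instance(sample(pk_accs, 1L), i)
    if (g$is_tf[i]) add_instance(sample(tf_accs, 1L), i)
    for (j in seq_len(sample(0:2, 1L))) add_instance(sample(common_accs, 1L), i)
  }
  domains <- do.call(rbind, rows)
  truth <- data.frame(
    accession = c(pk_accs, tf_accs, common_accs),
    planted_class = c(rep("PK-specific", length(pk_accs)),
                      rep("TF-specific", length(tf_accs)),
                      rep("neither", length(common_accs))),
    stringsAsFactors = FALSE)
  list(domains = domains, truth = truth)
}
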