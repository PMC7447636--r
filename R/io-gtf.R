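#' Write gene models as GTF and genome FASTA
#'
#' Emits gene/transcript/exon/CDS features with `gene_id`, `transcript_id`,
#' `gene_name`, `gene_biotype` and `exon_number` attributes. In this dialect
#' the CDS features include the stop codon, so CDS length stays divisible by
#' 3 and no separate stop_codon feature is written.
#'
#' @param models an `fs_gene_models` object.
#' @param gtf_path,fasta_path output paths.
#' @return invisibly, the paths.
#' @export
write_gene_models <- function(models, gtf_path, fasta_path) {
  g <- models$genes; ex <- models$exons
  feats <- list()
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    exi <- ex[ex$gene_id == gid, , drop = FALSE]
    cds <- cds_genomic_intervals(models, gid)
    widths <- cds$end - cds$start + 1L
    cds$phase <- as.integer((3L - cumsum(c(0L, head(widths, -1L))) %% 3L) %%
                              3L)
    span <- range(c(exi$start, exi$end))
    base <- data.frame(
      seqnames = g$contig[i], strand = g$strand[i],
      gene_id = gid, transcript_id = g$transcript_id[i],
      gene_name = g$symbol[i], gene_biotype = g$biotype[i],
      stringsAsFactors = FALSE)
    feats[[length(feats) + 1L]] <- cbind(
      base, type = c("gene", "transcript"),
      start = span[1L], end = span[2L], exon_number = NA_integer_,
      phase = NA_integer_)
    feats[[length(feats) + 1L]] <- cbind(
      base, type = "exon", start = exi$start, end = exi$end,
      exon_number = exi$exon_rank, phase = NA_integer_)
    feats[[length(feats) + 1L]] <- cbind(
      base, type = "CDS", start = cds$start, end = cds$end,
      exon_number = cds$exon_rank, phase = cds$phase)
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, type = df$type, phase = df$phase,
    gene_id = df$gene_id,
    transcript_id = df$transcript_id, gene_name = df$gene_name,
    gene_biotype = df$gene_biotype, exon_number = df$exon_number)
  rtracklayer::export(gr, gtf_path, format = "gtf")
  Biostrings::writeXStringSet(models$genome, fasta_path)
  invisible(c(gtf_path, fasta_path))
}

# Structural pre-scan of a GTF file: 9 tab-separated fields and a
# 'key "value";'-style attribute column; reports offending line numbers.
scan_gtf_lines <- function(path) {
  lines <- readLines(path)
  data_idx <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in data_idx) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L)
      stop("GTF parse error at line ", i, ": expected 9 tab-separated ",
           "fields, found ", length(fields))
    if (!grepl("\\w+ \"[^\"]*\"", fields[9L]))
      stop("GTF parse error at line ", i,
           ": malformed attribute column: ", fields[9L])
  }
  invisible(length(data_idx))
}

#' Read gene models from GTF + genome FASTA
#'
#' Parses the GTF via rtracklayer after a structural pre-scan that reports
#' malformed lines by line number, reconstructs per-gene transcript
#' coordinates (exons ordered 5'->3' in transcript orientation), extracts
#' transcript sequences from the genome, translates the CDS, and validates
#' all gene-model invariants (CDS length divisible by 3, CDS within the exon
#' union, sequence consistency).
#'
#' @param gtf_path,fasta_path input paths.
#' @return an `fs_gene_models` object. PK/TF labels are set from gene lists
#'   downstream, not from the GTF.
#' @export
read_gene_models <- function(gtf_path, fasta_path) {
  scan_gtf_lines(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  md <- as.data.frame(gr)
  md$seqnames <- as.character(md$seqnames)
  md$strand <- as.character(md$strand)

  genes <- list(); exons <- list(); tx_seq <- character(0)
  for (gid in unique(md$gene_id)) {
    sub <- md[md$gene_id == gid, , drop = FALSE]
    exi <- sub[sub$type == "exon", , drop = FALSE]
    cdsi <- sub[sub$type == "CDS", , drop = FALSE]
    if (!nrow(exi)) stop("GTF validation error: gene ", gid, " has no exons")
    strand <- exi$strand[1L]; contig <- exi$seqnames[1L]
    exi <- exi[order(exi$start, decreasing = (strand == "-")), , drop = FALSE]
    widths <- exi$end - exi$start + 1L
    tx_end <- cumsum(widths)
    tx_start <- tx_end - widths + 1L
    if (!(contig %in% names(genome)))
      stop("GTF validation error: contig ", contig, " absent from FASTA")
    contig_seq <- as.character(genome[[contig]])
    pieces <- vapply(seq_len(nrow(exi)), function(k) {
      s <- substr(contig_seq, exi$start[k], exi$end[k])
      if (strand == "-") reverse_complement(s) else s
    }, character(1))
    tx <- paste(pieces, collapse = "")

    cds_len <- sum(cdsi$end - cdsi$start + 1L)
    if (cds_len == 0L)
      stop("GTF validation error: gene ", gid, " has no CDS")
    if (cds_len %% 3L != 0L)
      stop("GTF validation error: CDS length of ", gid, " (", cds_len,
           ") is not divisible by 3")
    # CDS must fall inside the exon union; map its genomic extremes to
    # transcript coordinates through the exon table
    tx_of <- function(pos) {
      hit <- which(exi$start <= pos & pos <= exi$end)
      if (length(hit) != 1L)
        stop("GTF validation error: CDS of ", gid, " outside exons")
      if (strand == "+") tx_start[hit] + (pos - exi$start[hit])
      else tx_start[hit] + (exi$end[hit] - pos)
    }
    cds_tx <- sort(vapply(c(cdsi$start, cdsi$end), tx_of, numeric(1)))
    cds_tx_start <- as.integer(min(cds_tx))
    cds_tx_end <- as.integer(max(cds_tx))
    if (cds_tx_end - cds_tx_start + 1L != cds_len)
      stop("GTF validation error: CDS of ", gid,
           " is not contiguous in transcript coordinates")

    tr <- translate_to_stop(substr(tx, cds_tx_start, cds_tx_end))
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = gid, symbol = sub$gene_name[1L] %||% gid,
      biotype = sub$gene_biotype[1L] %||% "protein_coding",
      contig = contig, strand = strand,
      transcript_id = exi$transcript_id[1L],
      tx_len = nchar(tx), cds_tx_start = cds_tx_start,
      cds_tx_end = cds_tx_end, protein = tr$aa,
      is_pk = FALSE, is_tf = FALSE, stringsAsFactors = FALSE)
    exons[[length(exons) + 1L]] <- data.frame(
      gene_id = gid, transcript_id = exi$transcript_id,
      exon_rank = seq_len(nrow(exi)), contig = contig, strand = strand,
      start = exi$start, end = exi$end, tx_start = tx_start, tx_end = tx_end,
      stringsAsFactors = FALSE)
    tx_seq[gid] <- tx
  }
  gene_models(do.call(rbind, genes), do.call(rbind, exons), genome, tx_seq)
}

#' Apply PK/TF labels from gene lists to a model set
#'
#' @param models an `fs_gene_models` object.
#' @param pk_genes,tf_genes character vectors of gene ids.
#' @return the relabeled model set.
#' @export
label_gene_classes <- function(models, pk_genes, tf_genes) {
  models$genes$is_pk <- models$genes$gene_id %in% pk_genes
  models$genes$is_tf <- models$genes$gene_id %in% tf_genes
  models
}
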