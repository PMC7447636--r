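#' Gene model container
#'
#' A gene-model set holds one canonical transcript per gene: exon structure in
#' both genomic and transcript coordinates, CDS location in transcript
#' coordinates, the genome and transcript sequences, and PK/TF labels.
#' Coordinates are 1-based inclusive throughout (GTF convention). The CDS
#' includes the stop codon, so its length is divisible by 3 and translation of
#' the full CDS ends in exactly one stop.
#'
#' @param genes data.frame with columns `gene_id`, `symbol`, `biotype`,
#'   `contig`, `strand`, `transcript_id`, `tx_len`, `cds_tx_start`,
#'   `cds_tx_end`, `protein`, `is_pk`, `is_tf`.
#' @param exons data.frame with columns `gene_id`, `transcript_id`,
#'   `exon_rank`, `contig`, `strand`, `start`, `end`, `tx_start`, `tx_end`
#'   (ranks in transcript 5'->3' orientation).
#' @param genome named [Biostrings::DNAStringSet] of contig sequences.
#' @param tx_seq named character vector of transcript sequences (keyed by
#'   gene id).
#' @return object of class `fs_gene_models`.
#' @export
gene_models <- function(genes, exons, genome, tx_seq) {
  m <- structure(list(genes = genes, exons = exons, genome = genome,
                      tx_seq = tx_seq),
                 class = "fs_gene_models")
  validate_gene_models(m)
  m
}

#' Validate a gene-model set
#'
#' Checks the structural invariants: exons sorted and non-overlapping in
#' transcript orientation, transcript-coordinate intervals contiguous, CDS
#' within the transcript, CDS length divisible by 3, and sequence consistency
#' between genome slices and the stored transcript sequence.
#'
#' @param m an `fs_gene_models` object.
#' @return the object, invisibly; stops with a validation error otherwise.
#' @export
validate_gene_models <- function(m) {
  g <- m$genes
  stopifnot(is.data.frame(g), is.data.frame(m$exons))
  if (anyDuplicated(g$gene_id))
    stop("gene-model validation: duplicated gene ids")
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    ex <- m$exons[m$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$exon_rank), , drop = FALSE]
    if (nrow(ex) < 1L)
      stop("gene-model validation: gene ", gid, " has no exons")
    if (any(ex$tx_start > ex$tx_end) || any(ex$start > ex$end))
      stop("gene-model validation: inverted exon interval in ", gid)
    if (any(ex$tx_start[-1L] != ex$tx_end[-nrow(ex)] + 1L))
      stop("gene-model validation: non-contiguous transcript coords in ", gid)
    cds_len <- g$cds_tx_end[i] - g$cds_tx_start[i] + 1L
    if (cds_len %% 3L != 0L)
      stop("gene-model validation: CDS length of ", gid,
           " (", cds_len, ") is not divisible by 3")
    if (g$cds_tx_start[i] < 1L || g$cds_tx_end[i] > g$tx_len[i])
      stop("gene-model validation: CDS outside transcript in ", gid)
    if (ex$tx_end[nrow(ex)] != g$tx_len[i])
      stop("gene-model validation: exon span != tx_len in ", gid)
    # genomic slices, stitched in transcript orientation, must reproduce the
    # stored transcript sequence
    contig <- as.character(m$genome[[g$contig[i]]])
    pieces <- vapply(seq_len(nrow(ex)), function(k) {
      s <- substr(contig, ex$start[k], ex$end[k])
      if (g$strand[i] == "-") reverse_complement(s) else s
    }, character(1))
    if (paste(pieces, collapse = "") != m$tx_seq[[gid]])
      stop("gene-model validation: sequence mismatch for ", gid)
  }
  invisible(m)
}

gene_row <- function(models, gene_id) {
  i <- match(gene_id, models$genes$gene_id)
  if (is.na(i)) stop("unknown gene id: ", gene_id)
  models$genes[i, , drop = FALSE]
}

gene_exons <- function(models, gene_id) {
  ex <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  ex[order(ex$exon_rank), , drop = FALSE]
}

#' Map a genomic position to transcript coordinates
#'
#' @param models an `fs_gene_models` object.
#' @param gene_id gene whose transcript defines the coordinate system.
#' @param contig,pos genomic location (1-based).
#' @return 1-based transcript coordinate, or `NA` if the position is not
#'   exonic for that gene (intronic or off-contig).
#' @export
genomic_to_tx <- function(models, gene_id, contig, pos) {
  g <- gene_row(models, gene_id)
  if (contig != g$contig) return(NA_integer_)
  ex <- gene_exons(models, gene_id)
  hit <- which(ex$start <= pos & pos <= ex$end)
  if (length(hit) != 1L) return(NA_integer_)
  if (g$strand == "+") {
    ex$tx_start[hit] + (pos - ex$start[hit])
  } else {
    ex$tx_start[hit] + (ex$end[hit] - pos)
  }
}

#' Map a transcript coordinate to its genomic position
#'
#' Inverse of [genomic_to_tx()].
#'
#' @inheritParams genomic_to_tx
#' @param tx_pos 1-based transcript coordinate.
#' @return genomic position (1-based) on the gene's contig.
#' @export
tx_to_genomic <- function(models, gene_id, tx_pos) {
  g <- gene_row(models, gene_id)
  ex <- gene_exons(models, gene_id)
  hit <- which(ex$tx_start <= tx_pos & tx_pos <= ex$tx_end)
  if (length(hit) != 1L) stop("transcript coordinate out of range")
  if (g$strand == "+") {
    ex$start[hit] + (tx_pos - ex$tx_start[hit])
  } else {
    ex$end[hit] - (tx_pos - ex$tx_start[hit])
  }
}

# Is tx_pos the last base of an exon (5' junction side) / the first base of an
# exon (3' junction side) in transcript orientation?
is_exon_end_tx <- function(models, gene_id, tx_pos) {
  ex <- gene_exons(models, gene_id)
  tx_pos %in% ex$tx_end
}

is_exon_start_tx <- function(models, gene_id, tx_pos) {
  ex <- gene_exons(models, gene_id)
  tx_pos %in% ex$tx_start
}

# Genomic CDS intervals of a gene (intersection of the CDS transcript range
# with each exon), in transcript orientation order. Used by the GTF writer.
cds_genomic_intervals <- function(models, gene_id) {
  g <- gene_row(models, gene_id)
  ex <- gene_exons(models, gene_id)
  out <- list()
  for (k in seq_len(nrow(ex))) {
    a <- max(ex$tx_start[k], g$cds_tx_start)
    b <- min(ex$tx_end[k], g$cds_tx_end)
    if (a > b) next
    if (g$strand == "+") {
      gs <- ex$start[k] + (a - ex$tx_start[k])
      ge <- ex$start[k] + (b - ex$tx_start[k])
    } else {
      ge <- ex$end[k] - (a - ex$tx_start[k])
      gs <- ex$end[k] - (b - ex$tx_start[k])
    }
    out[[length(out) + 1L]] <- data.frame(
      gene_id = gene_id, exon_rank = ex$exon_rank[k], start = gs, end = ge,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Wild-type protein sequences of a model set
#'
#' @param models an `fs_gene_models` object.
#' @return named character vector, gene id -> amino-acid sequence (stop
#'   excluded).
#' @export
wt_proteins <- function(models) {
  setNames(models$genes$protein, models$genes$gene_id)
}
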