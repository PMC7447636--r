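#' Assemble a fusion transcript from a breakpoint call
#'
#' The fused transcript is the 5' partner's transcript sequence up to and
#' including the breakpoint exon boundary, concatenated with the 3' partner's
#' transcript from its breakpoint exon boundary to the transcript end. Both
#' breakpoints must coincide with annotated exon boundaries in transcript
#' orientation (last base of an exon for the 5' partner, first base of an
#' exon for the 3' partner); otherwise the call is unresolvable.
#'
#' @param call one-row data.frame (or list) with `gene5`, `gene3`, `contig5`,
#'   `pos5`, `contig3`, `pos3`.
#' @param models an `fs_gene_models` object.
#' @return list with `sequence` (fused nucleotide sequence),
#'   `junction_offset` (last 5'-derived base, in fused-transcript
#'   coordinates), and the breakpoint transcript coordinates `j5`, `j3`.
#' @export
assemble_fusion_transcript <- function(call, models) {
  j5 <- genomic_to_tx(models, call$gene5, call$contig5, call$pos5)
  j3 <- genomic_to_tx(models, call$gene3, call$contig3, call$pos3)
  if (is.na(j5) || !is_exon_end_tx(models, call$gene5, j5))
    stop("unresolvable call: 5' breakpoint is not an exon boundary of ",
         call$gene5)
  if (is.na(j3) || !is_exon_start_tx(models, call$gene3, j3))
    stop("unresolvable call: 3' breakpoint is not an exon boundary of ",
         call$gene3)
  tx5 <- models$tx_seq[[call$gene5]]
  tx3 <- models$tx_seq[[call$gene3]]
  list(sequence = paste0(substr(tx5, 1L, j5),
                         substr(tx3, j3, nchar(tx3))),
       junction_offset = j5, j5 = j5, j3 = j3)
}

#' Determine the frame effect of a fusion and translate its product
#'
#' Translation starts at the 5' partner's annotated start codon and proceeds
#' to the first stop codon. The fusion is in-frame when the 3' partner's
#' codon phase at the junction matches its annotated CDS phase (and the
#' junction-spanning codon, attributed to the 3' side, is not itself a stop).
#' `aa5` counts the codons completed strictly 5' of the junction; the
#' junction-spanning codon and everything after count toward `aa3`. A
#' junction upstream of the 5' CDS start is a promoter swap (full or
#' truncated 3' gene under the 5' gene's promoter): no protein is called.
#'
#' @param fused fused nucleotide sequence from
#'   [assemble_fusion_transcript()].
#' @param junction_offset last 5'-derived base in fused coordinates.
#' @param models an `fs_gene_models` object.
#' @param gene5,gene3 partner gene ids.
#' @param j3 3' breakpoint in the 3' partner's transcript coordinates.
#' @return list with `effect` ("in-frame", "out-of-frame" or
#'   "promoter-swap"), `sequence` (amino acids, no stop symbol), `aa5`,
#'   `aa3`, `protein_producing`.
#' @export
determine_frame_and_translate <- function(fused, junction_offset, models,
                                          gene5, gene3, j3) {
  g5 <- gene_row(models, gene5)
  g3 <- gene_row(models, gene3)
  if (junction_offset < g5$cds_tx_start) {
    return(list(effect = "promoter-swap", sequence = "", aa5 = 0L, aa3 = 0L,
                protein_producing = FALSE))
  }
  nt5 <- junction_offset - g5$cds_tx_start + 1L
  phase <- nt5 %% 3L
  o3 <- j3 - g3$cds_tx_start
  inframe <- o3 >= 0L && o3 <= (g3$cds_tx_end - g3$cds_tx_start + 1L) - 3L &&
    (o3 %% 3L) == phase
  if (inframe && phase > 0L) {
    hybrid <- substr(fused, junction_offset - phase + 1L,
                     junction_offset - phase + 3L)
    if (hybrid %in% STOP_CODONS) inframe <- FALSE
  }
  tr <- translate_to_stop(substr(fused, g5$cds_tx_start, nchar(fused)))
  aa5 <- min(nt5 %/% 3L, nchar(tr$aa))
  aa3 <- nchar(tr$aa) - aa5
  effect <- if (inframe) "in-frame" else "out-of-frame"
  list(effect = effect, sequence = tr$aa, aa5 = as.integer(aa5),
       aa3 = as.integer(aa3),
       protein_producing = classify_protein_producing(effect, aa5, aa3))
}

#' Protein-producing rule
#'
#' A fusion is protein-producing when it is in-frame and both partners
#' contribute more than 30 amino acids to the product (30 being the length
#' of the shortest non-repeat domain, so shorter contributions cannot carry
#' an intact domain).
#'
#' @param effect frame effect string.
#' @param aa5,aa3 per-partner amino-acid contributions.
#' @return logical flag.
#' @export
classify_protein_producing <- function(effect, aa5, aa3) {
  identical(effect, "in-frame") && aa5 > 30L && aa3 > 30L
}

#' Canonical (alphabetical) gene-pair label
#'
#' Gene pairs are reported in lexicographic order regardless of 5'/3'
#' orientation (the orientation stays on the fusion record itself).
#'
#' @param gene_a,gene_b gene symbols or ids.
#' @return length-2 character vector, sorted.
#' @export
canonical_pair <- function(gene_a, gene_b) {
  sort(c(gene_a, gene_b))
}

#' PK/TF category of a fusion pair
#'
#' PK-TF when one partner is a protein kinase and the other a transcription
#' factor; otherwise PK (or TF) when at least one partner is on the
#' respective list; otherwise "other". A gene present on both lists counts
#' for both memberships; if only one partner carries both labels the pair is
#' reported as PK.
#'
#' @param gene5,gene3 partner gene ids.
#' @param pk_genes,tf_genes character vectors.
#' @return one of "PK", "TF", "PK-TF", "other".
#' @export
classify_category <- function(gene5, gene3, pk_genes, tf_genes) {
  p5 <- gene5 %in% pk_genes; p3 <- gene3 %in% pk_genes
  t5 <- gene5 %in% tf_genes; t3 <- gene3 %in% tf_genes
  if ((p5 && t3) || (t5 && p3)) return("PK-TF")
  if (p5 || p3) return("PK")
  if (t5 || t3) return("TF")
  "other"
}

#' Annotate a table of fusion calls
#'
#' Runs assembly, frame determination, translation and categorization for
#' every call. Same-gene calls are rejected; calls whose breakpoints do not
#' resolve to exon boundaries are retained with status "unresolved" and
#' excluded from the protein set.
#'
#' @param calls fusion-call data.frame (see [read_fusion_calls()]).
#' @param models an `fs_gene_models` object.
#' @param pk_genes,tf_genes PK / TF gene lists.
#' @return data.frame with one row per call: call fields plus `status`,
#'   `effect`, `aa5`, `aa3`, `protein_producing`, `category`, `pair`,
#'   `protein`, `biotype5`, `biotype3`, and the duplicate key `fusion_key`.
#' @export
annotate_fusions <- function(calls, models, pk_genes = character(0),
                             tf_genes = character(0)) {
  rows <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, , drop = FALSE]
    base <- data.frame(
      call, status = "ok", effect = NA_character_, aa5 = NA_integer_,
      aa3 = NA_integer_, protein_producing = FALSE,
      category = classify_category(call$gene5, call$gene3, pk_genes,
                                   tf_genes),
      pair = paste(canonical_pair(call$gene5, call$gene3), collapse = "-"),
      protein = NA_character_, biotype5 = NA_character_,
      biotype3 = NA_character_, stringsAsFactors = FALSE)
    if (call$gene5 == call$gene3) {
      base$status <- "same-gene"
      rows[[i]] <- base
      next
    }
    base$biotype5 <- gene_row(models, call$gene5)$biotype
    base$biotype3 <- gene_row(models, call$gene3)$biotype
    asm <- tryCatch(assemble_fusion_transcript(call, models),
                    error = function(e) e)
    if (inherits(asm, "error")) {
      base$status <- "unresolved"
      rows[[i]] <- base
      next
    }
    fr <- determine_frame_and_translate(asm$sequence, asm$junction_offset,
                                        models, call$gene5, call$gene3,
                                        asm$j3)
    base$effect <- fr$effect
    base$aa5 <- fr$aa5; base$aa3 <- fr$aa3
    base$protein_producing <- fr$protein_producing
    base$protein <- fr$sequence
    if (fr$effect == "promoter-swap") base$status <- "promoter-swap"
    rows[[i]] <- base
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$fusion_key <- fusion_key(out)
  n_bad <- sum(out$status != "ok")
  if (n_bad)
    message("annotate_fusions: ", n_bad,
            " call(s) not annotated to a product (same-gene, unresolved ",
            "or promoter-swap)")
  out
}

# Duplicate key: gene ids (5'/3' order), biotypes, breakpoints, effect and
# resulting protein sequence.
fusion_key <- function(ann) {
  paste(ann$gene5, ann$gene3, ann$biotype5, ann$biotype3,
        ann$contig5, ann$pos5, ann$contig3, ann$pos3,
        ann$effect, ann$protein, sep = "|")
}

#' Deduplicate annotated fusions
#'
#' `level = "full"` keeps one representative per fusion key (gene ids,
#' biotypes, breakpoints, frame effect, protein sequence) — the cohort-level
#' uniqueness rule. `level = "pair_protein"` deduplicates on (gene pair,
#' protein sequence) only, as used for domain-level analyses. Both passes
#' are idempotent and input-order-independent as sets.
#'
#' @param ann annotated fusion data.frame from [annotate_fusions()].
#' @param level deduplication key, see above.
#' @return the unique subset (first representative kept).
#' @export
deduplicate <- function(ann, level = c("full", "pair_protein")) {
  level <- match.arg(level)
  key <- if (level == "full") fusion_key(ann)
         else paste(ann$pair, ann$protein, sep = "|")
  dropped <- sum(duplicated(key))
  if (dropped)
    message("deduplicate(", level, "): dropped ", dropped,
            " duplicate fusion(s)")
  ann[!duplicated(key), , drop = FALSE]
}
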