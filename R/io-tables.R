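write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, required = character(0)) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("parse error in ", path, ": missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Read / write fusion breakpoint calls
#'
#' Plain TSV with one detected breakpoint pair per row: `sample_barcode`,
#' `gene5`, `gene3`, `contig5`, `pos5`, `contig3`, `pos3` (positions 1-based).
#'
#' @param path file path.
#' @return data.frame of calls.
#' @export
read_fusion_calls <- function(path) {
  df <- read_tsv(path, c("sample_barcode", "gene5", "gene3", "contig5",
                         "pos5", "contig3", "pos3"))
  if (nrow(df) && any(df$pos5 < 1L | df$pos3 < 1L))
    stop("validation error in ", path, ": positions must be >= 1")
  df
}

#' @rdname read_fusion_calls
#' @param calls data.frame of calls.
#' @export
write_fusion_calls <- function(calls, path) write_tsv(calls, path)

#' Read / write a Pfam-style domain instance table
#'
#' Columns: `accession`, `name`, `protein`, `start`, `end`, `sequence`
#' (1-based inclusive amino-acid coordinates on the wild-type protein).
#' When `models` is supplied, every instance is checked against the
#' wild-type protein: `sequence` must equal the spanned substring and the
#' instance must be at least 5 residues long.
#'
#' @param path file path.
#' @param models optional `fs_gene_models` object for validation.
#' @return data.frame of domain instances.
#' @export
read_domain_table <- function(path, models = NULL) {
  df <- read_tsv(path, c("accession", "name", "protein", "start", "end",
                         "sequence"))
  if (nrow(df)) {
    if (any(df$start < 1L | df$start > df$end))
      stop("validation error in ", path, ": bad domain coordinates")
    if (any(df$end - df$start + 1L < 5L))
      stop("validation error in ", path, ": domain shorter than 5 aa")
    if (!is.null(models)) {
      prot <- wt_proteins(models)
      for (i in seq_len(nrow(df))) {
        p <- prot[[df$protein[i]]]
        if (is.null(p) || df$end[i] > nchar(p) ||
            substr(p, df$start[i], df$end[i]) != df$sequence[i])
          stop("validation error in ", path, ": domain row ", i,
               " does not match the wild-type protein")
      }
    }
  }
  df
}

#' @rdname read_domain_table
#' @param domains data.frame of domain instances.
#' @export
write_domain_table <- function(domains, path) write_tsv(domains, path)

#' Read / write a one-column gene list
#'
#' @param path file path (TSV with a `gene_id` header).
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) read_tsv(path, "gene_id")$gene_id

#' @rdname read_gene_list
#' @param genes character vector.
#' @export
write_gene_list <- function(genes, path)
  write_tsv(data.frame(gene_id = genes, stringsAsFactors = FALSE), path)

#' Read / write the clinical table
#'
#' Columns: `barcode` (TCGA-style), `project`, `stage_raw`,
#' `topography_raw`. Harmonization ([simplify_stage()],
#' [simplify_topography()]) is applied downstream, not at parse time.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical <- function(path)
  read_tsv(path, c("barcode", "project", "stage_raw", "topography_raw"))

#' @rdname read_clinical
#' @param clinical data.frame.
#' @export
write_clinical <- function(clinical, path) write_tsv(clinical, path)

#' Read / write pathway hierarchy files
#'
#' The hierarchy is an edge list (`parent`, `child`); gene-to-pathway
#' annotations are a two-column table (`gene_id`, `pathway_id`) covering all
#' hierarchy levels.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_pathway_edges <- function(path) read_tsv(path, c("parent", "child"))

#' @rdname read_pathway_edges
#' @param edges data.frame.
#' @export
write_pathway_edges <- function(edges, path) write_tsv(edges, path)

#' @rdname read_pathway_edges
#' @export
read_pathway_annotations <- function(path)
  read_tsv(path, c("gene_id", "pathway_id"))

#' @rdname read_pathway_edges
#' @param annotations data.frame.
#' @export
write_pathway_annotations <- function(annotations, path)
  write_tsv(annotations, path)

#' Default PSI-MITAB vocabulary mapping
#'
#' Maps interaction-type and detection-method strings to the `is_physical`
#' and `is_experimental` flags. The defaults treat association and direct
#' interaction types as physical, and common experimental assays as
#' experimental; inference-style methods are non-experimental.
#'
#' @return list with `physical_types` and `experimental_methods`.
#' @export
mitab_vocab <- function() {
  list(
    physical_types = c("physical association", "direct interaction",
                       "association"),
    experimental_methods = c("two hybrid", "pull down",
                             "affinity chromatography technology",
                             "x-ray crystallography",
                             "cross-linking study"))
}

#' Read a PSI-MITAB-subset interaction file
#'
#' Accepts the minimal 6-column dialect (`id_a`, `id_b`, `alias_a`,
#' `alias_b`, `detection_method`, `interaction_type`) or wider files; extra
#' columns are ignored, missing mandatory columns are a parse error. All
#' edges are returned with `is_physical` / `is_experimental` flags derived
#' from `vocab`; discarding non-physical edges is downstream policy, not
#' parsing. Edges are canonicalized undirected (`protein_a <= protein_b`);
#' self-loops and duplicate edges are dropped with a logged count.
#'
#' @param path file path.
#' @param vocab vocabulary mapping, see [mitab_vocab()].
#' @return data.frame of canonical edges with flag columns.
#' @export
read_interactions <- function(path, vocab = mitab_vocab()) {
  df <- read_tsv(path, c("id_a", "id_b", "detection_method",
                         "interaction_type"))
  a <- df$id_a; b <- df$id_b
  swap <- a > b; tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(
    protein_a = a, protein_b = b,
    interaction_type = df$interaction_type,
    detection_method = df$detection_method,
    is_physical = df$interaction_type %in% vocab$physical_types,
    is_experimental = df$detection_method %in% vocab$experimental_methods,
    stringsAsFactors = FALSE)
  self <- out$protein_a == out$protein_b
  if (any(self))
    message("read_interactions: dropped ", sum(self), " self-loop edge(s)")
  out <- out[!self, , drop = FALSE]
  dup <- duplicated(paste(out$protein_a, out$protein_b))
  if (any(dup))
    message("read_interactions: dropped ", sum(dup),
            " duplicate edge(s) after canonicalization")
  out[!dup, , drop = FALSE]
}

#' @rdname read_interactions
#' @param interactions data.frame with `protein_a`, `protein_b`,
#'   `interaction_type`, `detection_method`.
#' @export
write_interactions <- function(interactions, path) {
  write_tsv(data.frame(
    id_a = interactions$protein_a, id_b = interactions$protein_b,
    alias_a = "-", alias_b = "-",
    detection_method = interactions$detection_method,
    interaction_type = interactions$interaction_type,
    stringsAsFactors = FALSE), path)
}

HTSEQ_SUMMARY <- c("__no_feature", "__ambiguous", "__too_low_aQual",
                   "__not_aligned", "__alignment_not_unique")

#' Write / read HTSeq-count files (one two-column TSV per sample)
#'
#' Writers emit one `<barcode>.counts.tsv` per sample, gene rows followed by
#' the usual `__`-prefixed summary lines (which the reader excludes from the
#' gene set). The reader keys samples by the barcode parsed from each file
#' name and validates that all files share an identical gene set and that no
#' count is negative.
#'
#' @param counts integer matrix, genes x samples (column names are barcodes).
#' @param dir output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
write_htseq_counts <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    paths[j] <- file.path(dir, paste0(colnames(counts)[j], ".counts.tsv"))
    df <- data.frame(gene = c(rownames(counts), HTSEQ_SUMMARY),
                     count = c(counts[, j], c(107L, 31L, 5L, 42L, 18L)))
    write.table(df, paths[j], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_htseq_counts
#' @param paths character vector of HTSeq-count file paths.
#' @return for the reader: integer matrix, genes x samples.
#' @export
read_htseq_counts <- function(paths) {
  cols <- list()
  genes_ref <- NULL
  for (p in paths) {
    df <- read.delim(p, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE,
                     col.names = c("gene", "count"))
    df <- df[!startsWith(df$gene, "__"), , drop = FALSE]
    if (any(df$count < 0))
      stop("validation error in ", p, ": negative count")
    if (is.null(genes_ref)) {
      genes_ref <- df$gene
    } else if (!setequal(df$gene, genes_ref)) {
      diff <- union(setdiff(df$gene, genes_ref), setdiff(genes_ref, df$gene))
      stop("validation error: inconsistent gene sets across files; ",
           "symmetric difference: ", paste(diff, collapse = ", "))
    }
    barcode <- sub("\\.counts\\.tsv$", "", basename(p))
    cols[[barcode]] <- setNames(as.integer(df$count), df$gene)[genes_ref]
  }
  do.call(cbind, cols)
}
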