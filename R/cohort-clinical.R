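#' Barcode join key
#'
#' The join key between fusion calls, clinical records and count files is the
#' first three dash-delimited fields of the TCGA-style barcode
#' (e.g. "TCGA-WB-A80K").
#'
#' @param barcode character vector of barcodes.
#' @return character vector of join keys.
#' @export
barcode_key <- function(barcode) {
  vapply(strsplit(barcode, "-", fixed = TRUE), function(p)
    paste(head(p, 3L), collapse = "-"), character(1))
}

#' Left-join clinical records onto annotated fusions
#'
#' Joins on the barcode prefix key. Unmatched fusions are retained with
#' absent clinical fields and their number is logged. Duplicate barcodes in
#' the clinical table are a validation error.
#'
#' @param fusions annotated fusion data.frame (with `sample_barcode`).
#' @param clinical clinical data.frame (with `barcode`, `project`,
#'   `stage_raw`, `topography_raw`).
#' @return `fusions` with `project`, `stage_raw`, `stage`, `topography_raw`,
#'   `topography` columns added (`stage` / `topography` harmonized).
#' @export
join_clinical <- function(fusions, clinical) {
  ckey <- barcode_key(clinical$barcode)
  if (anyDuplicated(ckey))
    stop("validation error: duplicate barcode(s) in clinical table: ",
         paste(unique(ckey[duplicated(ckey)]), collapse = ", "))
  idx <- match(barcode_key(fusions$sample_barcode), ckey)
  n_un <- sum(is.na(idx))
  if (n_un)
    message("join_clinical: ", n_un,
            " fusion(s) without a matching clinical record")
  fusions$project <- clinical$project[idx]
  fusions$stage_raw <- clinical$stage_raw[idx]
  fusions$topography_raw <- clinical$topography_raw[idx]
  fusions$stage <- simplify_stage(fusions$stage_raw)
  fusions$topography <- suppressWarnings(
    simplify_topography(fusions$topography_raw))
  fusions
}

#' Simplify a raw tumor-stage string
#'
#' Trailing sub-stage qualifiers (A/B/C with optional numerals) are stripped,
#' so "Stage IIA" becomes "Stage II". "Stage 0", "Stage X" and "I/II NOS"
#' style entries are ignored (mapped to `NA`). Matching is
#' case-insensitive and the result is restricted to Stage I-IV. The
#' operation is idempotent.
#'
#' @param raw character vector of raw stage strings.
#' @return character vector of "Stage I".."Stage IV" or `NA`.
#' @export
simplify_stage <- function(raw) {
  vapply(raw, function(s) {
    if (is.na(s)) return(NA_character_)
    u <- toupper(trimws(s))
    m <- regmatches(u, regexec("^STAGE\\s+(IV|III|II|I)([ABC][0-9]*)?$", u))[[1]]
    if (length(m)) paste("Stage", m[2]) else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Simplify an ICD-O-3 topography code to its major code
#'
#' "C56.9" becomes "C56"; codes without a dot are returned unchanged;
#' non-conforming codes map to `NA` with a warning.
#'
#' @param code character vector of topography codes.
#' @return character vector of major codes or `NA`.
#' @export
simplify_topography <- function(code) {
  out <- vapply(code, function(s) {
    if (is.na(s)) return(NA_character_)
    s <- trimws(s)
    if (!grepl("^C[0-9]+(\\.[0-9]+)?$", s)) return(NA_character_)
    sub("\\..*$", "", s)
  }, character(1), USE.NAMES = FALSE)
  bad <- !is.na(code) & is.na(out)
  if (any(bad))
    warning("simplify_topography: ", sum(bad),
            " non-conforming code(s) set to NA")
  out
}

#' Bin a breakpoint into 5% chromosomal intervals
#'
#' Each contig is divided into 20 equal-width bins on the position scale;
#' the bin index is `floor(20 * (position - 1) / contig_length)`, clamped to
#' `[0, 19]`.
#'
#' @param position 1-based breakpoint position(s).
#' @param contig_length contig length(s).
#' @return integer bin index in `[0, 19]`.
#' @export
bin_breakpoint <- function(position, contig_length) {
  if (any(position < 1L | position > contig_length))
    stop("bin_breakpoint: position out of range")
  as.integer(pmin(pmax(floor(20 * (position - 1) / contig_length), 0), 19))
}

#' Tabulate breakpoints per contig into 20 bins
#'
#' @param contig,position breakpoint coordinates (vectors).
#' @param contig_lengths named vector of contig lengths.
#' @return data.frame `contig`, `bin_index` (0-19), `count`.
#' @export
bin_breakpoints <- function(contig, position, contig_lengths) {
  bins <- bin_breakpoint(position, contig_lengths[contig])
  out <- expand.grid(contig = unique(contig), bin_index = 0:19,
                     stringsAsFactors = FALSE)
  tab <- table(contig, bins)
  out$count <- mapply(function(cg, b) {
    if (cg %in% rownames(tab) && as.character(b) %in% colnames(tab))
      tab[cg, as.character(b)] else 0L
  }, out$contig, out$bin_index)
  out[order(out$contig, out$bin_index), , drop = FALSE]
}

#' Per-project / per-stage cohort summaries
#'
#' Counts unique fusion-sample pairs. The stage summary covers PK/TF fusions
#' (protein-producing fusions with a PK and/or TF partner) per project and
#' simplified stage: sample count, fusion count and fusions per sample,
#' with groups under `min_samples` flagged. The project summary reports the
#' PK-or-TF fraction of protein-producing fusions per project (absent — not
#' zero — for projects without protein-producing fusions).
#'
#' @param joined output of [join_clinical()] (deduplicated fusions with
#'   clinical fields).
#' @param clinical the clinical table (defines each project's sample count).
#' @param min_samples threshold below which a stage group is flagged small.
#' @return list with `stage_summary` and `project_summary` data.frames.
#' @export
summarize_by_project_stage <- function(joined, clinical, min_samples = 10L) {
  clinical$stage <- simplify_stage(clinical$stage_raw)
  pp <- joined[joined$protein_producing, , drop = FALSE]
  pktf <- pp[pp$category %in% c("PK", "TF", "PK-TF"), , drop = FALSE]

  groups <- unique(clinical[!is.na(clinical$stage),
                            c("project", "stage"), drop = FALSE])
  stage_summary <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    pr <- groups$project[i]; st <- groups$stage[i]
    n_samp <- sum(clinical$project == pr & !is.na(clinical$stage) &
                    clinical$stage == st)
    n_fus <- sum(pktf$project == pr & !is.na(pktf$stage) & pktf$stage == st,
                 na.rm = TRUE)
    data.frame(project = pr, stage = st, n_samples = n_samp,
               n_pk_tf_fusions = n_fus,
               fusions_per_sample = n_fus / n_samp,
               small_group = n_samp < min_samples,
               stringsAsFactors = FALSE)
  }))
  stage_summary <- stage_summary[order(stage_summary$project,
                                       stage_summary$stage), , drop = FALSE]

  projects <- unique(clinical$project)
  project_summary <- do.call(rbind, lapply(projects, function(pr) {
    n_pp <- sum(pp$project == pr, na.rm = TRUE)
    n_pktf <- sum(pktf$project == pr, na.rm = TRUE)
    data.frame(project = pr, n_protein_producing = n_pp,
               n_pk_tf = n_pktf,
               pk_tf_fraction = if (n_pp > 0) n_pktf / n_pp else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(stage_summary = stage_summary, project_summary = project_summary)
}
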