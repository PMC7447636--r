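#' Assess intactness of one domain instance in a fusion protein
#'
#' A domain is intact when its full wild-type amino-acid sequence occurs,
#' unmodified, in the fusion protein; any truncation (even by one residue)
#' breaks the call. The side is assigned from the matched position relative
#' to the 5' partner's contribution: matches starting after `aa5` lie on the
#' 3' side, all others (including junction-spanning reconstructions) on the
#' 5' side.
#'
#' @param fusion_protein amino-acid sequence of the fusion product.
#' @param aa5 number of amino acids contributed by the 5' partner.
#' @param instance one-row data.frame (or list) with at least `sequence`.
#' @return list with `intact` (flag), `side` ("5'", "3'" or `NA` when not
#'   intact) and `match_start`.
#' @export
assess_intactness <- function(fusion_protein, aa5, instance) {
  stopifnot(nzchar(instance$sequence))
  pos <- regexpr(instance$sequence, fusion_protein, fixed = TRUE)
  if (pos < 0L)
    return(list(intact = FALSE, side = NA_character_,
                match_start = NA_integer_))
  list(intact = TRUE, side = if (pos > aa5) "3'" else "5'",
       match_start = as.integer(pos))
}

#' Map wild-type domain instances onto a set of fusion proteins
#'
#' For each protein-producing fusion, every domain instance of either
#' partner is tested for full-length intactness in the fusion protein.
#' The same wild-type instance counts once per fusion, regardless of how
#' many positions it matches at.
#'
#' @param fusions annotated, deduplicated fusion data.frame (rows with
#'   `protein_producing`, `protein`, `aa5`, `gene5`, `gene3`, `fusion_key`).
#' @param domains domain instance table (see [read_domain_table()]).
#' @return data.frame of domain calls: `fusion_key`, `accession`, `name`,
#'   `protein` (wild-type gene), `instance_start`, `instance_end`, `intact`,
#'   `side`.
#' @export
map_domains <- function(fusions, domains) {
  pp <- fusions[fusions$protein_producing, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(pp))) {
    cand <- domains[domains$protein %in% c(pp$gene5[i], pp$gene3[i]), ,
                    drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      res <- assess_intactness(pp$protein[i], pp$aa5[i],
                               cand[k, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        fusion_key = pp$fusion_key[i], accession = cand$accession[k],
        name = cand$name[k], protein = cand$protein[k],
        instance_start = cand$start[k], instance_end = cand$end[k],
        intact = res$intact, side = res$side,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(fusion_key = character(0), accession = character(0),
                      name = character(0), protein = character(0),
                      instance_start = integer(0), instance_end = integer(0),
                      intact = logical(0), side = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Classify domains as PK- or TF-specific
#'
#' Occurrences are counted over intact domain copies within the analyzed
#' fusion set and attributed to PK/TF by the wild-type gene of the fusion
#' side carrying the copy. A domain is PK-specific (TF-specific) when at
#' least 95% of its copies sit on PK (TF) sides; a copy on a gene carrying
#' both labels counts toward PK. Domains with no intact copies are omitted.
#'
#' @param calls domain-call table from [map_domains()].
#' @param fusions the fusion table the calls were computed from (supplies
#'   each fusion's partner genes).
#' @param pk_genes,tf_genes PK / TF gene lists.
#' @param threshold specificity threshold (default 0.95).
#' @return data.frame: `accession`, `copies_total`, `copies_pk`,
#'   `copies_tf`, `class` in PK-specific / TF-specific / neither.
#' @export
classify_specificity <- function(calls, fusions, pk_genes, tf_genes,
                                 threshold = 0.95) {
  ic <- calls[calls$intact, , drop = FALSE]
  if (!nrow(ic))
    return(data.frame(accession = character(0), copies_total = integer(0),
                      copies_pk = integer(0), copies_tf = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  idx <- match(ic$fusion_key, fusions$fusion_key)
  side_gene <- ifelse(ic$side == "5'", fusions$gene5[idx],
                      fusions$gene3[idx])
  is_pk <- side_gene %in% pk_genes
  is_tf <- !is_pk & side_gene %in% tf_genes
  out <- do.call(rbind, lapply(unique(ic$accession), function(acc) {
    sel <- ic$accession == acc
    tot <- sum(sel); pk <- sum(is_pk[sel]); tf <- sum(is_tf[sel])
    cls <- if (pk / tot >= threshold) "PK-specific"
           else if (tf / tot >= threshold) "TF-specific"
           else "neither"
    data.frame(accession = acc, copies_total = tot, copies_pk = pk,
               copies_tf = tf, class = cls, stringsAsFactors = FALSE)
  }))
  out[order(out$accession), , drop = FALSE]
}

#' Domain-retention summaries
#'
#' Mean intact domains per protein-producing fusion, overall and split into
#' PK/TF fusions versus other protein-producing fusions, plus per-project
#' percentages of intact copies that belong to PK-/TF-specific domains.
#'
#' @param calls domain-call table from [map_domains()].
#' @param fusions annotated fusion table (with `project` when per-project
#'   splits are wanted).
#' @param specificity specificity table from [classify_specificity()].
#' @return list with `overall` (data.frame of means) and `per_project`
#'   (data.frame of PK-/TF-specific copy percentages; `NULL` without a
#'   `project` column).
#' @export
summarize_domains <- function(calls, fusions, specificity = NULL) {
  pp <- fusions[fusions$protein_producing, , drop = FALSE]
  ic <- calls[calls$intact, , drop = FALSE]
  n_intact <- setNames(rep(0L, nrow(pp)), pp$fusion_key)
  if (nrow(ic)) {
    tab <- table(ic$fusion_key)
    n_intact[names(tab)] <- as.integer(tab)
  }
  is_pktf <- pp$category %in% c("PK", "TF", "PK-TF")
  mean_or_zero <- function(x) if (length(x)) mean(x) else 0
  overall <- data.frame(
    group = c("all", "PK/TF", "other"),
    n_fusions = c(nrow(pp), sum(is_pktf), sum(!is_pktf)),
    mean_intact_domains = c(mean_or_zero(n_intact),
                            mean_or_zero(n_intact[is_pktf]),
                            mean_or_zero(n_intact[!is_pktf])),
    stringsAsFactors = FALSE)

  per_project <- NULL
  if (!is.null(specificity) && "project" %in% names(pp) && nrow(ic)) {
    cls <- setNames(specificity$class, specificity$accession)
    proj <- pp$project[match(ic$fusion_key, pp$fusion_key)]
    per_project <- do.call(rbind, lapply(
      unique(proj[!is.na(proj)]), function(pr) {
        sel <- !is.na(proj) & proj == pr
        tot <- sum(sel)
        pk <- sum(cls[ic$accession[sel]] == "PK-specific", na.rm = TRUE)
        tf <- sum(cls[ic$accession[sel]] == "TF-specific", na.rm = TRUE)
        data.frame(project = pr, n_intact_copies = tot,
                   pct_pk_specific = 100 * pk / tot,
                   pct_tf_specific = 100 * tf / tot,
                   stringsAsFactors = FALSE)
      }))
  }
  list(overall = overall, per_project = per_project)
}
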