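#' Specification of a synthetic fusion cohort
#'
#' Bundles every tunable of the synthetic-data generators: cohort size,
#' the fraction of fusions constructed in-frame, the fraction of genes
#' labeled protein kinase (PK) or transcription factor (TF), the
#' negative-binomial expression model, and the planted differential-expression
#' effects. All generators are pure functions of `(spec, seed)`.
#'
#' @param n_genes number of genes in the synthetic genome (one contig each).
#' @param n_samples number of cohort samples (TCGA-style barcodes).
#' @param n_fusions number of fusion breakpoint calls to generate.
#' @param frac_inframe target fraction of fusions whose junction preserves the
#'   3' partner's reading frame, in `[0, 1]`.
#' @param frac_pk,frac_tf fraction of genes labeled PK / TF
#'   (`frac_pk + frac_tf <= 1`).
#' @param nb_mean_log_range length-2 numeric, natural-log bounds for baseline
#'   expression means.
#' @param nb_dispersion shared NB dispersion `d` in `var = mu + d * mu^2`;
#'   must be positive.
#' @param planted_pairs list of planted effects, each a list with elements
#'   `pair` (canonical "A-B" gene-pair label), `genes` (character vector of
#'   gene ids) and `log2fc` (numeric scalar).
#' @param n_recurrent number of recurrent in-frame PK/TF fusion pairs planted
#'   across multiple samples (so pair groups with >= 2 expression files exist,
#'   as the differential-expression stage requires).
#' @param recurrent_depth number of samples each recurrent pair is planted in.
#' @param n_projects number of synthetic cancer projects samples are split
#'   across.
#' @param frac_nonphysical fraction of interaction edges flagged
#'   non-physical/non-experimental, to exercise downstream filtering.
#' @param dag_depth depth of the generated pathway hierarchy.
#' @param census_rate fraction of proteins placed on the synthetic cancer gene
#'   census list.
#' @param seed integer master seed.
#' @return object of class `fs_cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_genes = 80L, n_samples = 80L, n_fusions = 250L,
                        frac_inframe = 0.69, frac_pk = 0.1, frac_tf = 0.1,
                        nb_mean_log_range = c(log(20), log(2000)),
                        nb_dispersion = 0.1, planted_pairs = list(),
                        n_recurrent = 3L, recurrent_depth = 5L,
                        n_projects = 4L, frac_nonphysical = 0.2,
                        dag_depth = 4L, census_rate = 0.2, seed = 1L) {
  spec <- list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    n_fusions = as.integer(n_fusions), frac_inframe = frac_inframe,
    frac_pk = frac_pk, frac_tf = frac_tf,
    nb_mean_log_range = nb_mean_log_range, nb_dispersion = nb_dispersion,
    planted_pairs = planted_pairs, n_recurrent = as.integer(n_recurrent),
    recurrent_depth = as.integer(recurrent_depth),
    n_projects = as.integer(n_projects),
    frac_nonphysical = frac_nonphysical, dag_depth = as.integer(dag_depth),
    census_rate = census_rate, seed = as.integer(seed)
  )
  class(spec) <- "fs_cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_genes < 2L) stop("invalid spec: n_genes must be >= 2")
  if (spec$n_samples < 1L) stop("invalid spec: n_samples must be >= 1")
  if (spec$n_fusions < 0L) stop("invalid spec: n_fusions must be >= 0")
  if (spec$frac_inframe < 0 || spec$frac_inframe > 1)
    stop("invalid spec: frac_inframe must lie in [0, 1]")
  if (spec$frac_pk < 0 || spec$frac_tf < 0 ||
      spec$frac_pk + spec$frac_tf > 1)
    stop("invalid spec: frac_pk + frac_tf must not exceed 1")
  if (!is.numeric(spec$nb_dispersion) || spec$nb_dispersion <= 0)
    stop("invalid spec: nb_dispersion must be positive")
  if (length(spec$nb_mean_log_range) != 2L ||
      diff(spec$nb_mean_log_range) < 0)
    stop("invalid spec: nb_mean_log_range must be increasing bounds")
  for (pp in spec$planted_pairs) {
    if (!all(c("pair", "genes", "log2fc") %in% names(pp)))
      stop("invalid spec: each planted pair needs pair, genes, log2fc")
  }
  invisible(spec)
}
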