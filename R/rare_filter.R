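#' Rare-variant filter configuration
#'
#' Thresholds for the annotation-based candidate filters: functional
#' consequence (protein-altering or splice-site, including splice-site
#' synonymous), rarity across a panel of population frequency databases,
#' gene intolerance (RVIS percentile) and brain expression.
#'
#' @param max_af Maximum allele frequency tolerated in every configured
#'   database (default 0.01, i.e. <= 1%).
#' @param databases Database names; each must appear as an `af_<name>`
#'   column of the annotation table.  Defaults to the five-panel
#'   `1000G_ALL`, `ExAC_ALL`, `ExAC_EAS`, `HGVD`, `jMorp`.
#' @param max_rvis_percentile Keep genes with RVIS percentile <= this
#'   (default 25; low percentiles are intolerant genes).
#' @param min_brain_nx Keep genes with normalized brain expression >=
#'   this (default 1).
#' @param protein_altering_classes Consequence classes counted as
#'   protein-altering.
#' @param include_splice_synonymous Keep synonymous variants when they lie
#'   in a splice site (default `TRUE`).
#' @return A list of class `famseg_filter_config`.
#' @export
filter_config <- function(max_af = 0.01,
                          databases = c("1000G_ALL", "ExAC_ALL", "ExAC_EAS",
                                        "HGVD", "jMorp"),
                          max_rvis_percentile = 25,
                          min_brain_nx = 1,
                          protein_altering_classes = c("nonsynonymous",
                                                       "stopgain", "stoploss",
                                                       "frameshift_indel",
                                                       "inframe_indel",
                                                       "splicing"),
                          include_splice_synonymous = TRUE) {
  stopifnot(max_af >= 0, max_af <= 1,
            max_rvis_percentile >= 0, max_rvis_percentile <= 100)
  structure(list(max_af = max_af, databases = databases,
                 max_rvis_percentile = max_rvis_percentile,
                 min_brain_nx = min_brain_nx,
                 protein_altering_classes = protein_altering_classes,
                 include_splice_synonymous = include_splice_synonymous),
            class = "famseg_filter_config")
}

af_column <- function(db) paste0("af_", gsub("[^A-Za-z0-9_]", "_", db))

#' Consequence filter predicate
#'
#' `TRUE` for protein-altering consequences (nonsynonymous, stopgain,
#' stoploss, frameshift/in-frame indel, splicing) and for synonymous
#' variants located in a splice site.
#'
#' @param consequence Character vector of consequence classes.
#' @param splice_site Logical vector.
#' @param cfg A [filter_config()].
#' @return Logical vector.
#' @export
is_candidate_consequence <- function(consequence, splice_site,
                                     cfg = filter_config()) {
  hit <- consequence %in% cfg$protein_altering_classes
  if (cfg$include_splice_synonymous) {
    hit <- hit | (consequence %in% "synonymous" & splice_site %in% TRUE)
  }
  hit
}

#' Frequency filter predicate
#'
#' `TRUE` when the variant's allele frequency is at most `max_af` in
#' *every* configured database.  A missing frequency means the variant was
#' not observed in that database and passes (novel variants pass in all).
#'
#' @param ann Annotation data frame (rows aligned to variants) containing
#'   an `af_<db>` column for every configured database.
#' @param cfg A [filter_config()].
#' @return Logical vector.
#' @export
passes_frequency <- function(ann, cfg = filter_config()) {
  cols <- af_column(cfg$databases)
  absent <- setdiff(cols, names(ann))
  if (length(absent) > 0) {
    stop("configured frequency database column(s) missing from annotation: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ok <- rep(TRUE, nrow(ann))
  for (col in cols) {
    af <- ann[[col]]
    ok <- ok & (is.na(af) | af <= cfg$max_af)
  }
  ok
}

#' Gene-constraint filter predicate
#'
#' `TRUE` when at least one overlapped gene is both intolerant (RVIS
#' percentile <= `max_rvis_percentile`) and brain-expressed (normalized
#' expression >= `min_brain_nx`); both bounds inclusive.  Genes missing
#' from the gene table fail individually.
#'
#' @param genes Comma-separated gene symbols per variant.
#' @param gene_ann Gene annotation data frame (`gene`, `rvis_percentile`,
#'   `brain_nx`).
#' @param cfg A [filter_config()].
#' @return Logical vector.
#' @export
passes_gene_constraints <- function(genes, gene_ann, cfg = filter_config()) {
  ok_gene <- gene_ann$rvis_percentile <= cfg$max_rvis_percentile &
    gene_ann$brain_nx >= cfg$min_brain_nx
  good <- gene_ann$gene[!is.na(ok_gene) & ok_gene]
  vapply(split_genes(genes), function(g) any(g %in% good), logical(1))
}

#' Apply the rare-variant filters to an annotated table
#'
#' Conjunction of the consequence, frequency and gene-constraint
#' predicates; unannotated variants are dropped.  The predicates commute,
#' so application order does not matter.
#'
#' @param vt An annotated, QC-passed `famseg_vtab`.
#' @param cfg A [filter_config()].
#' @return The filtered table with a `filter_report` attribute counting,
#'   per rule, the variants that fail it (`n_in`, `n_unannotated`,
#'   `n_fail_consequence`, `n_fail_frequency`, `n_fail_gene`, `n_out`).
#' @export
apply_rare_filters <- function(vt, cfg = filter_config()) {
  if (is.null(vt$ann) || is.null(vt$gene_ann)) {
    stop("apply_rare_filters requires an annotated table; ",
         "run join_annotations() first", call. = FALSE)
  }
  ann <- vt$ann
  annotated <- ann$annotated
  ok_cons <- is_candidate_consequence(ann$consequence, ann$splice_site, cfg)
  ok_freq <- passes_frequency(ann, cfg)
  ok_gene <- passes_gene_constraints(ann$genes, vt$gene_ann, cfg)
  keep <- annotated & ok_cons & ok_freq & ok_gene
  keep[is.na(keep)] <- FALSE
  out <- subset_variants(vt, keep)
  attr(out, "filter_report") <- list(
    n_in = n_variants(vt),
    n_unannotated = sum(!annotated),
    n_fail_consequence = sum(annotated & !ok_cons, na.rm = TRUE),
    n_fail_frequency = sum(annotated & !ok_freq, na.rm = TRUE),
    n_fail_gene = sum(annotated & !ok_gene, na.rm = TRUE),
    n_out = n_variants(out)
  )
  out
}
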