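as_inhouse_counts <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) {
    return(stats::setNames(as.integer(x$detection_count),
                           variant_key(x$chrom, x$pos, x$ref, x$alt)))
  }
  x
}

#' Default enrichment universe of a bundle
#'
#' The genes carrying both an RVIS percentile and a brain-expression
#' value: the search space the rare-variant filters operate over.
#'
#' @param gene_ann Gene annotation data frame.
#' @return Character vector of gene symbols.
#' @export
default_universe <- function(gene_ann) {
  gene_ann$gene[!is.na(gene_ann$rvis_percentile) & !is.na(gene_ann$brain_nx)]
}

#' Run the full analysis pipeline on an input bundle
#'
#' Stage order: annotation join, quality control, kinship verification,
#' rare-variant filters, per-pedigree segregation classification and
#' candidate-set construction, then gene-set over-representation of the
#' candidate genes of each set (all-pedigree and strict).
#'
#' @param bundle A `famseg_bundle` from [simulate_cohort()],
#'   [read_bundle()] or [table2_fixture()].
#' @param qc_cfg A [qc_config()].
#' @param filter_cfg A [filter_config()].
#' @param mode Sharing mode for segregation (`"all"` or `"min2"`).
#' @param alpha Enrichment significance level on the Q-value.
#' @param universe Enrichment universe (default:
#'   [default_universe()] of the bundle's gene table).
#' @param kinship Compute the kinship verification stage (`TRUE` by
#'   default; it is informational and does not gate the pipeline).
#' @return A list of class `famseg_run` with elements `qc_report`,
#'   `filter_report`, `kinship` (verified pair table or `NULL`),
#'   `candidates` (list `all`/`strict`), `summary` (list `all`/`strict`
#'   from [summarize_candidates()]) and `enrichment` (list
#'   `all`/`strict`, `NULL` without gene sets).
#' @export
run_pipeline <- function(bundle, qc_cfg = qc_config(),
                         filter_cfg = filter_config(),
                         mode = c("all", "min2"), alpha = 0.05,
                         universe = NULL, kinship = TRUE) {
  mode <- match.arg(mode)
  vt <- join_annotations(bundle$vt, bundle$ann, bundle$gene_ann)
  vt_qc <- apply_qc(vt, as_inhouse_counts(bundle$inhouse), qc_cfg)
  kin <- NULL
  if (kinship) {
    kin <- verify_pedigrees(kinship_matrix(vt_qc), bundle$ped)
  }
  vt_filt <- apply_rare_filters(vt_qc, filter_cfg)
  sets <- build_candidate_sets(vt_filt, bundle$ped, mode = mode)
  summaries <- lapply(sets, summarize_candidates)
  enr <- NULL
  if (length(bundle$gmt) > 0) {
    if (is.null(universe)) universe <- default_universe(bundle$gene_ann)
    enr <- lapply(summaries, function(s) {
      enrich(s$genes, bundle$gmt, universe, alpha = alpha)
    })
  }
  structure(list(qc_report = attr(vt_qc, "qc_report"),
                 filter_report = attr(vt_filt, "filter_report"),
                 kinship = kin, candidates = sets, summary = summaries,
                 enrichment = enr,
                 config = list(qc = unclass(qc_cfg),
                               filter = unclass(filter_cfg),
                               mode = mode, alpha = alpha)),
            class = "famseg_run")
}

#' @export
print.famseg_run <- function(x, ...) {
  cat("famseg pipeline run\n")
  cat(sprintf("  QC: %d -> %d variants\n", x$qc_report$n_in, x$qc_report$n_out))
  cat(sprintf("  rare filters: %d -> %d variants\n",
              x$filter_report$n_in, x$filter_report$n_out))
  cat(sprintf("  candidates (all): %d variants in %d genes\n",
              x$summary$all$n_variants, x$summary$all$n_genes))
  cat(sprintf("  candidates (strict): %d variants in %d genes\n",
              x$summary$strict$n_variants, x$summary$strict$n_genes))
  if (!is.null(x$kinship)) {
    cat(sprintf("  kinship: %d pairs, %d mismatching expectation\n",
                nrow(x$kinship), sum(x$kinship$mismatch)))
  }
  invisible(x)
}

#' Write a bundle to a directory of plain-text files
#'
#' Emits the exact dialects the pipeline's readers consume: `cohort.vcf`,
#' `cohort.ped`, `cohort_meta.tsv`, `annotations.tsv`, `genes.tsv`,
#' `inhouse_counts.tsv`, `gene_sets.gmt`, `truth.tsv` and a
#' `manifest.json` echoing the simulation config and seed.  Output is
#' deterministic (no timestamps), so identical bundles yield
#' byte-identical files.
#'
#' @param bundle A `famseg_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             ped = file.path(dir, "cohort.ped"),
             meta = file.path(dir, "cohort_meta.tsv"),
             ann = file.path(dir, "annotations.tsv"),
             genes = file.path(dir, "genes.tsv"),
             inhouse = file.path(dir, "inhouse_counts.tsv"),
             gmt = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_vcf(bundle$vt, paths["vcf"])
  write_ped(bundle$ped, paths["ped"])
  meta <- data.frame(family_id = bundle$ped$family_id,
                     individual_id = bundle$ped$individual_id,
                     sequenced = as.integer(bundle$ped$sequenced),
                     consanguineous = as.integer(bundle$ped$consanguineous),
                     diagnosis = bundle$ped$diagnosis,
                     stringsAsFactors = FALSE)
  wt <- function(x, p) {
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  wt(meta, paths["meta"])
  wt(bundle$ann, paths["ann"])
  wt(bundle$gene_ann, paths["genes"])
  wt(bundle$inhouse, paths["inhouse"])
  if (length(bundle$gmt) > 0) {
    write_gmt(bundle$gmt, paths["gmt"])
  } else {
    writeLines(character(0), paths["gmt"])
  }
  wt(bundle$truth, paths["truth"])
  jsonlite::write_json(list(package = "famseg",
                            config = unclass(bundle$config)),
                       paths["manifest"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Read a bundle directory back through the pipeline's own readers
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `famseg_bundle` (the truth table is reread when present).
#' @export
read_bundle <- function(dir) {
  need <- c("cohort.vcf", "cohort.ped", "cohort_meta.tsv", "annotations.tsv",
            "genes.tsv", "inhouse_counts.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    stop("missing input file(s): ",
         paste(file.path(dir, missing), collapse = ", "), call. = FALSE)
  }
  ped <- attach_ped_meta(read_ped(file.path(dir, "cohort.ped")),
                         read_ped_meta(file.path(dir, "cohort_meta.tsv")))
  vt <- read_vcf(file.path(dir, "cohort.vcf"))
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  gene_ann <- read_gene_annotations(file.path(dir, "genes.tsv"))
  inhouse_path <- file.path(dir, "inhouse_counts.tsv")
  inhouse <- utils::read.table(inhouse_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE,
                               colClasses = c(chrom = "character"))
  gmt_path <- file.path(dir, "gene_sets.gmt")
  gmt <- if (file.exists(gmt_path) && file.size(gmt_path) > 0) {
    read_gmt(gmt_path)
  } else list()
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    utils::read.table(truth_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = c(chrom = "character"))
  } else NULL
  manifest_path <- file.path(dir, "manifest.json")
  config <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)$config
  } else NULL
  structure(list(ped = ped, vt = vt, ann = ann, gene_ann = gene_ann,
                 inhouse = inhouse, gmt = gmt, truth = truth,
                 config = config),
            class = "famseg_bundle")
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  qc <- data.frame(rule = names(run$qc_report),
                   count = unlist(run$qc_report), stringsAsFactors = FALSE)
  rownames(qc) <- NULL
  wt(qc, "qc_report.tsv")
  filt <- data.frame(rule = names(run$filter_report),
                     count = unlist(run$filter_report), stringsAsFactors = FALSE)
  rownames(filt) <- NULL
  wt(filt, "filter_report.tsv")
  if (!is.null(run$kinship)) wt(run$kinship, "kinship.tsv")
  wt(run$candidates$all, "candidates_all.tsv")
  wt(run$candidates$strict, "candidates_strict.tsv")
  if (!is.null(run$enrichment)) {
    wt(run$enrichment$all, "enrichment_all.tsv")
    wt(run$enrichment$strict, "enrichment_strict.tsv")
  }
  summary <- lapply(run$summary, function(s) {
    list(n_variants = s$n_variants, n_genes = s$n_genes,
         per_class = as.list(s$per_class), per_family = as.list(s$per_family))
  })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "famseg", config = run$config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the pipeline end-to-end on a bundle directory
#'
#' Reads every input with the package's readers, executes
#' [run_pipeline()], and writes machine-readable reports: QC and filter
#' rule counts, the verified kinship table, both candidate TSVs, a
#' summary JSON and enrichment TSVs, plus a manifest echoing the
#' configuration.  Outputs are deterministic: running twice on identical
#' inputs yields byte-identical files.
#'
#' @param input_dir Bundle directory (see [write_bundle()]).
#' @param out_dir Output directory.
#' @inheritParams run_pipeline
#' @return The `famseg_run`, invisibly.
#' @export
run_all <- function(input_dir, out_dir, qc_cfg = qc_config(),
                    filter_cfg = filter_config(), mode = "all",
                    alpha = 0.05) {
  bundle <- read_bundle(input_dir)
  run <- run_pipeline(bundle, qc_cfg = qc_cfg, filter_cfg = filter_cfg,
                      mode = mode, alpha = alpha)
  write_run(run, out_dir)
  invisible(run)
}
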