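#' Quality-control configuration
#'
#' Thresholds for genotype- and site-level QC.  Defaults follow standard
#' exome practice for family studies: read depth >= 10, genotype quality
#' >= 20, alternative allele ratio >= 25% for non-reference calls, sites
#' must pass VQSR and lie outside segmental duplications, and variants
#' detected in >= 20 samples of an in-house exome cohort are excluded as
#' platform-dependent systematic errors.
#'
#' @param min_dp Minimum read depth per call.
#' @param min_gq Minimum genotype quality per call.
#' @param min_aar Minimum alternative allele ratio for non-homref calls.
#' @param require_vqsr_pass Drop sites whose FILTER is not PASS.
#' @param exclude_segdup Drop sites flagged as segmental duplication.
#' @param inhouse_max_detections Highest tolerated in-house detection
#'   count; a variant seen in more samples than this is excluded
#'   (default 19, i.e. exclusion at >= 20 detections).
#' @return A list of class `famseg_qc_config`.
#' @export
qc_config <- function(min_dp = 10, min_gq = 20, min_aar = 0.25,
                      require_vqsr_pass = TRUE, exclude_segdup = TRUE,
                      inhouse_max_detections = 19) {
  stopifnot(min_aar >= 0, min_aar <= 1, min_dp >= 0, min_gq >= 0,
            inhouse_max_detections >= 0)
  structure(list(min_dp = min_dp, min_gq = min_gq, min_aar = min_aar,
                 require_vqsr_pass = require_vqsr_pass,
                 exclude_segdup = exclude_segdup,
                 inhouse_max_detections = inhouse_max_detections),
            class = "famseg_qc_config")
}

#' Alternative allele ratio of a genotype call
#'
#' `ad_alt / (ad_ref + ad_alt)`: the fraction of reads supporting the
#' alternate allele.  Undefined (`NA`) when the depths are missing or sum
#' to zero; an undefined ratio fails the QC threshold.
#'
#' @param ad_ref,ad_alt Reference / alternate allelic depths (vectors or
#'   matrices).
#' @return Numeric of the same shape, `NA` where undefined.
#' @export
alt_allele_ratio <- function(ad_ref, ad_alt) {
  tot <- ad_ref + ad_alt
  out <- ad_alt / tot
  out[!is.na(tot) & tot == 0] <- NA_real_
  out
}

#' Genotype-level QC predicate
#'
#' A call passes when depth and quality meet their thresholds and, for
#' non-reference genotypes, the alternative allele ratio meets its
#' threshold.  Homozygous-reference calls pass the ratio check vacuously;
#' missing genotypes fail.
#'
#' @param gt Genotype codes (0/1/2/`NA`).
#' @param dp,gq,ad_ref,ad_alt Call-level metrics, same shape as `gt`.
#' @param cfg A [qc_config()].
#' @return Logical of the same shape.
#' @export
passes_genotype_qc <- function(gt, dp, gq, ad_ref, ad_alt, cfg = qc_config()) {
  aar <- alt_allele_ratio(ad_ref, ad_alt)
  ok_aar <- (!is.na(gt) & gt == 0) | (!is.na(aar) & aar >= cfg$min_aar)
  ok <- !is.na(gt) &
    !is.na(dp) & dp >= cfg$min_dp &
    !is.na(gq) & gq >= cfg$min_gq &
    ok_aar
  ok
}

#' Site-level QC predicate
#'
#' @param filter_status Site FILTER status (`"pass"`, `"fail"`, `"other"`).
#' @param segdup Logical segmental-duplication flag (`NA` treated as
#'   `FALSE`: unannotated sites are not dropped here).
#' @param cfg A [qc_config()].
#' @return Logical vector.
#' @export
passes_site_qc <- function(filter_status, segdup, cfg = qc_config()) {
  ok <- rep(TRUE, length(filter_status))
  if (cfg$require_vqsr_pass) ok <- ok & filter_status == "pass"
  if (cfg$exclude_segdup) ok <- ok & !(segdup %in% TRUE)
  ok
}

#' In-house cohort exclusion predicate
#'
#' @param keys Variant keys (`chrom:pos:ref:alt`).
#' @param cohort_counts Named count vector from [read_inhouse_counts()];
#'   absent keys count 0.
#' @param cfg A [qc_config()].
#' @return Logical: `TRUE` where the variant is excluded (detections
#'   exceed `inhouse_max_detections`).
#' @export
inhouse_excluded <- function(keys, cohort_counts, cfg = qc_config()) {
  cnt <- cohort_counts[keys]
  cnt[is.na(cnt)] <- 0L
  unname(cnt > cfg$inhouse_max_detections)
}

#' Apply all quality-control rules to a variant table
#'
#' Site-failing records (VQSR failure, segmental duplication) and
#' in-house-excluded variants are dropped.  Genotype-failing calls are
#' demoted to missing rather than dropping the site, so that e.g. a
#' low-quality parental call can still block a de novo assignment; a site
#' is dropped only when no call survives.  The operation is idempotent.
#'
#' @param vt A `famseg_vtab` (annotated, if segdup exclusion is wanted).
#' @param cohort_counts Named detection-count vector (may be `NULL`).
#' @param cfg A [qc_config()].
#' @return The filtered `famseg_vtab` with a `qc_report` attribute: a list
#'   of per-rule counts (`n_in`, `n_fail_vqsr`, `n_fail_segdup`,
#'   `n_inhouse_excluded`, `n_calls_demoted`, `n_all_missing`, `n_out`).
#' @export
apply_qc <- function(vt, cohort_counts = NULL, cfg = qc_config()) {
  n_in <- n_variants(vt)
  segdup <- if (is.null(vt$ann)) rep(NA, n_in) else vt$ann$segdup
  fail_vqsr <- if (cfg$require_vqsr_pass) vt$variants$filter_status != "pass"
               else rep(FALSE, n_in)
  fail_segdup <- if (cfg$exclude_segdup) segdup %in% TRUE else rep(FALSE, n_in)
  excl_inhouse <- if (is.null(cohort_counts)) rep(FALSE, n_in)
                  else inhouse_excluded(vt$variants$key, cohort_counts, cfg)

  keep_site <- !(fail_vqsr | fail_segdup | excl_inhouse)
  vt2 <- subset_variants(vt, keep_site)

  ok <- passes_genotype_qc(vt2$gt, vt2$dp, vt2$gq, vt2$ad_ref, vt2$ad_alt, cfg)
  n_demoted <- sum(!ok & !is.na(vt2$gt))
  vt2$gt[!ok] <- NA_real_

  any_call <- rowSums(!is.na(vt2$gt)) > 0
  n_all_missing <- sum(!any_call)
  vt2 <- subset_variants(vt2, any_call)

  report <- list(
    n_in = n_in,
    n_fail_vqsr = sum(fail_vqsr),
    n_fail_segdup = sum(fail_segdup),
    n_inhouse_excluded = sum(excl_inhouse),
    n_calls_demoted = n_demoted,
    n_all_missing = n_all_missing,
    n_out = n_variants(vt2)
  )
  attr(vt2, "qc_report") <- report
  vt2
}
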