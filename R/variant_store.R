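#' @importFrom stats setNames
NULL

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct a variant table
#'
#' The central container of the pipeline: one row per biallelic variant
#' (after multiallelic splitting) with per-sample call matrices.  Genotypes
#' are coded 0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternate, `NA` = missing.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `filter_status` (`"pass"`, `"fail"`, `"other"`).
#' @param samples Character vector of sample ids (column order of the
#'   matrices).
#' @param gt,ad_ref,ad_alt,dp,gq Numeric matrices, variants x samples.
#' @param other_alt Logical matrix flagging calls that carried a different
#'   alternate allele before multiallelic splitting (recoded to 0 for this
#'   record).
#' @return An object of class `famseg_vtab`.
#' @export
variant_table <- function(variants, samples, gt, ad_ref, ad_alt, dp, gq,
                          other_alt = NULL) {
  n <- nrow(variants)
  variants$pos <- as.integer(variants$pos)
  stopifnot(all(variants$pos >= 1L))
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  if (anyDuplicated(variants$key)) {
    stop("duplicate variant key: ",
         variants$key[duplicated(variants$key)][1], call. = FALSE)
  }
  for (m in list(gt, ad_ref, ad_alt, dp, gq)) {
    stopifnot(nrow(m) == n, ncol(m) == length(samples))
  }
  if (is.null(other_alt)) {
    other_alt <- matrix(FALSE, n, length(samples))
  }
  dimnames(gt) <- dimnames(ad_ref) <- dimnames(ad_alt) <- dimnames(dp) <-
    dimnames(gq) <- dimnames(other_alt) <- list(variants$key, samples)
  structure(list(variants = variants, samples = samples, gt = gt,
                 ad_ref = ad_ref, ad_alt = ad_alt, dp = dp, gq = gq,
                 other_alt = other_alt, ann = NULL, gene_ann = NULL),
            class = "famseg_vtab")
}

#' @export
print.famseg_vtab <- function(x, ...) {
  cat(sprintf("famseg variant table: %d variants x %d samples (%s)\n",
              nrow(x$variants), length(x$samples),
              if (is.null(x$ann)) "unannotated" else "annotated"))
  invisible(x)
}

n_variants <- function(vt) nrow(vt$variants)

subset_variants <- function(vt, idx) {
  vt$variants <- vt$variants[idx, , drop = FALSE]
  rownames(vt$variants) <- NULL
  for (m in c("gt", "ad_ref", "ad_alt", "dp", "gq", "other_alt")) {
    vt[[m]] <- vt[[m]][idx, , drop = FALSE]
  }
  if (!is.null(vt$ann)) {
    vt$ann <- vt$ann[idx, , drop = FALSE]
    rownames(vt$ann) <- NULL
  }
  vt
}

#' Read a multi-sample VCF into a variant table
#'
#' Parses VCF 4.x (plain or bgzipped) via `vcfR`, then splits multiallelic
#' sites into one record per alternate allele (see
#' [split_multiallelic()]).  `GT` is required in FORMAT; `AD`, `DP` and
#' `GQ` are optional and yield missing values when absent.
#'
#' @param path Path to the VCF.
#' @return A `famseg_vtab` (see [variant_table()]).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_str <- vcfR::extract.gt(v, element = "GT")
  ad_str <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                     error = function(e) NULL)
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  gq <- tryCatch(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE),
                 error = function(e) NULL)
  samples <- colnames(v@gt)[-1]
  nv <- nrow(fix)
  blank_num <- function(m) if (is.null(m)) matrix(NA_real_, nv, length(samples)) else m
  blank_chr <- function(m) if (is.null(m)) matrix(NA_character_, nv, length(samples)) else m
  raw <- list(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
              alt = fix$ALT, filter = fix$FILTER, samples = samples,
              gt_str = gt_str, ad_str = blank_chr(ad_str),
              dp = blank_num(dp), gq = blank_num(gq))
  split_multiallelic(raw)
}

filter_status_of <- function(filter) {
  ifelse(filter == "PASS", "pass",
         ifelse(is.na(filter) | filter == ".", "other", "fail"))
}

#' Split multiallelic sites into per-allele records
#'
#' A site with k alternate alleles becomes k records sharing
#' `chrom`/`pos`/`ref`.  For the record of allele a: genotypes are recoded
#' against a (0/a het, a/a hom-alt); any call carrying a *different*
#' alternate allele (including mixed calls such as 1/2) is not a carrier
#' of allele a and is recoded to homozygous reference with the
#' `other_alt` flag set; `ad_alt` is allele a's own depth and `ad_ref`
#' the REF depth from the per-allele AD decomposition.  Biallelic input
#' passes through unchanged.
#'
#' @param raw A raw parse as produced inside [read_vcf()]: a list with
#'   `chrom`, `pos`, `ref`, `alt` (comma-joined alleles), `filter`,
#'   `samples`, and matrices `gt_str`, `ad_str`, `dp`, `gq`.
#' @return A `famseg_vtab` with one row per (site, alternate allele).
#' @export
split_multiallelic <- function(raw) {
  alts <- strsplit(raw$alt, ",", fixed = TRUE)
  k <- lengths(alts)
  site_idx <- rep(seq_along(k), k)
  allele_idx <- unlist(lapply(k, seq_len))
  n_out <- length(site_idx)
  ns <- length(raw$samples)

  variants <- data.frame(
    chrom = raw$chrom[site_idx],
    pos = raw$pos[site_idx],
    ref = raw$ref[site_idx],
    alt = unlist(alts),
    filter_status = filter_status_of(raw$filter[site_idx]),
    stringsAsFactors = FALSE
  )

  gt <- matrix(NA_real_, n_out, ns)
  ad_ref <- matrix(NA_real_, n_out, ns)
  ad_alt <- matrix(NA_real_, n_out, ns)
  other_alt <- matrix(FALSE, n_out, ns)

  # parse GT strings once per input site
  gt_alleles <- lapply(seq_along(raw$chrom), function(i) {
    lapply(strsplit(raw$gt_str[i, ], "[/|]"), function(a) {
      suppressWarnings(as.integer(a))
    })
  })
  ad_fields <- lapply(seq_along(raw$chrom), function(i) {
    lapply(strsplit(raw$ad_str[i, ], ",", fixed = TRUE), function(a) {
      suppressWarnings(as.numeric(a))
    })
  })

  for (r in seq_len(n_out)) {
    i <- site_idx[r]
    a <- allele_idx[r]
    for (s in seq_len(ns)) {
      al <- gt_alleles[[i]][[s]]
      if (length(al) == 0L || anyNA(al)) {
        gt[r, s] <- NA_real_
      } else if (any(!(al %in% c(0L, a)))) {
        gt[r, s] <- 0
        other_alt[r, s] <- TRUE
      } else {
        gt[r, s] <- if (length(al) == 1L) {
          if (al == a) 2 else 0   # haploid call
        } else {
          sum(al == a)
        }
      }
      ad <- ad_fields[[i]][[s]]
      if (length(ad) >= a + 1L) {
        ad_ref[r, s] <- ad[1]
        ad_alt[r, s] <- ad[a + 1L]
      }
    }
  }
  variant_table(variants, raw$samples, gt, ad_ref, ad_alt,
                dp = raw$dp[site_idx, , drop = FALSE],
                gq = raw$gq[site_idx, , drop = FALSE],
                other_alt = other_alt)
}

#' Write a variant table as VCF 4.2
#'
#' Emits one biallelic record per row with FORMAT `GT:AD:DP:GQ`; genotype
#' codes 0/1/2/NA map to `0/0`, `0/1`, `1/1`, `./.`.
#'
#' @param vt A `famseg_vtab`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(vt, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  filt <- ifelse(vt$variants$filter_status == "pass", "PASS",
                 ifelse(vt$variants$filter_status == "other", ".",
                        "VQSRTrancheSNP99.90to100.00"))
  n <- n_variants(vt)
  gt_chr <- matrix(gt_code[vt$gt + 1], n, length(vt$samples))
  gt_chr[is.na(vt$gt)] <- "./."
  fmt_num <- function(m, miss = ".") {
    out <- matrix(as.character(m), nrow(m), ncol(m))
    out[is.na(m)] <- miss
    out
  }
  ad_chr <- matrix(paste(fmt_num(vt$ad_ref), fmt_num(vt$ad_alt), sep = ","),
                   n, length(vt$samples))
  ad_chr[is.na(vt$ad_ref) & is.na(vt$ad_alt)] <- "."
  cells <- matrix(paste(gt_chr, ad_chr, fmt_num(vt$dp), fmt_num(vt$gq),
                        sep = ":"), n, length(vt$samples))
  body <- paste(vt$variants$chrom, vt$variants$pos, ".", vt$variants$ref,
                vt$variants$alt, ".", filt, ".", "GT:AD:DP:GQ",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=GRCh37",
    '##FILTER=<ID=PASS,Description="All filters passed">',
    '##FILTER=<ID=VQSRTrancheSNP99.90to100.00,Description="VQSR tranche failure">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read the per-variant annotation TSV
#'
#' Expected header: `chrom pos ref alt genes consequence splice_site
#' segdup af_<dbname>...`, tab-delimited.  `genes` is a comma-separated
#' list of overlapped gene symbols; allele frequencies are in `[0, 1]`
#' with `NA` meaning "not observed in that database".
#'
#' @param path Path to the TSV.
#' @return A data frame with `splice_site`/`segdup` as logicals.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", "."),
                           colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "ref", "alt", "genes", "consequence",
            "splice_site", "segdup")
  if (!all(need %in% names(ann))) {
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ann$splice_site <- as.logical(as.integer(ann$splice_site))
  ann$segdup <- as.logical(as.integer(ann$segdup))
  ann
}

#' Read the per-gene annotation TSV (RVIS percentile, brain expression)
#'
#' @param path Path to a TSV with header `gene rvis_percentile brain_nx`.
#' @return A data frame.
#' @export
read_gene_annotations <- function(path) {
  ga <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "rvis_percentile", "brain_nx")
  if (!all(need %in% names(ga))) {
    stop("gene TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ga
}

#' Read the in-house cohort detection-count TSV
#'
#' @param path Path to a TSV with header `chrom pos ref alt
#'   detection_count`.
#' @return A named integer vector of detection counts keyed by
#'   `chrom:pos:ref:alt`; variants absent from the table count 0.
#' @export
read_inhouse_counts <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  setNames(as.integer(x$detection_count),
           variant_key(x$chrom, x$pos, x$ref, x$alt))
}

#' Join variant and gene annotations onto a variant table
#'
#' Left join on the variant key `(chrom, pos, ref, alt)`.  Variants
#' without an annotation row are retained but flagged `annotated = FALSE`
#' and excluded from consequence/frequency/gene filtering downstream; the
#' count of such variants is reported via a message.
#'
#' @param vt A `famseg_vtab`.
#' @param ann Annotation data frame ([read_annotations()]).
#' @param gene_ann Gene annotation data frame ([read_gene_annotations()]).
#' @return `vt` with `$ann` (aligned to `$variants`) and `$gene_ann` set.
#' @export
join_annotations <- function(vt, ann, gene_ann) {
  akey <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(akey)) {
    stop("duplicate annotation key: ", akey[duplicated(akey)][1],
         call. = FALSE)
  }
  if (anyDuplicated(gene_ann$gene)) {
    stop("duplicate gene in gene annotation table", call. = FALSE)
  }
  idx <- match(vt$variants$key, akey)
  joined <- ann[ifelse(is.na(idx), 1L, idx),
                setdiff(names(ann), c("chrom", "pos", "ref", "alt")),
                drop = FALSE]
  joined[is.na(idx), ] <- NA
  joined$annotated <- !is.na(idx)
  rownames(joined) <- NULL
  n_un <- sum(!joined$annotated)
  if (n_un > 0) {
    message(sprintf("join_annotations: %d variant(s) lack annotation and are excluded from filtering", n_un))
  }
  vt$ann <- joined
  vt$gene_ann <- gene_ann
  vt
}

split_genes <- function(genes) {
  if (length(genes) == 0L) return(list())
  strsplit(ifelse(is.na(genes), "", as.character(genes)), ",", fixed = TRUE)
}
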