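test_that("a biallelic multi-sample VCF parses into records and calls", {
  path <- write_mini_vcf(c(
    vcf_row("1", 100, "A", "G", "PASS",
            c("0/1:20,18:38:99", "0/0:30,0:30:80", "1/1:0,25:25:60")),
    vcf_row("2", 200, "C", "T", "VQSRTrancheSNP99.90to100.00",
            c("./.:.:.:.", "0/1:10,10:20:50", "0/0:22,0:22:70"))))
  vt <- read_vcf(path)
  expect_equal(nrow(vt$variants), 2)
  expect_equal(vt$samples, c("S1", "S2", "S3"))
  expect_equal(unname(vt$gt[1, ]), c(1, 0, 2))
  expect_equal(unname(vt$ad_alt[1, ]), c(18, 0, 25))
  expect_equal(unname(vt$dp[2, ]), c(NA, 20, 22))
  expect_true(is.na(vt$gt[2, "S1"]))
  expect_equal(vt$variants$filter_status, c("pass", "fail"))
})

test_that("multiallelic sites split per allele with AD decomposition", {
  path <- write_mini_vcf(
    vcf_row("1", 500, "A", "C,T", "PASS",
            c("0/1:10,5,5:20:99",    # het for first alt
              "1/2:2,9,9:20:99",     # carries both alts
              "2/2:0,0,18:18:99")))  # hom for second alt
  vt <- read_vcf(path)
  expect_equal(nrow(vt$variants), 2)
  expect_equal(vt$variants$chrom, c("1", "1"))
  expect_equal(vt$variants$pos, c(500L, 500L))
  expect_equal(vt$variants$alt, c("C", "T"))
  # S1: het on the C record, other-alt homref on the T record
  expect_equal(unname(vt$gt[, "S1"]), c(1, 0))
  expect_equal(unname(vt$ad_ref[, "S1"]), c(10, 10))
  expect_equal(unname(vt$ad_alt[, "S1"]), c(5, 5))
  expect_false(vt$other_alt[1, "S1"])
  expect_true(vt$other_alt[2, "S1"])
  # S2 (1/2) is a carrier of neither allele under the strict definition
  expect_equal(unname(vt$gt[, "S2"]), c(0, 0))
  expect_true(all(vt$other_alt[, "S2"]))
  # S3 is hom for T, other-alt on the C record
  expect_equal(unname(vt$gt[, "S3"]), c(0, 2))
  expect_equal(unname(vt$ad_alt[, "S3"]), c(0, 18))
})

test_that("splitting preserves the multiset of sites", {
  path <- write_mini_vcf(c(
    vcf_row("1", 100, "A", "G", "PASS",
            rep("0/1:10,10:20:99", 3)),
    vcf_row("1", 500, "A", "C,T,G", "PASS",
            rep("0/1:10,5,3,2:20:99", 3))))
  vt <- read_vcf(path)
  site <- paste(vt$variants$chrom, vt$variants$pos, vt$variants$ref)
  expect_equal(sort(unique(site)), sort(c("1 100 A", "1 500 A")))
  expect_equal(as.vector(table(site)[c("1 100 A", "1 500 A")]), c(1L, 3L))
})

test_that("annotation join is lossless and flags unannotated variants", {
  path <- write_mini_vcf(c(
    vcf_row("X", 43662605, "C", "T", "PASS", rep("0/1:10,10:20:99", 3)),
    vcf_row("1", 999, "A", "G", "PASS", rep("0/0:20,0:20:99", 3))))
  vt <- read_vcf(path)
  ann <- data.frame(chrom = "X", pos = 43662605L, ref = "C", alt = "T",
                    genes = "MAOB", consequence = "nonsynonymous",
                    splice_site = 0L, segdup = 0L,
                    af_ExAC_ALL = 0.0004, af_ExAC_EAS = 0,
                    af_1000G_ALL = 0.00052, af_HGVD = 0.00042, af_jMorp = 0,
                    stringsAsFactors = FALSE)
  gene_ann <- data.frame(gene = "MAOB", rvis_percentile = 20, brain_nx = 2,
                         stringsAsFactors = FALSE)
  expect_message(vt2 <- join_annotations(vt, ann, gene_ann), "1 variant")
  expect_equal(sum(vt2$ann$annotated), 1)
  expect_equal(sum(!vt2$ann$annotated) + sum(vt2$ann$annotated),
               nrow(vt2$variants))
  maob <- vt2$ann[vt2$variants$key == "X:43662605:C:T", ]
  expect_equal(maob$af_ExAC_ALL, 0.0004)
  expect_equal(maob$af_1000G_ALL, 0.00052)
  expect_equal(maob$af_HGVD, 0.00042)
  expect_equal(maob$af_jMorp, 0)
  expect_equal(maob$genes, "MAOB")

  dup <- rbind(ann, ann)
  expect_error(join_annotations(vt, dup, gene_ann), "duplicate annotation")
})

test_that("VCF writing round-trips through the reader", {
  set.seed(42)
  n <- 30
  v <- data.frame(chrom = as.character(sample(1:22, n, TRUE)),
                  pos = sample.int(1e6, n), ref = "A", alt = "T",
                  filter_status = sample(c("pass", "fail"), n, TRUE),
                  stringsAsFactors = FALSE)
  v <- v[!duplicated(variant_key(v$chrom, v$pos, v$ref, v$alt)), ]
  n <- nrow(v)
  gt <- matrix(sample(c(0, 1, 2, NA), n * 3, TRUE), n, 3)
  dp <- matrix(sample(10:80, n * 3, TRUE), n, 3)
  ad_alt <- matrix(0, n, 3); ad_alt[gt %in% 1] <- 15; ad_alt[gt %in% 2] <- 40
  gq <- matrix(sample(20:99, n * 3, TRUE), n, 3)
  vt <- variant_table(v, c("S1", "S2", "S3"), gt, dp - ad_alt, ad_alt, dp, gq)
  path <- tempfile(fileext = ".vcf")
  write_vcf(vt, path)
  vt2 <- read_vcf(path)
  ord <- match(vt$variants$key, vt2$variants$key)
  expect_false(anyNA(ord))
  expect_equal(unname(vt2$gt[ord, ]), unname(vt$gt), ignore_attr = TRUE)
  expect_equal(unname(vt2$dp[ord, ]), unname(vt$dp), ignore_attr = TRUE)
  expect_equal(unname(vt2$gq[ord, ]), unname(vt$gq), ignore_attr = TRUE)
  expect_equal(unname(vt2$ad_alt[ord, ]), unname(vt$ad_alt),
               ignore_attr = TRUE)
  expect_equal(vt2$variants$filter_status[ord], vt$variants$filter_status)
})

test_that("duplicate variant keys are rejected", {
  v <- data.frame(chrom = c("1", "1"), pos = c(5L, 5L), ref = "A", alt = "G",
                  filter_status = "pass", stringsAsFactors = FALSE)
  m <- matrix(0, 2, 1)
  expect_error(variant_table(v, "S", m, m, m, m, m), "duplicate variant key")
})
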