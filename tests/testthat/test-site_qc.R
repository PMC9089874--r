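test_that("alternative allele ratio handles boundaries and degenerate depth", {
  expect_equal(alt_allele_ratio(30, 10), 0.25)
  expect_true(is.na(alt_allele_ratio(0, 0)))
  expect_equal(alt_allele_ratio(0, 42), 1)
  expect_true(is.na(alt_allele_ratio(NA, 10)))
})

test_that("genotype QC thresholds are inclusive and missing calls fail", {
  cfg <- qc_config()
  # depth below 10 fails regardless of quality and ratio
  expect_false(passes_genotype_qc(1, dp = 9, gq = 99, ad_ref = 10,
                                  ad_alt = 10, cfg))
  # exact boundaries pass: dp 10, gq 20, AAR 0.25
  expect_true(passes_genotype_qc(1, dp = 10, gq = 20, ad_ref = 30,
                                 ad_alt = 10, cfg))
  expect_false(passes_genotype_qc(NA, dp = 50, gq = 99, ad_ref = 20,
                                  ad_alt = 20, cfg))
  # homref passes the ratio check vacuously
  expect_true(passes_genotype_qc(0, dp = 30, gq = 50, ad_ref = 30,
                                 ad_alt = 0, cfg))
  # het below the ratio fails
  expect_false(passes_genotype_qc(1, dp = 40, gq = 99, ad_ref = 36,
                                  ad_alt = 4, cfg))
})

test_that("site QC requires VQSR pass and no segmental duplication", {
  cfg <- qc_config()
  expect_true(passes_site_qc("pass", FALSE, cfg))
  expect_false(passes_site_qc("fail", FALSE, cfg))
  expect_false(passes_site_qc("pass", TRUE, cfg))
  relaxed <- qc_config(require_vqsr_pass = FALSE, exclude_segdup = FALSE)
  expect_true(passes_site_qc("fail", TRUE, relaxed))
})

test_that("in-house exclusion triggers at 20 detections, absent keys kept", {
  counts <- c("1:10:A:G" = 20L, "1:20:A:G" = 19L)
  cfg <- qc_config()
  expect_true(inhouse_excluded("1:10:A:G", counts, cfg))
  expect_false(inhouse_excluded("1:20:A:G", counts, cfg))
  expect_false(inhouse_excluded("1:30:A:G", counts, cfg))
})

make_qc_table <- function(n = 30, ns = 4, seed = 1) {
  set.seed(seed)
  v <- data.frame(chrom = "1", pos = seq_len(n), ref = "A", alt = "G",
                  filter_status = sample(c("pass", "fail"), n, TRUE,
                                         prob = c(0.9, 0.1)),
                  stringsAsFactors = FALSE)
  gt <- matrix(sample(c(0, 1, 2, NA), n * ns, TRUE), n, ns)
  dp <- matrix(sample(5:60, n * ns, TRUE), n, ns)
  gq <- matrix(sample(10:99, n * ns, TRUE), n, ns)
  ad_alt <- matrix(sample(0:30, n * ns, TRUE), n, ns)
  ad_alt[gt %in% 0] <- 0
  variant_table(v, paste0("S", seq_len(ns)), gt,
                pmax(dp - ad_alt, 0), ad_alt, dp, gq)
}

test_that("genotype failures demote the call but keep the site", {
  v <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G",
                  filter_status = "pass", stringsAsFactors = FALSE)
  gt <- matrix(c(1, 1), 1, 2)
  dp <- matrix(c(5, 50), 1, 2)   # first call under-covered
  gq <- matrix(99, 1, 2)
  ad_alt <- matrix(c(2, 25), 1, 2)
  vt <- variant_table(v, c("A", "B"), gt, dp - ad_alt, ad_alt, dp, gq)
  out <- apply_qc(vt)
  expect_equal(nrow(out$variants), 1)
  expect_true(is.na(out$gt[1, "A"]))
  expect_equal(out$gt[1, "B"], 1)
  expect_equal(attr(out, "qc_report")$n_calls_demoted, 1)
})

test_that("apply_qc is idempotent and reports per-rule counts", {
  vt <- make_qc_table()
  out1 <- apply_qc(vt)
  out2 <- apply_qc(out1)
  expect_equal(out2$variants, out1$variants)
  expect_equal(out2$gt, out1$gt)
  expect_equal(attr(out2, "qc_report")$n_calls_demoted, 0)
  expect_equal(attr(out2, "qc_report")$n_fail_vqsr, 0)
  rep1 <- attr(out1, "qc_report")
  expect_equal(rep1$n_in - rep1$n_fail_vqsr - rep1$n_all_missing, rep1$n_out)
})

test_that("tightening any QC threshold only shrinks the surviving calls", {
  for (seed in 1:10) {
    vt <- make_qc_table(seed = seed)
    base <- apply_qc(vt)
    for (cfg in list(qc_config(min_dp = 30), qc_config(min_gq = 60),
                     qc_config(min_aar = 0.4))) {
      tight <- apply_qc(vt, cfg = cfg)
      # surviving (variant, sample) calls under the tight config are a
      # subset of those under the default
      calls_of <- function(x) {
        idx <- which(!is.na(x$gt), arr.ind = TRUE)
        paste(x$variants$key[idx[, 1]], x$samples[idx[, 2]])
      }
      expect_true(all(calls_of(tight) %in% calls_of(base)))
    }
  }
})
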