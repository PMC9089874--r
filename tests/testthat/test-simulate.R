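small_cfg <- function(seed = 1, ...) {
  sim_config(n_background_sites = 800, seed = seed, ...)
}

test_that("the same seed reproduces the bundle exactly", {
  b1 <- simulate_cohort(small_cfg(seed = 5))
  b2 <- simulate_cohort(small_cfg(seed = 5))
  expect_identical(b1, b2)
  b3 <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(b1$vt$gt, b3$vt$gt))
})

test_that("a background-only bundle yields empty candidate sets", {
  b <- simulate_cohort(sim_config(n_background_sites = 400, n_shared_het = 0,
                                  n_de_novo = 0, n_homozygous = 0,
                                  n_hemizygous = 0, decoys = FALSE, seed = 3))
  expect_equal(nrow(b$truth), 0)
  run <- run_pipeline(b, kinship = FALSE)
  expect_equal(nrow(run$candidates$all), 0)
  expect_equal(nrow(run$candidates$strict), 0)
  # and no site is dropped by QC on clean background data
  expect_equal(run$qc_report$n_fail_vqsr, 0)
  expect_equal(run$qc_report$n_fail_segdup, 0)
  expect_equal(run$qc_report$n_inhouse_excluded, 0)
})

test_that("clean-mode transmission is Mendelian outside planted de novo sites", {
  b <- simulate_cohort(small_cfg(seed = 9))
  ped <- b$ped
  gt <- b$vt$gt
  dn_keys <- b$truth$key[b$truth$class == "de_novo"]
  auto <- !famseg:::x_chrom(b$vt$variants$chrom)
  scan_rows <- which(auto & !(b$vt$variants$key %in% dn_keys))
  violations <- 0L
  for (i in seq_len(nrow(ped))) {
    kid <- ped$individual_id[i]
    fa <- ped$father_id[i]; mo <- ped$mother_id[i]
    if (is.na(fa) || is.na(mo)) next
    if (!all(c(kid, fa, mo) %in% colnames(gt))) next
    k <- gt[scan_rows, kid]; f <- gt[scan_rows, fa]; m <- gt[scan_rows, mo]
    # allele counts a child cannot receive from its parents
    bad <- (f == 0 & m == 0 & k > 0) | (f == 2 & m == 2 & k < 2) |
      ((f == 0 & m == 2) | (f == 2 & m == 0)) & k != 1 |
      (f == 0 | m == 0) & k == 2 | (f == 2 | m == 2) & k == 0
    violations <- violations + sum(bad, na.rm = TRUE)
  }
  expect_equal(violations, 0L)
})

test_that("founder genotypes are in Hardy-Weinberg proportions", {
  cfg <- sim_config(n_background_sites = 5000, n_shared_het = 0,
                    n_de_novo = 0, n_homozygous = 0, n_hemizygous = 0,
                    decoys = FALSE, seed = 13)
  b <- simulate_cohort(cfg)
  ped <- b$ped
  founders <- ped$individual_id[is.na(ped$father_id) & is.na(ped$mother_id) &
                                ped$sequenced]
  expect_gt(length(founders), 2)
  gt <- b$vt$gt[, founders, drop = FALSE]
  af <- b$ann[[famseg:::af_column("1000G_ALL")]]
  # pooled heterozygote count vs binomial expectation under HWE
  p_het <- 2 * af * (1 - af)
  expected <- sum(p_het) * length(founders)
  variance <- sum(p_het * (1 - p_het)) * length(founders)
  observed <- sum(gt == 1)
  expect_lt(abs(observed - expected), 3 * sqrt(variance))
  # and alt-allele dosage matches the annotated frequency
  exp_alt <- sum(2 * af) * length(founders)
  var_alt <- sum(2 * af * (1 - af)) * length(founders)
  expect_lt(abs(sum(gt) - exp_alt), 4 * sqrt(var_alt))
})

test_that("bundles round-trip through the pipeline's own readers", {
  b <- simulate_cohort(small_cfg(seed = 4))
  dir <- tempfile("bundle")
  expect_no_warning(write_bundle(b, dir))
  expect_no_warning(b2 <- read_bundle(dir))
  expect_equal(b2$ped$individual_id, b$ped$individual_id)
  expect_equal(b2$ped$sequenced, b$ped$sequenced)
  expect_equal(b2$ped$consanguineous, b$ped$consanguineous)
  ord <- match(b$vt$variants$key, b2$vt$variants$key)
  expect_false(anyNA(ord))
  expect_equal(unname(b2$vt$gt[ord, b$vt$samples]), unname(b$vt$gt))
  expect_equal(unname(b2$vt$dp[ord, b$vt$samples]), unname(b$vt$dp))
  expect_equal(b2$truth$key, b$truth$key)
  expect_equal(length(b2$gmt), length(b$gmt))
  # the two routes agree end to end
  r1 <- run_pipeline(b, kinship = FALSE)
  r2 <- run_pipeline(b2, kinship = FALSE)
  key_fam <- function(x) sort(paste(x$key, x$family_id, x$seg_class))
  expect_equal(key_fam(r2$candidates$all), key_fam(r1$candidates$all))
  expect_equal(key_fam(r2$candidates$strict), key_fam(r1$candidates$strict))
})

test_that("noise at rate zero is the identity; ledger matches perturbations", {
  b <- simulate_cohort(small_cfg(seed = 8))
  b0 <- add_genotype_noise(b, 0)
  expect_equal(b0$vt, b$vt)
  expect_equal(nrow(b0$noise_ledger), 0)
  bn <- add_genotype_noise(b, 0.02, seed = 77)
  led <- bn$noise_ledger
  expect_gt(nrow(led), 0)
  # every ledger entry corresponds to an actually changed call
  for (i in sample(nrow(led), min(30, nrow(led)))) {
    r <- match(led$key[i], b$vt$variants$key)
    s <- match(led$sample[i], b$vt$samples)
    changed <- !identical(b$vt$gt[r, s], bn$vt$gt[r, s]) ||
      !identical(b$vt$dp[r, s], bn$vt$dp[r, s]) ||
      !identical(b$vt$gq[r, s], bn$vt$gq[r, s])
    expect_true(changed)
  }
  # and every changed genotype call is in the ledger
  diff_idx <- which((b$vt$gt != bn$vt$gt) | (b$vt$dp != bn$vt$dp) |
                    (b$vt$gq != bn$vt$gq), arr.ind = TRUE)
  keys <- paste(b$vt$variants$key[diff_idx[, 1]],
                b$vt$samples[diff_idx[, 2]])
  expect_true(all(keys %in% paste(led$key, led$sample)))
})

test_that("impossible planting configurations raise config errors", {
  # a cohort of sibships with unsequenced parents cannot host de novo
  ped <- sibship_ped()
  expect_error(simulate_cohort(sim_config(n_background_sites = 10,
                                          n_de_novo = 1, n_shared_het = 0,
                                          n_homozygous = 0, n_hemizygous = 0,
                                          decoys = FALSE), ped = ped),
               "config error")
  # no affected male: hemizygous planting impossible
  ped2 <- sibship_ped(sexes = c("female", "female"))
  expect_error(simulate_cohort(sim_config(n_background_sites = 10,
                                          n_de_novo = 0, n_shared_het = 0,
                                          n_homozygous = 0, n_hemizygous = 1,
                                          decoys = FALSE), ped = ped2),
               "affected male")
})
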