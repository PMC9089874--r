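test_that("genotype states recode male X hemizygosity outside the PAR", {
  # published hemizygous position, male hom-alt coded diploid
  expect_equal(genotype_state(2, "male", "X", 43662605), "hemi_alt")
  expect_equal(genotype_state(1, "male", "X", 43662605), "hemi_alt")
  expect_equal(genotype_state(0, "male", "X", 43662605), "homref")
  expect_equal(genotype_state(1, "female", "X", 43662605), "het")
  # PAR1 is autosomal-like
  expect_equal(genotype_state(1, "male", "X", 100000), "het")
  expect_equal(genotype_state(1, "male", "X", 155000000), "het")
  expect_equal(genotype_state(1, "male", "7", 100), "het")
  expect_true(is.na(genotype_state(NA, "male", "X", 43662605)) ||
              genotype_state(NA, "male", "X", 43662605) == "missing")
  expect_warning(s <- genotype_state(1, "unknown", "X", 43662605),
                 "unknown sex")
  expect_equal(s, "missing")
})

test_that("sharing requires two carriers and full affected concordance", {
  p <- sibship_ped()
  st <- function(s1, s2, u1) c(S1 = s1, S2 = s2, U1 = u1)
  expect_true(shared_among_affected(st("het", "het", "homref"), p,
                                    strict = TRUE))
  # control carrier blocks strict but not lenient sharing
  expect_false(shared_among_affected(st("het", "het", "het"), p,
                                     strict = TRUE))
  expect_true(shared_among_affected(st("het", "het", "het"), p,
                                    strict = FALSE))
  # a single carrier is never enough
  expect_false(shared_among_affected(st("het", "homref", "homref"), p))
  # all-affected rule vs min2 relaxation needs a third affected member
  p3 <- sibship_ped(sexes = c("male", "female"))
  p3 <- rbind(p3, p3[3, ])
  p3$individual_id[6] <- "S3"
  class(p3) <- c("famseg_ped", "data.frame")
  st3 <- c(S1 = "het", S2 = "het", S3 = "homref", U1 = "homref")
  expect_false(shared_among_affected(st3, p3, mode = "all"))
  expect_true(shared_among_affected(st3, p3, mode = "min2"))
  # a missing affected call does not break the all-affected rule
  expect_true(shared_among_affected(st("het", "het", "homref")[
    c("S1", "S2")], p))
})

test_that("de novo needs carrier child and confident homref unaffected parents", {
  p <- trio_ped()
  expect_true(is_de_novo(c(FA = "homref", MO = "homref", KID = "het"), p))
  expect_false(is_de_novo(c(FA = "het", MO = "homref", KID = "het"), p))
  # missing parent call blocks the assignment (conservative)
  expect_false(is_de_novo(c(FA = "missing", MO = "homref", KID = "het"), p))
  # affected parent disqualifies the trio regardless of genotypes
  p_aff <- trio_ped(father_aff = "affected")
  expect_false(is_de_novo(c(FA = "homref", MO = "homref", KID = "het"),
                          p_aff))
  # unsequenced parents cannot anchor a de novo call
  p_unseq <- trio_ped()
  p_unseq$sequenced[1:2] <- FALSE
  expect_false(is_de_novo(c(KID = "het"), p_unseq))
})

test_that("recessive homozygous needs hom-alt affecteds and no hom-alt control", {
  p <- sibship_ped()
  st <- function(s1, s2, u1) c(S1 = s1, S2 = s2, U1 = u1)
  expect_true(is_recessive_homozygous(st("homalt", "homalt", "het"), p))
  expect_false(is_recessive_homozygous(st("homalt", "het", "homref"), p))
  expect_false(is_recessive_homozygous(st("homalt", "homalt", "homalt"), p))
})

test_that("hemizygous requires concordant affected males and carrier females", {
  # family shaped like the published X-linked case: two affected sons,
  # affected carrier mother, unaffected father
  ped <- data.frame(
    family_id = "H", individual_id = c("FA", "MO", "S1", "S2"),
    father_id = c(NA, NA, "FA", "FA"), mother_id = c(NA, NA, "MO", "MO"),
    sex = c("male", "female", "male", "male"),
    affection = c("unaffected", "affected", "affected", "affected"),
    sequenced = TRUE, consanguineous = FALSE, diagnosis = NA,
    stringsAsFactors = FALSE)
  class(ped) <- c("famseg_ped", "data.frame")
  st <- function(fa, mo, s1, s2) c(FA = fa, MO = mo, S1 = s1, S2 = s2)
  expect_true(is_hemizygous_candidate(st("homref", "het", "hemi_alt",
                                         "hemi_alt"), ped))
  expect_false(is_hemizygous_candidate(st("homref", "het", "hemi_alt",
                                          "homref"), ped))
  expect_false(is_hemizygous_candidate(st("hemi_alt", "het", "hemi_alt",
                                          "hemi_alt"), ped))
  # affected female must be a het carrier
  expect_false(is_hemizygous_candidate(st("homref", "homref", "hemi_alt",
                                          "hemi_alt"), ped))
})

test_that("classification precedence resolves multi-class hits", {
  ped <- data.frame(
    family_id = "H", individual_id = c("FA", "MO", "S1", "S2"),
    father_id = c(NA, NA, "FA", "FA"), mother_id = c(NA, NA, "MO", "MO"),
    sex = c("male", "female", "male", "male"),
    affection = c("unaffected", "affected", "affected", "affected"),
    sequenced = TRUE, consanguineous = FALSE, diagnosis = NA,
    stringsAsFactors = FALSE)
  class(ped) <- c("famseg_ped", "data.frame")
  # X variant satisfying both hemizygous and shared rules -> hemizygous
  st <- c(FA = "homref", MO = "het", S1 = "hemi_alt", S2 = "hemi_alt")
  cls <- classify_variant(st, ped, "X", 43662605)
  expect_equal(cls$seg_class, "hemizygous_x")
  expect_setequal(cls$carriers, c("MO", "S1", "S2"))
  # autosomal shared het
  p <- sibship_ped()
  cls2 <- classify_variant(c(S1 = "het", S2 = "het", U1 = "homref"), p,
                           "5", 100)
  expect_equal(cls2$seg_class, "shared_het")
  expect_setequal(cls2$carriers, c("S1", "S2"))
  # variant carried only by a control classifies as nothing
  expect_null(classify_variant(c(S1 = "homref", S2 = "homref", U1 = "het"),
                               p, "5", 100))
  # homozygous beats shared
  cls3 <- classify_variant(c(S1 = "homalt", S2 = "homalt", U1 = "homref"),
                           p, "5", 100)
  expect_equal(cls3$seg_class, "homozygous_recessive")
})

test_that("candidate summaries deduplicate variants and union genes", {
  empty <- summarize_candidates(famseg:::empty_candidates())
  expect_equal(empty$n_variants, 0)
  expect_equal(empty$n_genes, 0)
  # the 15 published loss-of-function candidates: 15 variants in 15 genes
  t1 <- summarize_candidates(table1_fixture())
  expect_equal(t1$n_variants, 15)
  expect_equal(t1$n_genes, 15)
  expect_true(all(c("SLC9A8", "ZNF205", "RFWD3") %in% t1$genes))
  # two candidates in the same gene count once; a variant seen in two
  # families counts once
  cand <- rbind(
    data.frame(family_id = c("A", "B"), chrom = "1", pos = 10L, ref = "A",
               alt = "G", key = "1:10:A:G", genes = "GENE1",
               seg_class = "shared_het", carriers = "",
               stringsAsFactors = FALSE),
    data.frame(family_id = "A", chrom = "1", pos = 99L, ref = "A",
               alt = "G", key = "1:99:A:G", genes = "GENE1",
               seg_class = "de_novo", carriers = "", stringsAsFactors = FALSE))
  s <- summarize_candidates(cand)
  expect_equal(s$n_variants, 2)
  expect_equal(s$n_genes, 1)
  expect_equal(as.integer(s$per_class["shared_het"]), 2L)
})

test_that("the strict set is contained in the all set on control families", {
  b <- simulate_cohort(sim_config(n_background_sites = 500, seed = 21))
  vt <- join_annotations(b$vt, b$ann, b$gene_ann)
  vtq <- apply_qc(vt, famseg:::as_inhouse_counts(b$inhouse))
  sets <- build_candidate_sets(apply_rare_filters(vtq), b$ped)
  key_fam <- function(x) paste(x$key, x$family_id)
  expect_true(all(key_fam(sets$strict) %in% key_fam(sets$all)))
  ctl_fams <- c("F01", "F04", "F05", "F10", "F11", "F13", "F14")
  expect_true(all(sets$strict$family_id %in% ctl_fams))
})
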