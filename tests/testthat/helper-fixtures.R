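# Shared test fixtures, built in code.

# A minimal VCF written line-by-line (independent of write_vcf) so the
# parser is tested against externally-authored text.
mini_vcf_lines <- function(body) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    body)
}

write_mini_vcf <- function(body) {
  path <- tempfile(fileext = ".vcf")
  writeLines(mini_vcf_lines(body), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, filter, calls) {
  paste(c(chrom, pos, ".", ref, alt, ".", filter, ".", "GT:AD:DP:GQ", calls),
        collapse = "\t")
}

# a simple trio pedigree: sequenced unaffected parents, one affected child
trio_ped <- function(child_sex = "male", father_aff = "unaffected",
                     mother_aff = "unaffected") {
  ped <- data.frame(
    family_id = "T1",
    individual_id = c("FA", "MO", "KID"),
    father_id = c(NA, NA, "FA"),
    mother_id = c(NA, NA, "MO"),
    sex = c("male", "female", child_sex),
    affection = c(father_aff, mother_aff, "affected"),
    sequenced = TRUE, consanguineous = FALSE, diagnosis = NA_character_,
    stringsAsFactors = FALSE)
  class(ped) <- c("famseg_ped", "data.frame")
  ped
}

# a sibship with two affected children, one unaffected sequenced sib,
# unsequenced parents
sibship_ped <- function(sexes = c("male", "female"), ctl = TRUE) {
  ids <- c("FA", "MO", "S1", "S2", if (ctl) "U1")
  ped <- data.frame(
    family_id = "S1F",
    individual_id = ids,
    father_id = c(NA, NA, "FA", "FA", if (ctl) "FA"),
    mother_id = c(NA, NA, "MO", "MO", if (ctl) "MO"),
    sex = c("male", "female", sexes, if (ctl) "female"),
    affection = c("unaffected", "unaffected", "affected", "affected",
                  if (ctl) "unaffected"),
    sequenced = c(FALSE, FALSE, TRUE, TRUE, if (ctl) TRUE),
    consanguineous = FALSE, diagnosis = NA_character_,
    stringsAsFactors = FALSE)
  class(ped) <- c("famseg_ped", "data.frame")
  ped
}

# random annotated variant table for filter-algebra properties
random_ann_table <- function(n = 40) {
  ann <- data.frame(
    chrom = as.character(sample(1:22, n, TRUE)),
    pos = sample.int(1e6, n),
    ref = "A", alt = "G",
    genes = sample(c("G1", "G2", "G3", "G4", "G1,G2"), n, TRUE),
    consequence = sample(c("nonsynonymous", "synonymous", "stopgain",
                           "other", "splicing"), n, TRUE),
    splice_site = sample(0:1, n, TRUE),
    segdup = 0L,
    af_DB1 = round(stats::runif(n, 0, 0.05), 4),
    af_DB2 = ifelse(stats::runif(n) < 0.3, NA,
                    round(stats::runif(n, 0, 0.05), 4)),
    stringsAsFactors = FALSE)
  ann <- ann[!duplicated(variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)), ]
  n <- nrow(ann)
  v <- ann[, c("chrom", "pos", "ref", "alt")]
  v$filter_status <- "pass"
  gt <- matrix(sample(c(0, 1, 2, NA), n * 2, TRUE), n, 2)
  dp <- matrix(50, n, 2); gq <- matrix(90, n, 2)
  ad_alt <- matrix(20, n, 2)
  vt <- variant_table(v, c("A1", "A2"), gt, dp - ad_alt, ad_alt, dp, gq)
  gene_ann <- data.frame(gene = c("G1", "G2", "G3", "G4"),
                         rvis_percentile = c(10, 30, 20, 80),
                         brain_nx = c(2, 3, 0.5, 4),
                         stringsAsFactors = FALSE)
  join_annotations(vt, ann, gene_ann)
}

# genotype simulation oracles for kinship calibration, independent of the
# package's cohort simulator: site-wise HWE founders and single-allele
# Mendelian transmission
sim_pair <- function(n, relation = c("parent_offspring", "full_sib",
                                     "unrelated", "identical")) {
  relation <- match.arg(relation)
  p <- stats::runif(n, 0.05, 0.5)
  draw <- function() stats::rbinom(n, 1, p) + stats::rbinom(n, 1, p)
  transmit <- function(g) stats::rbinom(n, 1, g / 2)
  switch(relation,
    identical = { g <- draw(); list(g, g) },
    unrelated = list(draw(), draw()),
    parent_offspring = {
      g1 <- draw()
      list(g1, transmit(g1) + stats::rbinom(n, 1, p))
    },
    full_sib = {
      gf <- draw(); gm <- draw()
      list(transmit(gf) + transmit(gm), transmit(gf) + transmit(gm))
    })
}
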