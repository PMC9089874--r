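#' Hand-built mini-cohort of the seven published homozygous/hemizygous
#' and de novo variants
#'
#' A three-family bundle encoding the printed de novo (CACNA1C, PODNL1,
#' DLL3, ODC1, SAPCD2), recessive homozygous (CNTN6, in the
#' consanguineous family) and X-linked hemizygous (MAOB, affected
#' brothers with a heterozygous carrier mother) candidate variants at
#' their published GRCh37 positions and with their published database
#' allele frequencies.  Pedigrees are shaped so each variant realizes its
#' published class: the affected mother's own parents are included as
#' sequenced unaffected members so her de novo variants are assignable,
#' with the grandmother carrying the X variant so it segregates as
#' hemizygous rather than de novo.  REF/ALT alleles and read depths are
#' synthetic (the published table reports cDNA changes, not VCF alleles).
#'
#' @return A `famseg_bundle` whose truth table lists the seven variants
#'   with their expected classes.
#' @export
table2_fixture <- function() {
  rows <- list(
    # family, id, father, mother, sex, affection, sequenced, diagnosis
    list("P4", "P4_FA", NA, NA, "male", "unaffected", TRUE, NA),
    list("P4", "P4_MO", NA, NA, "female", "unaffected", TRUE, NA),
    list("P4", "N0674", "P4_FA", "P4_MO", "female", "affected", TRUE, "SCZ"),
    list("P4", "N0673", "P4_FA", "P4_MO", "male", "affected", TRUE, "SCZ"),
    list("P10", "P10_FA", NA, NA, "male", "unaffected", TRUE, NA),
    list("P10", "P10_MO", NA, NA, "female", "unaffected", TRUE, NA),
    list("P10", "N0688", "P10_FA", "P10_MO", "male", "affected", TRUE, "SCZ"),
    list("P10", "N0689", "P10_FA", "P10_MO", "female", "affected", TRUE, "SCZ"),
    list("P13", "P13_GF", NA, NA, "male", "unaffected", TRUE, NA),
    list("P13", "P13_GM", NA, NA, "female", "unaffected", TRUE, NA),
    list("P13", "P13_FA", NA, NA, "male", "unaffected", TRUE, NA),
    list("P13", "N1010", "P13_GF", "P13_GM", "female", "affected", TRUE, "OCD"),
    list("P13", "N0812", "P13_FA", "N1010", "male", "affected", TRUE, "SCZ"),
    list("P13", "N0813", "P13_FA", "N1010", "male", "affected", TRUE, "SCZ"))
  ped <- do.call(rbind, lapply(rows, function(r) {
    data.frame(family_id = r[[1]], individual_id = r[[2]],
               father_id = if (is.na(r[[3]])) NA_character_ else r[[3]],
               mother_id = if (is.na(r[[4]])) NA_character_ else r[[4]],
               sex = r[[5]], affection = r[[6]], sequenced = r[[7]],
               consanguineous = FALSE, diagnosis = r[[8]],
               stringsAsFactors = FALSE)
  }))
  ped$consanguineous <- ped$family_id == "P10"
  validate_ped(ped)
  class(ped) <- c("famseg_ped", "data.frame")
  samples <- ped$individual_id

  v <- data.frame(
    chrom = c("12", "19", "19", "2", "9", "3", "X"),
    pos = c(2224447L, 14046846L, 39993536L, 10582149L, 139964552L,
            1363404L, 43662605L),
    ref = c("C", "G", "G", "C", "CAGG", "T", "C"),
    alt = c("T", "A", "T", "T", "C", "G", "T"),
    filter_status = "pass", stringsAsFactors = FALSE)
  genes <- c("CACNA1C", "PODNL1", "DLL3", "ODC1", "SAPCD2", "CNTN6", "MAOB")
  consequence <- c("nonsynonymous", "nonsynonymous", "nonsynonymous",
                   "nonsynonymous", "inframe_indel", "nonsynonymous",
                   "nonsynonymous")
  class <- c("de_novo", "de_novo", "de_novo", "de_novo", "de_novo",
             "homozygous_recessive", "hemizygous_x")
  family <- c("P4", "P4", "P4", "P13", "P13", "P10", "P13")

  gt <- matrix(0, 7, length(samples), dimnames = list(NULL, samples))
  gt[1, "N0674"] <- 1                      # CACNA1C de novo
  gt[2, "N0674"] <- 1                      # PODNL1 de novo
  gt[3, "N0673"] <- 1                      # DLL3 de novo
  gt[4, "N1010"] <- 1                      # ODC1 de novo in the mother
  gt[5, "N1010"] <- 1                      # SAPCD2 de novo in the mother
  gt[6, c("N0688", "N0689")] <- 2          # CNTN6 homozygous sibs
  gt[6, c("P10_FA", "P10_MO")] <- 1        # carrier first-cousin parents
  gt[7, c("N0812", "N0813")] <- 2          # MAOB hemizygous brothers
  gt[7, c("N1010", "P13_GM")] <- 1         # het mother; het grandmother

  dp <- matrix(60, 7, length(samples))
  gq <- matrix(99, 7, length(samples))
  ad_alt <- matrix(0, 7, length(samples))
  ad_alt[gt == 1] <- 30
  ad_alt[gt == 2] <- 60
  vt <- variant_table(v, samples, gt, dp - ad_alt, ad_alt, dp, gq)

  # published MAFs: ExAC_ALL ExAC_EAS 1000G_ALL HGVD jMorp
  maf <- rbind(
    c(0, 0, 0, 0, 0),                                  # CACNA1C
    c(0, 0, 0, 0, 0),                                  # PODNL1
    c(0, 0, 0, 0, 0),                                  # DLL3
    c(0.000022, 0.0002, 0, 0, 0),                      # ODC1
    c(0, 0, 0, 0, 0),                                  # SAPCD2
    c(0.000011, 0.0002, 0, 0.0016, 0.002),             # CNTN6
    c(0.0004, 0, 0.00052, 0.00042, 0))                 # MAOB
  ann <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                    genes = genes, consequence = consequence,
                    splice_site = 0L, segdup = 0L,
                    af_ExAC_ALL = maf[, 1], af_ExAC_EAS = maf[, 2],
                    af_1000G_ALL = maf[, 3], af_HGVD = maf[, 4],
                    af_jMorp = maf[, 5], stringsAsFactors = FALSE)
  gene_ann <- data.frame(gene = genes, rvis_percentile = 10, brain_nx = 3,
                         stringsAsFactors = FALSE)
  truth <- data.frame(
    key = variant_key(v$chrom, v$pos, v$ref, v$alt),
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    family_id = family, class = class, fate = "pass",
    in_all = TRUE, in_strict = TRUE, stringsAsFactors = FALSE)
  inhouse <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        detection_count = integer(), stringsAsFactors = FALSE)
  structure(list(ped = ped, vt = vt, ann = ann, gene_ann = gene_ann,
                 inhouse = inhouse, gmt = list(), truth = truth,
                 config = list(fixture = "table2")),
            class = "famseg_bundle")
}

#' Candidate-set fixture of the fifteen published loss-of-function
#' variants
#'
#' The published loss-of-function candidates (one per gene, across eight
#' pedigrees) as an already-classified candidate data frame, for
#' exercising the candidate-set summary arithmetic.  REF/ALT alleles are
#' synthetic placeholders consistent with each variant's functional class.
#'
#' @return A candidate data frame in the layout of
#'   [build_candidate_sets()] with 15 rows.
#' @export
table1_fixture <- function() {
  v <- list(
    list("1",  "20", 48479568L, "CA", "C",  "SLC9A8"),
    list("3",  "19", 56000877L, "C", "CG",  "SSC5D"),
    list("6",  "10", 26785321L, "G", "C",   "APBB1IP"),
    list("7",  "19", 33167791L, "GAAGGTCCTGGGCCCCGGGCCCG", "G", "RGS9BP"),
    list("8",  "1",  60306057L, "CT", "C",  "HOOK1"),
    list("8",  "16", 3165404L,  "G", "T",   "ZNF205"),
    list("9",  "2",  84932821L, "C", "T",   "DNAH6"),
    list("10", "2",  80085187L, "C", "A",   "CTNNA2"),
    list("10", "18", 6898571L,  "T", "C",   "ARHGAP28"),
    list("10", "7",  12384097L, "C", "CT",  "VWDE"),
    list("11", "17", 18150343L, "G", "A",   "FLII"),
    list("11", "19", 33134477L, "G", "A",   "ANKRD27"),
    list("14", "4",  186357227L, "A", "AAT", "C4orf47"),
    list("14", "8",  29043913L, "CTT", "C", "KIF13B"),
    list("14", "16", 74694876L, "CGTGGTGGT", "C", "RFWD3"))
  do.call(rbind, lapply(v, function(r) {
    data.frame(family_id = r[[1]], chrom = r[[2]], pos = r[[3]],
               ref = r[[4]], alt = r[[5]],
               key = variant_key(r[[2]], r[[3]], r[[4]], r[[5]]),
               genes = r[[6]], seg_class = "shared_het", carriers = "",
               stringsAsFactors = FALSE)
  }))
}
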