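#' The default 14-family multiplex cohort pedigree
#'
#' A fixed cohort structure emulating a multiplex-family exome study:
#' 14 families, 39 sequenced members of whom 30 are affected (29 with the
#' primary diagnosis and one with OCD, the affected mother of family 13)
#' and 9 are unaffected within-family controls.  Exactly seven families
#' (1, 4, 5, 10, 11, 13 and 14) contain sequenced controls.  Family 4 is
#' a quartet with both parents sequenced and unaffected (the de novo
#' configuration); family 10 is consanguineous (the sequenced parents are
#' first cousins, so their affected children are inbred and eligible for
#' recessive homozygous candidates); family 13 carries an affected mother
#' and two affected sons (the X-linked hemizygous configuration).
#' Remaining families are affected sibships with unsequenced parents.
#'
#' @return A `famseg_ped` data frame (sequenced flags, consanguinity and
#'   diagnoses filled in).
#' @export
cohort_pedigree <- function() {
  rows <- list()
  add <- function(fam, id, fa, mo, sex, aff, seq, diag = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family_id = fam, individual_id = paste0(fam, "_", id),
      father_id = if (is.na(fa)) NA_character_ else paste0(fam, "_", fa),
      mother_id = if (is.na(mo)) NA_character_ else paste0(fam, "_", mo),
      sex = sex, affection = aff, sequenced = seq,
      consanguineous = FALSE, diagnosis = diag, stringsAsFactors = FALSE)
  }
  sibship <- function(fam, aff_sexes, n_ctl_sibs = 0L) {
    add(fam, "FA", NA, NA, "male", "unaffected", FALSE)
    add(fam, "MO", NA, NA, "female", "unaffected", FALSE)
    for (i in seq_along(aff_sexes)) {
      add(fam, paste0("S", i), "FA", "MO", aff_sexes[i], "affected", TRUE, "SCZ")
    }
    for (i in seq_len(n_ctl_sibs)) {
      add(fam, paste0("U", i), "FA", "MO",
          if (i %% 2) "female" else "male", "unaffected", TRUE)
    }
  }
  sibship("F01", c("male", "female"), 1L)
  sibship("F02", c("male", "female", "male"))
  sibship("F03", c("female", "male"))
  # F04: quartet, both parents sequenced and unaffected
  add("F04", "FA", NA, NA, "male", "unaffected", TRUE)
  add("F04", "MO", NA, NA, "female", "unaffected", TRUE)
  add("F04", "S1", "FA", "MO", "female", "affected", TRUE, "SCZ")
  add("F04", "S2", "FA", "MO", "male", "affected", TRUE, "SCZ")
  sibship("F05", c("male", "female"), 1L)
  sibship("F06", c("male", "female"))
  sibship("F07", c("female", "male"))
  sibship("F08", c("male", "male"))
  sibship("F09", c("female", "female"))
  # F10: consanguineous; sequenced parents are first cousins
  add("F10", "GGF", NA, NA, "male", "unaffected", FALSE)
  add("F10", "GGM", NA, NA, "female", "unaffected", FALSE)
  add("F10", "U1",  "GGF", "GGM", "male", "unaffected", FALSE)
  add("F10", "U1W", NA, NA, "female", "unaffected", FALSE)
  add("F10", "U2",  "GGF", "GGM", "female", "unaffected", FALSE)
  add("F10", "U2H", NA, NA, "male", "unaffected", FALSE)
  add("F10", "FA",  "U1", "U1W", "male", "unaffected", TRUE)
  add("F10", "MO",  "U2H", "U2", "female", "unaffected", TRUE)
  add("F10", "S1",  "FA", "MO", "male", "affected", TRUE, "SCZ")
  add("F10", "S2",  "FA", "MO", "female", "affected", TRUE, "SCZ")
  sibship("F11", c("male", "female"), 1L)
  sibship("F12", c("male", "female"))
  # F13: affected mother (OCD) and two affected sons; father is the control
  add("F13", "FA", NA, NA, "male", "unaffected", TRUE)
  add("F13", "MO", NA, NA, "female", "affected", TRUE, "OCD")
  add("F13", "S1", "FA", "MO", "male", "affected", TRUE, "SCZ")
  add("F13", "S2", "FA", "MO", "male", "affected", TRUE, "SCZ")
  sibship("F14", c("female", "male"), 1L)

  ped <- do.call(rbind, rows)
  ped$consanguineous <- ped$family_id == "F10"
  validate_ped(ped)
  class(ped) <- c("famseg_ped", "data.frame")
  ped
}

#' Simulation configuration
#'
#' @param n_background_sites Number of independent autosomal background
#'   sites (default 20,000), drawn with allele frequencies uniform on
#'   `maf_range` and transmitted by Mendelian segregation; these anchor
#'   the kinship estimates and are too common to pass the rarity filter.
#' @param maf_range Allele-frequency range of background sites.
#' @param n_shared_het,n_de_novo,n_homozygous,n_hemizygous Planted
#'   candidate counts per segregation class.
#' @param decoys Plant one decoy per filter rule (common frequency,
#'   non-splice synonymous consequence, tolerant gene, non-brain gene,
#'   segmental duplication, VQSR failure, low depth, in-house common)?
#' @param depth_mu,depth_size Mean and size of the negative-binomial read
#'   depth distribution at background sites (overdispersed, so
#'   allele-ratio boundary cases arise naturally).
#' @param genotype_error_rate Per-call perturbation rate applied by
#'   [add_genotype_noise()] when the cohort is simulated in noise mode
#'   (default 0: clean mode).
#' @param seed Integer seed; the entire bundle is byte-reproducible given
#'   the seed.
#' @return A list of class `famseg_sim_config`.
#' @export
sim_config <- function(n_background_sites = 20000,
                       maf_range = c(0.05, 0.5),
                       n_shared_het = 8, n_de_novo = 3, n_homozygous = 1,
                       n_hemizygous = 1, decoys = TRUE,
                       depth_mu = 60, depth_size = 8,
                       genotype_error_rate = 0, seed = 1) {
  stopifnot(n_background_sites >= 0, n_shared_het >= 0, n_de_novo >= 0,
            n_homozygous >= 0, n_hemizygous >= 0,
            genotype_error_rate >= 0, genotype_error_rate <= 1)
  structure(list(n_background_sites = n_background_sites,
                 maf_range = maf_range, n_shared_het = n_shared_het,
                 n_de_novo = n_de_novo, n_homozygous = n_homozygous,
                 n_hemizygous = n_hemizygous, decoys = decoys,
                 depth_mu = depth_mu, depth_size = depth_size,
                 genotype_error_rate = genotype_error_rate, seed = seed),
            class = "famseg_sim_config")
}

# Mendelian genotype simulation for every pedigree member (columns), one
# independent biallelic site per row.  Founders are drawn from the site
# allele frequency; each non-founder receives one allele from each parent
# with probability gt/2.
sim_genotypes <- function(ped, maf) {
  n <- length(maf)
  ids <- ped$individual_id
  G <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  done <- rep(FALSE, length(ids))
  while (!all(done)) {
    ready <- which(!done & vapply(seq_along(ids), function(i) {
      (is.na(fa[i]) || done[fa[i]]) && (is.na(mo[i]) || done[mo[i]])
    }, logical(1)))
    if (length(ready) == 0L) stop("pedigree loop: cannot order members")
    for (i in ready) {
      if (is.na(fa[i]) && is.na(mo[i])) {
        G[, i] <- stats::rbinom(n, 1, maf) + stats::rbinom(n, 1, maf)
      } else {
        gf <- if (is.na(fa[i])) stats::rbinom(n, 1, maf)
              else stats::rbinom(n, 1, G[, fa[i]] / 2)
        gm <- if (is.na(mo[i])) stats::rbinom(n, 1, maf)
              else stats::rbinom(n, 1, G[, mo[i]] / 2)
        G[, i] <- gf + gm
      }
      done[i] <- TRUE
    }
  }
  G
}

rand_ref_alt <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

# het the maternal ancestor line of `ids` so a planted allele has a
# Mendelian-consistent transmission path down to its carriers
het_maternal_line <- function(G, p, ids) {
  mo <- stats::setNames(p$mother_id, p$individual_id)
  for (id in ids) {
    m <- mo[[id]]
    while (!is.na(m)) {
      G[m] <- max(G[m], 1)
      m <- mo[[m]]
    }
  }
  G
}

plant_shared_style <- function(G, ped, fam, carrier_kids = NULL) {
  # affected children het with a het carrier line through their mothers;
  # everyone else homozygous reference
  p <- ped[ped$family_id == fam, ]
  kids <- if (is.null(carrier_kids)) {
    p$individual_id[p$affection == "affected" & p$sequenced]
  } else carrier_kids
  G[kids] <- 1
  het_maternal_line(G, p, kids)
}

#' Generate a complete ground-truthed synthetic cohort bundle
#'
#' Produces every input the pipeline consumes — multi-sample VCF calls,
#' pedigree with sidecar metadata, per-variant and per-gene annotation
#' tables, in-house detection counts, gene sets — plus a truth table
#' recording each planted variant's intended segregation class and fate.
#' Background sites are common (they fail the rarity filter by
#' construction) and provide the kinship signal; planted candidates are
#' novel in all frequency databases and receive genotypes realizing their
#' class; decoys are planted to violate exactly one filter rule each.
#'
#' The truth table's `in_all`/`in_strict` columns state expected
#' membership in the two candidate sets: e.g. shared variants whose
#' obligate carrier parent is a sequenced control (families 4 and 10) are
#' expected in the all-pedigree set but not the strict set.
#'
#' @param cfg A [sim_config()].
#' @param ped Cohort pedigree (default [cohort_pedigree()]).
#' @return A list of class `famseg_bundle`: `ped`, `vt` (a
#'   `famseg_vtab` over the sequenced samples), `ann`, `gene_ann`,
#'   `inhouse` (data frame), `gmt`, `truth`, `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(), ped = cohort_pedigree()) {
  set.seed(cfg$seed)
  fams <- unique(ped$family_id)
  seq_ids <- ped$individual_id[ped$sequenced]

  ## ---- background sites ----
  nb <- cfg$n_background_sites
  bg_chrom <- sample(as.character(1:22), nb, replace = TRUE)
  bg_pos <- sample.int(199000000L, nb) + 1000000L
  ord <- order(as.integer(bg_chrom), bg_pos)
  bg_chrom <- bg_chrom[ord]; bg_pos <- bg_pos[ord]
  ra <- rand_ref_alt(nb)
  maf <- stats::runif(nb, cfg$maf_range[1], cfg$maf_range[2])
  G_bg <- sim_genotypes(ped, maf)

  n_bg_genes <- 300L
  bg_genes <- sprintf("BG%04d", seq_len(n_bg_genes))
  bg_ann <- data.frame(
    chrom = bg_chrom, pos = bg_pos, ref = ra$ref, alt = ra$alt,
    genes = sample(bg_genes, nb, replace = TRUE),
    consequence = sample(c("synonymous", "nonsynonymous", "other"), nb,
                         replace = TRUE, prob = c(0.3, 0.5, 0.2)),
    splice_site = integer(nb), segdup = integer(nb),
    stringsAsFactors = FALSE)

  ## ---- planted variants ----
  plan <- list()
  G_pl <- list()
  n_all <- nrow(ped)
  zero_row <- stats::setNames(rep(0, n_all), ped$individual_id)
  next_pos <- 100000L
  cand_i <- 0L
  add_plant <- function(fam, class, fate, in_all, in_strict, genes,
                        consequence, splice_site, G_row, chrom = NULL,
                        pos_offset = 0L, af = 0, segdup = FALSE,
                        vqsr_fail = FALSE, inhouse_count = 0L,
                        low_dp_carriers = FALSE) {
    cand_i <<- cand_i + 1L
    next_pos <<- next_pos + 137L
    plan[[length(plan) + 1L]] <<- list(
      chrom = if (is.null(chrom)) as.character((cand_i %% 22L) + 1L) else chrom,
      pos = next_pos + pos_offset, ref = "C", alt = "T",
      family = fam, class = class, fate = fate,
      in_all = in_all, in_strict = in_strict, genes = genes,
      consequence = consequence, splice_site = splice_site,
      af = af, segdup = segdup, vqsr_fail = vqsr_fail,
      inhouse_count = inhouse_count, low_dp_carriers = low_dp_carriers)
    G_pl[[length(G_pl) + 1L]] <<- G_row
  }
  has_controls <- vapply(pedigrees(ped), function(p)
    length(sequenced_controls(p)) > 0, logical(1))
  ctl_of <- function(fam) {
    p <- ped[ped$family_id == fam, ]
    p$individual_id[p$sequenced & p$affection == "unaffected"]
  }

  # shared het: mother-borne carrier path; strict membership depends on
  # whether the obligate carrier mother is herself a sequenced control
  shared_fams <- rep(fams, length.out = max(cfg$n_shared_het, 1L))
  for (i in seq_len(cfg$n_shared_het)) {
    fam <- shared_fams[i]
    G_row <- plant_shared_style(zero_row, ped, fam)
    carriers <- names(G_row)[G_row > 0]
    ctl_carrier <- any(carriers %in% ctl_of(fam))
    splice_syn <- i == 1L   # exercise the splice-site synonymous route
    add_plant(fam, "shared_het", "pass", TRUE,
              in_strict = has_controls[fam] && !ctl_carrier,
              genes = sprintf("CAND%02d", cand_i + 1L),
              consequence = if (splice_syn) "synonymous" else
                sample(c("nonsynonymous", "stopgain", "frameshift_indel",
                         "splicing", "inframe_indel"), 1),
              splice_site = splice_syn, G_row = G_row)
  }

  # de novo: affected children of sequenced unaffected parent pairs
  dn_eligible <- list()
  for (fam in fams) {
    p <- ped[ped$family_id == fam, ]
    for (a in p$individual_id[p$affection == "affected" & p$sequenced]) {
      f <- p$father_id[p$individual_id == a]
      m <- p$mother_id[p$individual_id == a]
      if (is.na(f) || is.na(m)) next
      ok <- function(x) {
        x %in% p$individual_id[p$sequenced & p$affection == "unaffected"]
      }
      if (ok(f) && ok(m)) dn_eligible[[length(dn_eligible) + 1L]] <- c(fam, a)
    }
  }
  if (cfg$n_de_novo > 0 && length(dn_eligible) == 0L) {
    stop("config error: de novo planting requires an affected child of ",
         "sequenced unaffected parents", call. = FALSE)
  }
  for (i in seq_len(cfg$n_de_novo)) {
    e <- dn_eligible[[(i - 1L) %% length(dn_eligible) + 1L]]
    G_row <- zero_row; G_row[e[2]] <- 1
    add_plant(e[1], "de_novo", "pass", TRUE, TRUE,
              genes = sprintf("CAND%02d", cand_i + 1L),
              consequence = "nonsynonymous", splice_site = FALSE,
              G_row = G_row)
  }

  # recessive homozygous: prefer the consanguineous family; carrier path
  # runs het through every ancestor chain so transmission is consistent
  hom_fams <- fams[vapply(fams, function(fam) {
    p <- ped[ped$family_id == fam, ]
    aff <- p$affection == "affected" & p$sequenced
    sum(aff) >= 2 && all(!is.na(p$father_id[aff]))
  }, logical(1))]
  cons_first <- unique(c(fams[vapply(fams, function(f)
    any(ped$consanguineous[ped$family_id == f]), logical(1))], hom_fams))
  cons_first <- cons_first[cons_first %in% hom_fams]
  if (cfg$n_homozygous > 0 && length(cons_first) == 0L) {
    stop("config error: homozygous planting requires >= 2 affected sibs",
         call. = FALSE)
  }
  for (i in seq_len(cfg$n_homozygous)) {
    fam <- cons_first[(i - 1L) %% length(cons_first) + 1L]
    p <- ped[ped$family_id == fam, ]
    kids <- p$individual_id[p$affection == "affected" & p$sequenced &
                            !is.na(p$father_id)]
    G_row <- zero_row
    G_row[kids] <- 2
    # het every ancestor of the affected children
    anc <- kids
    repeat {
      par_ids <- unique(stats::na.omit(c(p$father_id[p$individual_id %in% anc],
                                         p$mother_id[p$individual_id %in% anc])))
      new <- setdiff(par_ids, names(G_row)[G_row > 0])
      if (length(new) == 0L) break
      G_row[new] <- 1
      anc <- new
    }
    add_plant(fam, "homozygous_recessive", "pass", TRUE,
              in_strict = has_controls[fam],
              genes = sprintf("CAND%02d", cand_i + 1L),
              consequence = "nonsynonymous", splice_site = FALSE,
              G_row = G_row)
  }

  # X-linked hemizygous: affected males hemizygous, affected/carrier
  # females het, on non-PAR X
  hemi_fams <- fams[vapply(fams, function(fam) {
    p <- ped[ped$family_id == fam, ]
    any(p$affection == "affected" & p$sequenced & p$sex == "male")
  }, logical(1))]
  hemi_fams <- unique(c(intersect("F13", hemi_fams), hemi_fams))
  if (cfg$n_hemizygous > 0 && length(hemi_fams) == 0L) {
    stop("config error: hemizygous planting requires a family with an ",
         "affected male", call. = FALSE)
  }
  for (i in seq_len(cfg$n_hemizygous)) {
    fam <- hemi_fams[(i - 1L) %% length(hemi_fams) + 1L]
    p <- ped[ped$family_id == fam, ]
    aff <- p$individual_id[p$affection == "affected" & p$sequenced]
    sex <- stats::setNames(p$sex, p$individual_id)
    G_row <- zero_row
    G_row[aff[sex[aff] == "male"]] <- 2
    G_row[aff[sex[aff] == "female"]] <- 1
    G_row <- het_maternal_line(G_row, p, aff)
    add_plant(fam, "hemizygous_x", "pass", TRUE,
              in_strict = has_controls[fam],
              genes = sprintf("CAND%02d", cand_i + 1L),
              consequence = "nonsynonymous", splice_site = FALSE,
              G_row = G_row, chrom = "X", pos_offset = 43000000L)
  }

  # decoys: shared-style genotypes, each violating exactly one rule
  if (cfg$decoys) {
    decoy_fams <- setdiff(fams, c("F04", "F10", "F13"))
    d_i <- 0L
    decoy <- function(fate, gene, consequence = "nonsynonymous", ...) {
      d_i <<- d_i + 1L
      fam <- decoy_fams[(d_i - 1L) %% length(decoy_fams) + 1L]
      G_row <- plant_shared_style(zero_row, ped, fam)
      add_plant(fam, "decoy", fate, FALSE, FALSE, genes = gene,
                consequence = consequence, splice_site = FALSE,
                G_row = G_row, ...)
    }
    decoy("dropped-by-frequency", "DECOY_FREQ", af = 0.05)
    decoy("dropped-by-consequence", "DECOY_CONS", consequence = "synonymous")
    decoy("dropped-by-rvis", "DECOY_RVIS")
    decoy("dropped-by-brain_nx", "DECOY_BRAIN")
    decoy("dropped-by-segdup", "DECOY_SEGDUP", segdup = TRUE)
    decoy("dropped-by-vqsr", "DECOY_VQSR", vqsr_fail = TRUE)
    decoy("dropped-by-genotype_qc", "DECOY_DP", low_dp_carriers = TRUE)
    decoy("dropped-by-inhouse", "DECOY_INHOUSE", inhouse_count = 25L)
  }

  ## ---- assemble variant table over sequenced samples ----
  np <- length(plan)
  pl_chrom <- vapply(plan, `[[`, character(1), "chrom")
  pl_pos <- vapply(plan, function(x) as.integer(x$pos), integer(1))
  variants <- data.frame(
    chrom = c(bg_chrom, pl_chrom),
    pos = c(bg_pos, pl_pos),
    ref = c(ra$ref, vapply(plan, `[[`, character(1), "ref")),
    alt = c(ra$alt, vapply(plan, `[[`, character(1), "alt")),
    filter_status = c(rep("pass", nb),
                      ifelse(vapply(plan, `[[`, logical(1), "vqsr_fail"),
                             "fail", "pass")),
    stringsAsFactors = FALSE)

  G_pl_mat <- if (np > 0) do.call(rbind, G_pl)[, seq_ids, drop = FALSE]
              else matrix(0, 0, length(seq_ids))
  gt <- rbind(G_bg[, seq_ids, drop = FALSE], G_pl_mat)
  nv <- nrow(gt); ns <- ncol(gt)

  dp <- matrix(stats::rnbinom(nb * ns, mu = cfg$depth_mu,
                              size = cfg$depth_size), nb, ns)
  gq <- matrix(sample(40:99, nb * ns, replace = TRUE), nb, ns)
  ad_alt <- matrix(0, nb, ns)
  het <- !is.na(G_bg[, seq_ids]) & G_bg[, seq_ids] == 1
  hom <- !is.na(G_bg[, seq_ids]) & G_bg[, seq_ids] == 2
  ad_alt[het] <- stats::rbinom(sum(het), dp[het], 0.5)
  ad_alt[hom] <- dp[hom]
  ad_ref <- dp - ad_alt

  if (np > 0) {
    dp_p <- matrix(60, np, ns)
    gq_p <- matrix(99, np, ns)
    ad_alt_p <- matrix(0, np, ns)
    ad_alt_p[G_pl_mat == 1] <- 30
    ad_alt_p[G_pl_mat == 2] <- 60
    ad_ref_p <- dp_p - ad_alt_p
    low_dp <- vapply(plan, `[[`, logical(1), "low_dp_carriers")
    for (r in which(low_dp)) {
      carriers <- colnames(G_pl_mat)[G_pl_mat[r, ] > 0]
      dp_p[r, match(carriers, seq_ids)] <- 5
      ad_ref_p[r, match(carriers, seq_ids)] <- 3
      ad_alt_p[r, match(carriers, seq_ids)] <- 2
    }
    dp <- rbind(dp, dp_p); gq <- rbind(gq, gq_p)
    ad_ref <- rbind(ad_ref, ad_ref_p); ad_alt <- rbind(ad_alt, ad_alt_p)
  }
  vt <- variant_table(variants, seq_ids, gt, ad_ref, ad_alt, dp, gq)

  ## ---- annotations ----
  af_cols <- c("af_1000G_ALL", "af_ExAC_ALL", "af_ExAC_EAS", "af_HGVD",
               "af_jMorp")
  for (col in af_cols) bg_ann[[col]] <- round(maf, 5)
  pl_ann <- data.frame(
    chrom = pl_chrom, pos = pl_pos,
    ref = rep("C", np), alt = rep("T", np),
    genes = vapply(plan, `[[`, character(1), "genes"),
    consequence = vapply(plan, `[[`, character(1), "consequence"),
    splice_site = as.integer(vapply(plan, `[[`, logical(1), "splice_site")),
    segdup = as.integer(vapply(plan, `[[`, logical(1), "segdup")),
    stringsAsFactors = FALSE)
  for (col in af_cols) {
    pl_ann[[col]] <- vapply(plan, function(x) x$af, numeric(1))
  }
  ann <- rbind(bg_ann, pl_ann)

  cand_genes <- grep("^CAND", ann$genes, value = TRUE)
  gene_ann <- rbind(
    data.frame(gene = bg_genes,
               rvis_percentile = round(stats::runif(n_bg_genes, 0, 100), 2),
               brain_nx = round(stats::runif(n_bg_genes, 0, 5), 3),
               stringsAsFactors = FALSE),
    data.frame(gene = unique(cand_genes),
               rvis_percentile = round(stats::runif(length(unique(cand_genes)),
                                                    1, 20), 2),
               brain_nx = round(stats::runif(length(unique(cand_genes)),
                                             1.5, 4), 3),
               stringsAsFactors = FALSE),
    data.frame(gene = c("DECOY_FREQ", "DECOY_CONS", "DECOY_RVIS",
                        "DECOY_BRAIN", "DECOY_SEGDUP", "DECOY_VQSR",
                        "DECOY_DP", "DECOY_INHOUSE"),
               rvis_percentile = c(10, 10, 80, 10, 10, 10, 10, 10),
               brain_nx = c(3, 3, 3, 0.2, 3, 3, 3, 3),
               stringsAsFactors = FALSE))

  ## ---- in-house counts: systematic-error plants plus sparse noise ----
  ih_idx <- which(vapply(plan, function(x) x$inhouse_count, integer(1)) > 0)
  n_rare <- min(50L, nb)
  rare_rows <- if (nb > 0) sort(sample.int(nb, n_rare)) else integer(0)
  inhouse <- rbind(
    data.frame(chrom = bg_chrom[rare_rows], pos = bg_pos[rare_rows],
               ref = ra$ref[rare_rows], alt = ra$alt[rare_rows],
               detection_count = sample(1:19, n_rare, replace = TRUE),
               stringsAsFactors = FALSE),
    data.frame(chrom = pl_chrom[ih_idx], pos = pl_pos[ih_idx],
               ref = rep("C", length(ih_idx)), alt = rep("T", length(ih_idx)),
               detection_count = vapply(plan[ih_idx],
                                        function(x) x$inhouse_count,
                                        integer(1)),
               stringsAsFactors = FALSE))

  ## ---- gene sets ----
  gmt <- list(list(set_id = "SET:CAND", name = "planted candidate pathway",
                   members = unique(c(cand_genes, bg_genes[1:10]))))
  for (i in 1:5) {
    gmt[[length(gmt) + 1L]] <- list(
      set_id = sprintf("SET:BG%02d", i), name = sprintf("background set %d", i),
      members = sample(bg_genes, 40))
  }

  ## ---- truth table ----
  truth <- data.frame(
    key = variant_key(pl_chrom, pl_pos, rep("C", np), rep("T", np)),
    chrom = pl_chrom, pos = pl_pos, ref = rep("C", np), alt = rep("T", np),
    family_id = vapply(plan, `[[`, character(1), "family"),
    class = vapply(plan, `[[`, character(1), "class"),
    fate = vapply(plan, `[[`, character(1), "fate"),
    in_all = vapply(plan, `[[`, logical(1), "in_all"),
    in_strict = vapply(plan, `[[`, logical(1), "in_strict"),
    stringsAsFactors = FALSE)

  structure(list(ped = ped, vt = vt, ann = ann, gene_ann = gene_ann,
                 inhouse = inhouse, gmt = gmt, truth = truth, config = cfg),
            class = "famseg_bundle")
}

#' Perturb a bundle's genotype calls and record a noise ledger
#'
#' Emulates genotyping noise: each call of the bundle's variant table is
#' independently selected with probability `rate` and perturbed in one of
#' three ways (read depth collapsed to 5, genotype quality collapsed to
#' 10, or the genotype flipped to a different value with allelic depths
#' rewritten consistently).  Every perturbed call is recorded in the
#' ledger, so downstream false negatives can be traced to their cause.
#'
#' @param bundle A `famseg_bundle`.
#' @param rate Per-call perturbation probability in `[0, 1]`.
#' @param seed Seed for the perturbation draws.
#' @return The bundle with perturbed `vt` and a `noise_ledger` data frame
#'   (`key`, `sample`, `field`, `old`, `new`).
#' @export
add_genotype_noise <- function(bundle, rate, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  vt <- bundle$vt
  nv <- n_variants(vt); ns <- length(vt$samples)
  hit <- which(matrix(stats::runif(nv * ns) < rate, nv, ns))
  if (length(hit) == 0L) {
    bundle$noise_ledger <- data.frame(
      key = character(), sample = character(), field = character(),
      old = character(), new = character(), stringsAsFactors = FALSE)
    return(bundle)
  }
  kind <- sample(c("low_dp", "low_gq", "gt_flip"), length(hit), replace = TRUE)
  r <- (hit - 1L) %% nv + 1L
  s <- (hit - 1L) %/% nv + 1L
  old <- character(length(hit))
  new <- character(length(hit))

  i_dp <- kind == "low_dp"
  old[i_dp] <- as.character(vt$dp[hit[i_dp]])
  new[i_dp] <- "5"
  vt$dp[hit[i_dp]] <- 5

  i_gq <- kind == "low_gq"
  old[i_gq] <- as.character(vt$gq[hit[i_gq]])
  new[i_gq] <- "10"
  vt$gq[hit[i_gq]] <- 10

  i_gt <- kind == "gt_flip"
  gt_old <- vt$gt[hit[i_gt]]
  shift <- sample(1:2, sum(i_gt), replace = TRUE)
  gt_new <- ifelse(is.na(gt_old), shift - 1, (gt_old + shift) %% 3)
  old[i_gt] <- as.character(gt_old)
  new[i_gt] <- as.character(gt_new)
  vt$gt[hit[i_gt]] <- gt_new
  d <- vt$dp[hit[i_gt]]
  d[is.na(d)] <- 60
  ad_new <- numeric(sum(i_gt))
  ad_new[gt_new == 1] <- floor(d[gt_new == 1] / 2)
  ad_new[gt_new == 2] <- d[gt_new == 2]
  vt$ad_alt[hit[i_gt]] <- ad_new
  vt$ad_ref[hit[i_gt]] <- d - ad_new

  bundle$vt <- vt
  bundle$noise_ledger <- data.frame(
    key = vt$variants$key[r], sample = vt$samples[s], field = kind,
    old = old, new = new, stringsAsFactors = FALSE)
  bundle
}
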