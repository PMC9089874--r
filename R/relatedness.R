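#' Classify a kinship estimate into a relationship degree
#'
#' Standard KING cutpoints: phi > 0.354 duplicate/monozygotic;
#' (0.177, 0.354] first degree; (0.0884, 0.177] second; (0.0442, 0.0884]
#' third; otherwise unrelated.  An undefined estimate (`NA`) maps to
#' `"unrelated"`.
#'
#' @param phi Numeric vector of kinship estimates.
#' @return Character vector of degrees.
#' @export
classify_degree <- function(phi) {
  out <- rep("unrelated", length(phi))
  out[!is.na(phi) & phi > 0.0442] <- "third"
  out[!is.na(phi) & phi > 0.0884] <- "second"
  out[!is.na(phi) & phi > 0.177]  <- "first"
  out[!is.na(phi) & phi > 0.354]  <- "duplicate_or_MZ"
  out
}

#' KING-robust kinship estimate for one sample pair
#'
#' The within-family robust estimator behind vcftools' `--relatedness2`:
#' over co-called biallelic sites,
#' \deqn{\hat\phi = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa,i} + N_{Aa,j}}}
#' where \eqn{N_{Aa,Aa}} counts sites where both samples are heterozygous,
#' \eqn{N_{AA,aa}} sites where they are opposite homozygotes, and
#' \eqn{N_{Aa,i}} the heterozygous-site count of each sample.  Sites with
#' a missing call in either sample are skipped.  Expected values: 0.5 for
#' duplicates/MZ twins, about 0.25 for first-degree relatives, about 0 for
#' unrelated pairs (negative for structurally diverged pairs).
#'
#' @param g_i,g_j Genotype code vectors (0/1/2/`NA`) aligned on the same
#'   sites.
#' @return A list with `phi` (`NA` when the denominator is zero),
#'   `n_sites` (co-called sites used) and `degree` (see
#'   [classify_degree()]).
#' @export
king_kinship <- function(g_i, g_j) {
  if (length(g_i) != length(g_j)) {
    stop("genotype vectors must have equal length", call. = FALSE)
  }
  use <- !is.na(g_i) & !is.na(g_j)
  gi <- g_i[use]; gj <- g_j[use]
  n_hh <- sum(gi == 1 & gj == 1)
  n_opp <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
  het_i <- sum(gi == 1)
  het_j <- sum(gj == 1)
  denom <- het_i + het_j
  phi <- if (denom == 0) NA_real_ else (n_hh - 2 * n_opp) / denom
  list(phi = phi, n_sites = sum(use), degree = classify_degree(phi))
}

x_chrom <- function(chrom) {
  sub("^chr", "", chrom) %in% c("X", "23")
}

#' All-pairs KING-robust kinship matrix
#'
#' Computes [king_kinship()] for every pair of samples via indicator-
#' matrix cross products (fast for cohort-scale site counts).  X-chromosome
#' sites are excluded: hemizygous male genotypes would bias the
#' autosomal-diploid estimator.
#'
#' @param vt A QC-passed `famseg_vtab` (kinship should be estimated
#'   before rarity filtering, which would strip the common variants that
#'   stabilize the estimate).
#' @param samples Samples to include (default: all in `vt`).
#' @return A data frame with columns `INDV1`, `INDV2`, `N_SITES`,
#'   `RELATEDNESS_PHI`, `degree`, one row per unordered pair.
#' @export
kinship_matrix <- function(vt, samples = vt$samples) {
  keep <- !x_chrom(vt$variants$chrom)
  g <- vt$gt[keep, match(samples, vt$samples), drop = FALSE]
  M <- (!is.na(g)) * 1
  H <- (!is.na(g) & g == 1) * 1
  A0 <- (!is.na(g) & g == 0) * 1
  A2 <- (!is.na(g) & g == 2) * 1
  n_hh <- crossprod(H)
  n_opp <- crossprod(A0, A2) + crossprod(A2, A0)
  het_shared <- crossprod(H, M)           # [i, j]: i het, j co-called
  denom <- het_shared + t(het_shared)
  n_sites <- crossprod(M)
  phi <- (n_hh - 2 * n_opp) / denom       # NaN where denom == 0
  phi[!is.finite(phi)] <- NA_real_

  ns <- length(samples)
  if (ns < 2L) {
    return(data.frame(INDV1 = character(), INDV2 = character(),
                      N_SITES = integer(), RELATEDNESS_PHI = numeric(),
                      degree = character(), stringsAsFactors = FALSE))
  }
  pairs <- which(upper.tri(phi), arr.ind = TRUE)
  data.frame(
    INDV1 = samples[pairs[, 1]],
    INDV2 = samples[pairs[, 2]],
    N_SITES = n_sites[pairs],
    RELATEDNESS_PHI = phi[pairs],
    degree = classify_degree(phi[pairs]),
    stringsAsFactors = FALSE
  )
}

#' Verify estimated kinship against pedigree expectations
#'
#' For each sample pair, the expected relationship degree is derived from
#' the pedigree graph: within a family the path-counting kinship
#' coefficient ([ped_kinship()]) is mapped through the same cutpoints as
#' the estimates (parent-offspring and full sibs, phi = 1/4, expect first
#' degree; half-sib/avuncular/grandparental, 1/8, second; first cousins,
#' 1/16, third); cross-family pairs are expected unrelated.  An undefined
#' estimate counts as a mismatch whenever a relationship is expected.
#'
#' @param kin Kinship data frame from [kinship_matrix()].
#' @param ped A `famseg_ped` data frame covering the samples (individual
#'   ids must be unique across families).
#' @return `kin` with added columns `expected_phi`, `expected_degree` and
#'   logical `mismatch`.
#' @export
verify_pedigrees <- function(kin, ped) {
  fam_of <- stats::setNames(ped$family_id, ped$individual_id)
  peds <- pedigrees(ped)
  phi_exp <- mapply(function(i, j) {
    fi <- fam_of[i]; fj <- fam_of[j]
    if (is.na(fi) || is.na(fj) || fi != fj) return(0)
    k <- ped_kinship(peds[[fi]])
    k[i, j]
  }, kin$INDV1, kin$INDV2)
  kin$expected_phi <- unname(phi_exp)
  kin$expected_degree <- classify_degree(kin$expected_phi)
  kin$mismatch <- kin$degree != kin$expected_degree |
    (is.na(kin$RELATEDNESS_PHI) & kin$expected_degree != "unrelated")
  kin
}
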