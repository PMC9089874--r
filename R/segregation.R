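# GRCh37 pseudoautosomal regions on X (1-based, inclusive)
PAR1_GRCH37 <- c(60001L, 2699520L)
PAR2_GRCH37 <- c(154931044L, 155260560L)

in_par <- function(chrom, pos) {
  x_chrom(chrom) &
    ((pos >= PAR1_GRCH37[1] & pos <= PAR1_GRCH37[2]) |
     (pos >= PAR2_GRCH37[1] & pos <= PAR2_GRCH37[2]))
}

#' Sex- and chromosome-aware genotype state
#'
#' Recodes diploid genotype codes into inheritance-model states.  On the
#' non-pseudoautosomal X, male calls are hemizygous: any alternate-bearing
#' genotype (het-coded diploid or hom-alt) becomes `hemi_alt`; males of
#' unknown sex get `missing` with a warning.  Pseudoautosomal regions
#' (GRCh37 X:60001-2699520 and X:154931044-155260560) are treated as
#' autosomal.
#'
#' @param gt Genotype codes (0/1/2/`NA`).
#' @param sex `"male"`, `"female"` or `"unknown"` (recycled).
#' @param chrom,pos Variant coordinates (recycled against `gt`).
#' @return Character vector of states: `"homref"`, `"het"`, `"homalt"`,
#'   `"hemi_alt"`, `"missing"`.
#' @export
genotype_state <- function(gt, sex, chrom, pos) {
  n <- max(length(gt), length(chrom))
  gt <- rep_len(gt, n); sex <- rep_len(sex, n)
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  state <- c("homref", "het", "homalt")[gt + 1]
  state[is.na(gt)] <- "missing"
  hemi_zone <- x_chrom(chrom) & !in_par(chrom, pos)
  male_alt <- hemi_zone & sex == "male" & !is.na(gt) & gt > 0
  state[male_alt] <- "hemi_alt"
  unk <- hemi_zone & sex == "unknown" & !is.na(gt)
  if (any(unk)) {
    warning("unknown sex for non-PAR X call(s); state set to missing")
    state[unk] <- "missing"
  }
  state
}

is_carrier_state <- function(state) state %in% c("het", "homalt", "hemi_alt")

family_states <- function(vt, p) {
  ids <- intersect(sequenced_members(p), vt$samples)
  if (length(ids) == 0L) {
    return(matrix(character(0), nrow = n_variants(vt), ncol = 0,
                  dimnames = list(vt$variants$key, character(0))))
  }
  sex <- stats::setNames(p$sex, p$individual_id)[ids]
  m <- vapply(seq_along(ids), function(j) {
    genotype_state(vt$gt[, ids[j]], sex[[j]],
                   vt$variants$chrom, vt$variants$pos)
  }, character(n_variants(vt)))
  matrix(m, nrow = n_variants(vt), ncol = length(ids),
         dimnames = list(vt$variants$key, ids))
}

#' Shared-among-affected predicate
#'
#' A variant segregates with disease in a family when at least two
#' sequenced affected members carry a non-reference state and (in the
#' default `"all"` sharing mode) every sequenced affected member with a
#' non-missing call carries it.  With `strict = TRUE`, no sequenced
#' control may carry it.
#'
#' @param states Named state vector (see [genotype_state()]) over the
#'   family's sequenced members.
#' @param p Single-family `famseg_ped` data frame.
#' @param strict Exclude the variant if any control carries it.
#' @param mode `"all"` (every non-missing affected must carry) or
#'   `"min2"` (any two affected carriers suffice).
#' @return Logical scalar.
#' @export
shared_among_affected <- function(states, p, strict = FALSE,
                                  mode = c("all", "min2")) {
  mode <- match.arg(mode)
  aff <- intersect(affected_members(p), names(states))
  s_aff <- states[aff]
  called <- s_aff != "missing"
  carriers <- is_carrier_state(s_aff)
  if (sum(carriers) < 2L) return(FALSE)
  if (mode == "all" && any(called & !carriers)) return(FALSE)
  if (strict) {
    ctl <- intersect(sequenced_controls(p), names(states))
    if (any(is_carrier_state(states[ctl]))) return(FALSE)
  }
  TRUE
}

#' De novo predicate
#'
#' A variant is de novo in a family when some sequenced affected member
#' carries a non-reference state while both parents are members of the
#' pedigree, sequenced, unaffected, and confidently homozygous reference
#' (a missing or QC-demoted parental call blocks the assignment).  De
#' novo candidates are accepted only from unaffected parents: an affected
#' parent could transmit shared rare variants instead.
#'
#' @inheritParams shared_among_affected
#' @return Logical scalar; attribute `"probands"` lists the qualifying
#'   carriers.
#' @export
is_de_novo <- function(states, p) {
  aff <- intersect(affected_members(p), names(states))
  fa <- stats::setNames(p$father_id, p$individual_id)
  mo <- stats::setNames(p$mother_id, p$individual_id)
  affection <- stats::setNames(p$affection, p$individual_id)
  probands <- character()
  for (a in aff) {
    if (!is_carrier_state(states[[a]])) next
    f <- fa[[a]]; m <- mo[[a]]
    if (is.na(f) || is.na(m)) next
    if (!(f %in% names(states)) || !(m %in% names(states))) next
    if (affection[[f]] != "unaffected" || affection[[m]] != "unaffected") next
    if (states[[f]] != "homref" || states[[m]] != "homref") next
    probands <- c(probands, a)
  }
  structure(length(probands) > 0L, probands = probands)
}

#' Recessive-homozygous predicate
#'
#' At least two affected members (all non-missing affected members in
#' `"all"` mode) are homozygous for the alternate allele and no sequenced
#' control is.  Heterozygous (carrier) parents do not block the call.
#' The family's consanguinity flag is informative, not required.
#'
#' @inheritParams shared_among_affected
#' @return Logical scalar.
#' @export
is_recessive_homozygous <- function(states, p, mode = c("all", "min2")) {
  mode <- match.arg(mode)
  aff <- intersect(affected_members(p), names(states))
  s_aff <- states[aff]
  hom <- s_aff == "homalt"
  called <- s_aff != "missing"
  if (sum(hom) < 2L) return(FALSE)
  if (mode == "all" && any(called & !hom)) return(FALSE)
  ctl <- intersect(sequenced_controls(p), names(states))
  if (any(states[ctl] == "homalt")) return(FALSE)
  TRUE
}

#' X-linked hemizygous predicate
#'
#' For a non-PAR X variant: every sequenced affected male with a
#' non-missing call is hemizygous for the alternate allele (and at least
#' one such male exists), every sequenced affected female with a
#' non-missing call is a heterozygous carrier, and no sequenced
#' unaffected male is hemizygous.  Unaffected heterozygous females are
#' permitted carriers, consistent with X-linked recessive transmission
#' through carrier mothers.
#'
#' @inheritParams shared_among_affected
#' @return Logical scalar.
#' @export
is_hemizygous_candidate <- function(states, p) {
  sex <- stats::setNames(p$sex, p$individual_id)
  aff <- intersect(affected_members(p), names(states))
  ctl <- intersect(sequenced_controls(p), names(states))
  aff_m <- aff[sex[aff] == "male"]
  aff_f <- aff[sex[aff] == "female"]
  s_m <- states[aff_m]; s_m <- s_m[s_m != "missing"]
  if (length(s_m) == 0L || any(s_m != "hemi_alt")) return(FALSE)
  s_f <- states[aff_f]; s_f <- s_f[s_f != "missing"]
  if (any(s_f != "het")) return(FALSE)
  ctl_m <- ctl[sex[ctl] == "male"]
  if (any(states[ctl_m] == "hemi_alt")) return(FALSE)
  TRUE
}

#' Classify a variant's segregation pattern in one family
#'
#' Applies the four inheritance-model predicates with a fixed precedence
#' for variants satisfying more than one:
#' de novo > X-linked hemizygous > recessive homozygous > shared
#' heterozygous.  Returns `NULL` when none fires.
#'
#' @inheritParams shared_among_affected
#' @param chrom Chromosome of the variant (hemizygous classification is
#'   attempted only on X).
#' @param pos Position (pseudoautosomal handling).
#' @return `NULL`, or a list with `seg_class` and `carriers` (affected
#'   carrier ids; for de novo, the qualifying probands).
#' @export
classify_variant <- function(states, p, chrom, pos = NA_integer_,
                             strict = FALSE, mode = c("all", "min2")) {
  mode <- match.arg(mode)
  aff <- intersect(affected_members(p), names(states))
  aff_carriers <- aff[is_carrier_state(states[aff])]
  dn <- is_de_novo(states, p)
  if (dn) {
    return(list(seg_class = "de_novo", carriers = attr(dn, "probands")))
  }
  on_x <- x_chrom(chrom) && !is.na(pos) && !in_par(chrom, pos)
  if (on_x && is_hemizygous_candidate(states, p)) {
    return(list(seg_class = "hemizygous_x", carriers = aff_carriers))
  }
  if (is_recessive_homozygous(states, p, mode)) {
    return(list(seg_class = "homozygous_recessive",
                carriers = aff[states[aff] == "homalt"]))
  }
  if (shared_among_affected(states, p, strict, mode)) {
    return(list(seg_class = "shared_het", carriers = aff_carriers))
  }
  NULL
}

empty_candidates <- function() {
  data.frame(family_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), key = character(),
             genes = character(), seg_class = character(),
             carriers = character(), stringsAsFactors = FALSE)
}

classify_family <- function(vt, p, strict = FALSE, mode = "all") {
  st <- family_states(vt, p)
  if (ncol(st) == 0L) return(empty_candidates())
  any_carrier <- rowSums(matrix(is_carrier_state(st), nrow = nrow(st))) > 0
  rows <- which(any_carrier)
  out <- lapply(rows, function(i) {
    cls <- classify_variant(st[i, ], p, vt$variants$chrom[i],
                            vt$variants$pos[i], strict = strict, mode = mode)
    if (is.null(cls)) return(NULL)
    v <- vt$variants[i, ]
    data.frame(family_id = p$family_id[1], chrom = v$chrom, pos = v$pos,
               ref = v$ref, alt = v$alt, key = v$key,
               genes = if (is.null(vt$ann)) NA_character_ else vt$ann$genes[i],
               seg_class = cls$seg_class,
               carriers = paste(cls$carriers, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_candidates() else out
}

#' Build the all-pedigree and strict candidate sets
#'
#' The *all* set classifies every family's variants under lenient sharing
#' (control carriers do not block a shared call).  The *strict* set is
#' restricted to families with at least one sequenced control and applies
#' strict sharing, so that variants carried by healthy relatives are
#' excluded.
#'
#' @param vt A fully filtered (QC + rare filters) `famseg_vtab`.
#' @param ped A `famseg_ped` covering the cohort.
#' @param mode Sharing mode, `"all"` (default) or `"min2"`.
#' @return A list with data frames `all` and `strict` (see
#'   [classify_variant()] for the per-row classes).
#' @export
build_candidate_sets <- function(vt, ped, mode = c("all", "min2")) {
  mode <- match.arg(mode)
  peds <- pedigrees(ped)
  all_set <- do.call(rbind, c(list(empty_candidates()),
    lapply(peds, classify_family, vt = vt, strict = FALSE, mode = mode)))
  ctl_peds <- peds[vapply(peds, function(p) length(sequenced_controls(p)) > 0,
                          logical(1))]
  strict_set <- do.call(rbind, c(list(empty_candidates()),
    lapply(ctl_peds, classify_family, vt = vt, strict = TRUE, mode = mode)))
  rownames(all_set) <- rownames(strict_set) <- NULL
  list(all = all_set, strict = strict_set)
}

#' Summarize a candidate set
#'
#' Variants are deduplicated across families by `(chrom, pos, ref, alt)`;
#' genes are the union of the candidates' (possibly multi-gene) gene
#' sets.
#'
#' @param cand A candidate data frame from [build_candidate_sets()].
#' @return A list with `n_variants`, `n_genes`, `genes` (the unique gene
#'   symbols), `per_class` and `per_family` count tables.
#' @export
summarize_candidates <- function(cand) {
  genes <- unique(unlist(split_genes(cand$genes)))
  genes <- genes[nzchar(genes)]
  list(
    n_variants = length(unique(cand$key)),
    n_genes = length(genes),
    genes = sort(genes),
    per_class = table(cand$seg_class),
    per_family = table(cand$family_id)
  )
}
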