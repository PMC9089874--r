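#' Parse a 6-column PED pedigree file
#'
#' Reads the classic whitespace-delimited PED dialect
#' (`FamID IndID FatherID MotherID Sex Affection`) into a validated
#' pedigree table.  Sex is coded 1 = male, 2 = female, 0 = unknown;
#' affection 1 = unaffected, 2 = affected, 0 = unknown.  A parent id of
#' `"0"` means the parent is not in the pedigree.
#'
#' Validation enforces the structural invariants of a pedigree: individual
#' ids are unique within a family, every non-"0" parent id resolves to a
#' member of the same family, fathers are male and mothers are female.
#'
#' @param path Path to a PED file, or a character vector of PED lines.
#' @return A data frame of class `famseg_ped` with columns `family_id`,
#'   `individual_id`, `father_id`, `mother_id` (`NA` when absent), `sex`
#'   (`"male"`, `"female"`, `"unknown"`), `affection` (`"affected"`,
#'   `"unaffected"`, `"unknown"`), plus sidecar columns `sequenced`
#'   (logical, `TRUE` until metadata says otherwise), `consanguineous`
#'   (logical) and `diagnosis` (character).
#' @seealso [attach_ped_meta()], [pedigrees()], [write_ped()]
#' @export
read_ped <- function(path) {
  lines <- if (length(path) == 1L && !grepl("[\n\t ]", path) && file.exists(path)) {
    readLines(path)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("PED parse error: no data rows", call. = FALSE)
  }
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) != 6L)
  if (length(bad) > 0L) {
    stop(sprintf("PED parse error at line %d: expected 6 fields, got %d",
                 bad[1], length(fields[[bad[1]]])), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  sex_map <- c(`1` = "male", `2` = "female", `0` = "unknown")
  aff_map <- c(`1` = "unaffected", `2` = "affected", `0` = "unknown")
  if (!all(m[, 5] %in% names(sex_map))) {
    stop("PED parse error: sex must be coded 0/1/2", call. = FALSE)
  }
  if (!all(m[, 6] %in% names(aff_map))) {
    stop("PED parse error: affection must be coded 0/1/2", call. = FALSE)
  }
  ped <- data.frame(
    family_id     = m[, 1],
    individual_id = m[, 2],
    father_id     = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother_id     = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex           = unname(sex_map[m[, 5]]),
    affection     = unname(aff_map[m[, 6]]),
    sequenced     = TRUE,
    consanguineous = FALSE,
    diagnosis     = NA_character_,
    stringsAsFactors = FALSE
  )
  validate_ped(ped)
  class(ped) <- c("famseg_ped", "data.frame")
  ped
}

validate_ped <- function(ped) {
  for (fam in unique(ped$family_id)) {
    p <- ped[ped$family_id == fam, ]
    if (anyDuplicated(p$individual_id)) {
      stop(sprintf("PED parse error: duplicate individual id in family %s: %s",
                   fam, p$individual_id[duplicated(p$individual_id)][1]),
           call. = FALSE)
    }
    for (col in c("father_id", "mother_id")) {
      ref <- p[[col]]
      missing_ref <- !is.na(ref) & !(ref %in% p$individual_id)
      if (any(missing_ref)) {
        stop(sprintf("PED structural error: %s '%s' of %s not a member of family %s",
                     sub("_id", "", col), ref[missing_ref][1],
                     p$individual_id[missing_ref][1], fam), call. = FALSE)
      }
    }
    sex_of <- stats::setNames(p$sex, p$individual_id)
    fa <- p$father_id[!is.na(p$father_id)]
    if (any(sex_of[fa] != "male")) {
      stop(sprintf("PED structural error: father %s in family %s is not male",
                   fa[sex_of[fa] != "male"][1], fam), call. = FALSE)
    }
    mo <- p$mother_id[!is.na(p$mother_id)]
    if (any(sex_of[mo] != "female")) {
      stop(sprintf("PED structural error: mother %s in family %s is not female",
                   mo[sex_of[mo] != "female"][1], fam), call. = FALSE)
    }
  }
  invisible(ped)
}

#' Serialize a pedigree table back to PED text
#'
#' Inverse of [read_ped()] on the canonical dialect: parse, serialize and
#' re-parse is the identity.
#'
#' @param ped A `famseg_ped` data frame.
#' @param path Optional output path; when `NULL` the PED lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`), a character vector
#'   of PED lines.
#' @export
write_ped <- function(ped, path = NULL) {
  sex_code <- c(male = "1", female = "2", unknown = "0")
  aff_code <- c(unaffected = "1", affected = "2", unknown = "0")
  lines <- paste(ped$family_id, ped$individual_id,
                 ifelse(is.na(ped$father_id), "0", ped$father_id),
                 ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                 sex_code[ped$sex], aff_code[ped$affection])
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read the pedigree sidecar metadata table
#'
#' The PED format carries neither sequencing status nor consanguinity, so
#' both travel in a sidecar TSV with columns `family_id`, `individual_id`,
#' `sequenced` (0/1), `consanguineous` (0/1, a per-family flag repeated on
#' each row) and `diagnosis` (free text).
#'
#' @param path Path to the sidecar TSV.
#' @return A data frame with the columns above (`sequenced` and
#'   `consanguineous` as logicals).
#' @export
read_ped_meta <- function(path) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c(family_id = "character",
                                           individual_id = "character"))
  need <- c("family_id", "individual_id", "sequenced", "consanguineous", "diagnosis")
  if (!all(need %in% names(meta))) {
    stop("pedigree metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  meta$sequenced <- as.logical(as.integer(meta$sequenced))
  meta$consanguineous <- as.logical(as.integer(meta$consanguineous))
  meta
}

#' Attach sidecar metadata to a pedigree table
#'
#' @param ped A `famseg_ped` data frame from [read_ped()].
#' @param meta A sidecar data frame from [read_ped_meta()].
#' @return `ped` with `sequenced`, `consanguineous` and `diagnosis` filled
#'   in.  Individuals absent from the sidecar keep `sequenced = FALSE`
#'   (only listed members were sequenced); consanguinity is the OR over a
#'   family's sidecar rows.
#' @export
attach_ped_meta <- function(ped, meta) {
  key_ped <- paste(ped$family_id, ped$individual_id)
  key_meta <- paste(meta$family_id, meta$individual_id)
  idx <- match(key_ped, key_meta)
  ped$sequenced <- !is.na(idx) & meta$sequenced[ifelse(is.na(idx), 1L, idx)]
  ped$diagnosis <- ifelse(is.na(idx), NA_character_,
                          meta$diagnosis[ifelse(is.na(idx), 1L, idx)])
  cons_fam <- tapply(meta$consanguineous, meta$family_id, any)
  ped$consanguineous <- as.logical(cons_fam[ped$family_id])
  ped$consanguineous[is.na(ped$consanguineous)] <- FALSE
  ped
}

#' Split a pedigree table into per-family pedigrees
#'
#' @param ped A `famseg_ped` data frame.
#' @return A named list (by `family_id`) of single-family `famseg_ped`
#'   data frames, each carrying a `consanguineous` attribute.
#' @export
pedigrees <- function(ped) {
  fams <- unique(ped$family_id)
  out <- lapply(fams, function(f) {
    p <- ped[ped$family_id == f, , drop = FALSE]
    rownames(p) <- NULL
    attr(p, "consanguineous") <- any(p$consanguineous)
    class(p) <- c("famseg_ped", "data.frame")
    p
  })
  stats::setNames(out, fams)
}

#' Sequenced affected members of a pedigree
#'
#' Any affected diagnosis counts as affected (the PED affection column is
#' binary; the specific diagnosis lives in the sidecar).  Individuals with
#' unknown affection are excluded.
#'
#' @param p A single-family `famseg_ped` data frame.
#' @return Character vector of individual ids.
#' @export
affected_members <- function(p) {
  p$individual_id[p$sequenced & p$affection == "affected"]
}

#' Sequenced unaffected members of a pedigree
#'
#' The within-family controls: sequenced members explicitly coded
#' unaffected.  Unknown affection is excluded (conservative).
#'
#' @inheritParams affected_members
#' @return Character vector of individual ids.
#' @export
sequenced_controls <- function(p) {
  p$individual_id[p$sequenced & p$affection == "unaffected"]
}

#' Sequenced members of a pedigree
#' @inheritParams affected_members
#' @return Character vector of individual ids.
#' @export
sequenced_members <- function(p) {
  p$individual_id[p$sequenced]
}

#' Pedigree-expected kinship coefficients
#'
#' Computes the classic path-counting kinship coefficient phi for every
#' pair of members of one family by the standard recursion: for founders
#' phi(i, i) = 1/2 and phi(i, j) = 0; otherwise
#' phi(i, i) = 1/2 (1 + phi(father, mother)) and, taking j to be the
#' individual of greater generation depth,
#' phi(i, j) = (phi(i, father_j) + phi(i, mother_j)) / 2.
#' Parent-offspring and full sibs give 1/4; half sibs, avuncular and
#' grandparental pairs 1/8; first cousins 1/16.  Consanguineous unions
#' raise coefficients accordingly.
#'
#' @param p A single-family `famseg_ped` data frame.
#' @return A symmetric numeric matrix of kinship coefficients with
#'   individual ids as dimnames.
#' @export
ped_kinship <- function(p) {
  ids <- p$individual_id
  n <- length(ids)
  fa <- match(p$father_id, ids)
  mo <- match(p$mother_id, ids)
  depth <- rep(NA_integer_, n)
  gen_depth <- function(i) {
    if (!is.na(depth[i])) return(depth[i])
    d <- 0L
    if (!is.na(fa[i])) d <- max(d, gen_depth(fa[i]) + 1L)
    if (!is.na(mo[i])) d <- max(d, gen_depth(mo[i]) + 1L)
    depth[i] <<- d
    d
  }
  for (i in seq_len(n)) gen_depth(i)
  phi <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  kin <- function(i, j) {
    if (!is.na(phi[i, j])) return(phi[i, j])
    v <- if (i == j) {
      if (is.na(fa[i]) || is.na(mo[i])) 0.5 else 0.5 * (1 + kin(fa[i], mo[i]))
    } else {
      # recurse through the parents of the deeper individual
      if (depth[j] < depth[i]) { tmp <- i; i <- j; j <- tmp }
      if (is.na(fa[j]) && is.na(mo[j])) {
        0
      } else {
        f <- if (is.na(fa[j])) 0 else kin(i, fa[j])
        m <- if (is.na(mo[j])) 0 else kin(i, mo[j])
        (f + m) / 2
      }
    }
    phi[i, j] <<- v
    phi[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in i:n) kin(i, j)
  phi
}
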