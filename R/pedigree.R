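#' @importFrom stats rbinom rpois runif rnorm setNames
#' @importFrom utils read.table write.table head tail
NULL

AFFECTION_LEVELS <- c("CD", "UC", "unaffected", "unknown")
SEX_LEVELS <- c("male", "female", "unknown")

# PED numeric dialect: affection column extended so the two IBD subtypes are
# distinguishable (1 = unaffected, 2 = CD, 3 = UC, 0/-9 = unknown).
PED_AFFECTION_CODES <- c(`1` = "unaffected", `2` = "CD", `3` = "UC",
                         `0` = "unknown", `-9` = "unknown")
PED_SEX_CODES <- c(`1` = "male", `2` = "female", `0` = "unknown")

#' Construct a validated pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' `family_id`, `id`, `father`, `mother` (`NA` when unknown), `sex`
#' (`male`/`female`/`unknown`), `affection` (`CD`/`UC`/`unaffected`/`unknown`)
#' and `sequenced` (logical; whether genotype data exist for the member).
#'
#' @param family_id single family label.
#' @param id character vector of unique individual ids.
#' @param father,mother character vectors of parent ids, `NA` when missing.
#' @param sex character vector, one of `"male"`, `"female"`, `"unknown"`.
#' @param affection character vector, one of `"CD"`, `"UC"`, `"unaffected"`,
#'   `"unknown"`.
#' @param sequenced logical vector; defaults to all `TRUE`.
#' @return an object of class `fam_pedigree`.
#' @export
pedigree <- function(family_id, id, father = NA, mother = NA,
                     sex = "unknown", affection = "unknown",
                     sequenced = TRUE) {
  n <- length(id)
  ped <- data.frame(
    family_id = rep_len(as.character(family_id), n),
    id = as.character(id),
    father = rep_len(as.character(father), n),
    mother = rep_len(as.character(mother), n),
    sex = rep_len(as.character(sex), n),
    affection = rep_len(as.character(affection), n),
    sequenced = rep_len(as.logical(sequenced), n),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("fam_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate pedigree invariants
#'
#' Checks id uniqueness, referential integrity of parent links, allowed
#' affection and sex codes, and that the parentage graph is acyclic.
#'
#' @param ped a `fam_pedigree`.
#' @return `ped`, invisibly; errors on violation.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  req <- c("family_id", "id", "father", "mother", "sex", "affection",
           "sequenced")
  missing_cols <- setdiff(req, names(ped))
  if (length(missing_cols))
    stop("pedigree is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(ped$id))
    stop("duplicate individual ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  if (length(unique(ped$family_id)) != 1L)
    stop("a pedigree holds exactly one family")
  bad_aff <- setdiff(unique(ped$affection), AFFECTION_LEVELS)
  if (length(bad_aff))
    stop("unknown affection code(s): ", paste(bad_aff, collapse = ", "))
  bad_sex <- setdiff(unique(ped$sex), SEX_LEVELS)
  if (length(bad_sex))
    stop("unknown sex code(s): ", paste(bad_sex, collapse = ", "))
  for (col in c("father", "mother")) {
    p <- ped[[col]]
    unknown <- !is.na(p) & !(p %in% ped$id)
    if (any(unknown))
      stop("structural error: ", col, " id(s) absent from family: ",
           paste(unique(p[unknown]), collapse = ", "))
  }
  ped_topological_order(ped)  # errors on cycles
  invisible(ped)
}

# Topological order of individuals (founders first); errors on cyclic
# parentage.
ped_topological_order <- function(ped) {
  order_ids <- character(0)
  placed <- setNames(rep(FALSE, nrow(ped)), ped$id)
  remaining <- ped$id
  while (length(remaining)) {
    ready <- vapply(remaining, function(i) {
      r <- ped[ped$id == i, ]
      (is.na(r$father) || placed[[r$father]]) &&
        (is.na(r$mother) || placed[[r$mother]])
    }, logical(1))
    if (!any(ready))
      stop("structural error: cyclic parentage involving: ",
           paste(remaining, collapse = ", "))
    order_ids <- c(order_ids, remaining[ready])
    placed[remaining[ready]] <- TRUE
    remaining <- remaining[!ready]
  }
  order_ids
}

#' Founders of a pedigree
#' @param ped a `fam_pedigree`.
#' @return character vector of ids with no recorded parents.
#' @export
founders <- function(ped) ped$id[is.na(ped$father) & is.na(ped$mother)]

#' Affected members of a pedigree
#' @param ped a `fam_pedigree`.
#' @param subtype restrict to one subtype (`"CD"` or `"UC"`); default both.
#' @return character vector of affected ids.
#' @export
affected_members <- function(ped, subtype = c("CD", "UC")) {
  subtype <- match.arg(subtype, several.ok = TRUE)
  ped$id[ped$affection %in% subtype]
}

#' Read a PED/FAM pedigree file
#'
#' Six-column whitespace-delimited PED dialect: family id, individual id,
#' father id, mother id, sex (1 = male, 2 = female, 0 = unknown) and an
#' affection column extended beyond the binary convention so that the two
#' IBD subtypes are kept apart: 1 = unaffected, 2 = CD, 3 = UC,
#' 0 or -9 = unknown.  A parent id of `"0"` encodes a missing parent.  An
#' optional seventh column (0/1) flags whether the member was sequenced;
#' absent, all members are taken as sequenced.
#'
#' @param path path to the PED file.
#' @param family optional family id to extract when the file holds several.
#' @return a `fam_pedigree`, or a named list of them when the file contains
#'   more than one family and `family` is not given.
#' @export
read_pedigree <- function(path, family = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "#")
  if (ncol(tab) < 6)
    stop("parse error: PED file needs at least 6 columns, found ", ncol(tab))
  names(tab)[1:6] <- c("fid", "iid", "pat", "mat", "sex", "aff")
  bad <- setdiff(unique(tab$aff), names(PED_AFFECTION_CODES))
  if (length(bad))
    stop("parse error: unknown affection code(s): ",
         paste(bad, collapse = ", "))
  bad_sex <- setdiff(unique(tab$sex), names(PED_SEX_CODES))
  if (length(bad_sex))
    stop("parse error: unknown sex code(s): ", paste(bad_sex, collapse = ", "))
  seqd <- if (ncol(tab) >= 7) tab[[7]] == "1" else rep(TRUE, nrow(tab))
  build <- function(rows, s) {
    pedigree(
      family_id = rows$fid[1],
      id = rows$iid,
      father = ifelse(rows$pat == "0", NA, rows$pat),
      mother = ifelse(rows$mat == "0", NA, rows$mat),
      sex = unname(PED_SEX_CODES[rows$sex]),
      affection = unname(PED_AFFECTION_CODES[rows$aff]),
      sequenced = s
    )
  }
  fids <- unique(tab$fid)
  if (!is.null(family)) {
    if (!family %in% fids) stop("family not in file: ", family)
    keep <- tab$fid == family
    return(build(tab[keep, ], seqd[keep]))
  }
  if (length(fids) == 1L) return(build(tab, seqd))
  setNames(lapply(fids, function(f) build(tab[tab$fid == f, ],
                                          seqd[tab$fid == f])), fids)
}

#' Write a pedigree (or list of pedigrees) as a PED file
#'
#' Inverse of [read_pedigree()]; the affection dialect is documented there.
#'
#' @param ped a `fam_pedigree` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  peds <- if (inherits(ped, "fam_pedigree")) list(ped) else ped
  rows <- lapply(peds, function(p) {
    validate_pedigree(p)
    data.frame(
      fid = p$family_id,
      iid = p$id,
      pat = ifelse(is.na(p$father), "0", p$father),
      mat = ifelse(is.na(p$mother), "0", p$mother),
      sex = names(PED_SEX_CODES)[match(p$sex, PED_SEX_CODES)],
      aff = names(PED_AFFECTION_CODES)[match(p$affection,
                                             PED_AFFECTION_CODES)],
      seqd = ifelse(p$sequenced, "1", "0"),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.fam_pedigree <- function(x, ...) {
  aff <- table(factor(x$affection, AFFECTION_LEVELS))
  cat(sprintf(
    "<fam_pedigree> family %s: %d members (%d CD, %d UC, %d unaffected, %d unknown), %d founders\n",
    x$family_id[1], nrow(x), aff[["CD"]], aff[["UC"]], aff[["unaffected"]],
    aff[["unknown"]], length(founders(x))))
  NextMethod()
  invisible(x)
}
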