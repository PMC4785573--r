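# Built-in reconstructions of the five multiplex IBD study pedigrees.
#
# The published cohort consists of five American families of European
# descent: two deep pedigrees in which the affected members are distantly
# related (families 1 and 2) and three nuclear or near-nuclear families
# (families 3-5).  The original pedigree drawings are not machine-readable,
# so the structures below are reconstructions that honour every textual
# constraint: member identifiers and affection subtypes of all genotyped
# individuals, the number of affected members per family, the "two branches
# related over 10 generations" description of family 1, and the multiple
# distantly related branches of family 2 (whose member 2-V-1 has separate
# ancestry and is excluded from segment-sharing analysis).  Ungenotyped
# connecting ancestors are synthetic placeholders; their ids follow the
# generation-numbering convention of the drawings.

# chain of ungenotyped ancestors: couple -> ... -> head
ped_chain <- function(fid, ids, spouses, top_father, top_mother) {
  n <- length(ids)
  list(
    id = c(ids, spouses),
    father = c(top_father, ids[-n][seq_len(n - 1)], rep(NA, length(spouses))),
    mother = c(top_mother, spouses[seq_len(n - 1)], rep(NA, length(spouses)))
  )
}

#' Reconstructed study pedigrees
#'
#' Returns the five multiplex-family pedigrees used throughout the package:
#' family 1 (two branches joined at an ancestral couple, paths of 5 and 6
#' meioses to the branch parents, four CD and one UC affected), family 2
#' (four distantly related branches below a common ancestral couple carrying
#' one CD and three UC affecteds, plus the separately descended UC individual
#' 2-V-1), family 3 (UC father, two CD children), family 4 (unaffected
#' parents, five of six children with CD, one grandchild) and family 5
#' (three CD children, their unaffected parents and a UC uncle).
#'
#' Members with `sequenced = TRUE` (38 in all) correspond to genotyped study
#' individuals; untyped connecting ancestors are placeholders.
#'
#' @return named list of five `fam_pedigree` objects.
#' @export
cohort_pedigrees <- function() {
  list(
    fam1 = family1_pedigree(),
    fam2 = family2_pedigree(),
    fam3 = family3_pedigree(),
    fam4 = family4_pedigree(),
    fam5 = family5_pedigree()
  )
}

#' @rdname cohort_pedigrees
#' @export
family1_pedigree <- function() {
  # ancestral couple 1-I-1 x 1-I-2; branch A: 5 meioses to 1-VI-4 (CD) whose
  # children are 1-VII-4 (CD) and 1-VII-6 (UC); branch B: 6 meioses to the
  # unaffected conduit 1-VI-2 whose children are 1-VII-1 and 1-VII-2 (CD).
  # The path between the two branch parents spans 11 meioses ("distant
  # relationship over 10 generations").
  a <- ped_chain("1", c("1-II-1", "1-III-1", "1-IV-1", "1-V-1", "1-VI-4"),
                 c("1-II-2", "1-III-2", "1-IV-2", "1-V-2"),
                 "1-I-1", "1-I-2")
  b <- ped_chain("1",
                 c("1-II-3", "1-III-3", "1-IV-3", "1-IV-5", "1-V-3", "1-VI-2"),
                 c("1-II-4", "1-III-4", "1-IV-4", "1-IV-6", "1-V-4"),
                 "1-I-1", "1-I-2")
  id <- c("1-I-1", "1-I-2", a$id, b$id,
          "1-VI-5", "1-VII-4", "1-VII-6",           # branch A sibship
          "1-VI-3", "1-VII-1", "1-VII-2", "1-VII-3", # branch B sibship
          "1-VII-5")                                 # married-in, genotyped
  father <- c(NA, NA, a$father, b$father,
              NA, "1-VI-5", "1-VI-5",
              NA, "1-VI-2", "1-VI-2", "1-VI-2",
              NA)
  mother <- c(NA, NA, a$mother, b$mother,
              NA, "1-VI-4", "1-VI-4",
              NA, "1-VI-3", "1-VI-3", "1-VI-3",
              NA)
  aff <- setNames(rep("unknown", length(id)), id)
  aff[c("1-VI-4", "1-VII-4", "1-VII-1", "1-VII-2")] <- "CD"
  aff["1-VII-6"] <- "UC"
  aff[c("1-VI-2", "1-VI-3", "1-VI-5", "1-VII-3", "1-VII-5")] <- "unaffected"
  seqd <- id %in% c("1-VI-2", "1-VI-3", "1-VI-4", "1-VI-5", "1-VII-1",
                    "1-VII-2", "1-VII-3", "1-VII-4", "1-VII-5", "1-VII-6")
  pedigree("1", id, father, mother, affection = unname(aff[id]),
           sequenced = seqd)
}

#' @rdname cohort_pedigrees
#' @export
family2_pedigree <- function() {
  # common ancestral couple 2-II-1 x 2-II-2 with four descending branches of
  # 4, 4, 5 and 6 meioses ending in 2-VI-3 (UC), 2-VI-5 (CD), 2-VII-1 (UC)
  # and 2-VIII-1 (UC).  2-V-1 (UC) descends from separate distant ancestry
  # (related to 2-VII-1 over 10 generations) and is excluded from
  # segment-sharing analyses.
  b1 <- ped_chain("2", c("2-III-1", "2-IV-2", "2-V-3", "2-VI-3"),
                  c("2-III-2", "2-IV-3", "2-V-4"), "2-II-1", "2-II-2")
  b2 <- ped_chain("2", c("2-III-3", "2-IV-4", "2-V-5", "2-VI-5"),
                  c("2-III-4", "2-IV-5", "2-V-6"), "2-II-1", "2-II-2")
  b3 <- ped_chain("2", c("2-III-5", "2-IV-6", "2-V-7", "2-VI-7", "2-VII-1"),
                  c("2-III-6", "2-IV-7", "2-V-8", "2-VI-8"),
                  "2-II-1", "2-II-2")
  b4 <- ped_chain("2",
                  c("2-III-7", "2-IV-8", "2-V-9", "2-VI-9", "2-VII-2",
                    "2-VIII-1"),
                  c("2-III-8", "2-IV-9", "2-V-10", "2-VI-10", "2-VII-3"),
                  "2-II-1", "2-II-2")
  id <- c("2-II-1", "2-II-2", b1$id, b2$id, b3$id, b4$id, "2-V-1")
  father <- c(NA, NA, b1$father, b2$father, b3$father, b4$father, NA)
  mother <- c(NA, NA, b1$mother, b2$mother, b3$mother, b4$mother, NA)
  aff <- setNames(rep("unknown", length(id)), id)
  aff[c("2-VI-3", "2-VII-1", "2-VIII-1", "2-V-1")] <- "UC"
  aff["2-VI-5"] <- "CD"
  aff[c("2-VII-2", "2-VII-3")] <- "unaffected"
  seqd <- id %in% c("2-V-1", "2-VI-3", "2-VI-5", "2-VII-1", "2-VII-2",
                    "2-VII-3", "2-VIII-1")
  pedigree("2", id, father, mother, affection = unname(aff[id]),
           sequenced = seqd)
}

#' @rdname cohort_pedigrees
#' @export
family3_pedigree <- function() {
  pedigree("3",
           id = c("3-II-1", "3-II-2", "3-III-1", "3-III-2", "3-III-3"),
           father = c(NA, NA, "3-II-2", "3-II-2", "3-II-2"),
           mother = c(NA, NA, "3-II-1", "3-II-1", "3-II-1"),
           sex = c("female", "male", "unknown", "unknown", "unknown"),
           affection = c("unaffected", "UC", "unaffected", "CD", "CD"),
           sequenced = TRUE)
}

#' @rdname cohort_pedigrees
#' @export
family4_pedigree <- function() {
  id <- c("4-I-1", "4-I-2", paste0("4-II-", 1:7), "4-III-1")
  father <- c(NA, NA, rep("4-I-1", 6), NA, "4-II-7")
  mother <- c(NA, NA, rep("4-I-2", 6), NA, "4-II-1")
  aff <- c("unaffected", "unaffected",
           "CD", "unaffected", "CD", "CD", "CD", "CD",
           "unaffected", "unaffected")
  sex <- c("male", "female", "female", rep("unknown", 5), "male", "female")
  pedigree("4", id, father, mother, sex = sex, affection = aff,
           sequenced = TRUE)
}

#' @rdname cohort_pedigrees
#' @export
family5_pedigree <- function() {
  # 5-II-1 (UC) is the uncle of the three CD children; 5-II-2 is his sibling
  # and the children's blood parent, 5-II-3 the married-in parent.  5-III-1
  # was not available for sequencing.
  id <- c("5-I-1", "5-I-2", "5-II-1", "5-II-2", "5-II-3",
          "5-III-1", "5-III-2", "5-III-3", "5-III-4")
  father <- c(NA, NA, "5-I-1", "5-I-1", NA,
              rep("5-II-3", 4))
  mother <- c(NA, NA, "5-I-2", "5-I-2", NA,
              rep("5-II-2", 4))
  aff <- c("unknown", "unknown", "UC", "unaffected", "unaffected",
           "unknown", "CD", "CD", "CD")
  sex <- c("male", "female", "unknown", "female", "male",
           rep("unknown", 4))
  seqd <- !id %in% c("5-I-1", "5-I-2", "5-III-1")
  pedigree("5", id, father, mother, sex = sex, affection = aff,
           sequenced = seqd)
}
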