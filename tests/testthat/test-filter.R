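# candidate_filter: the four-clause cascade, zygosity models, compound-het
# pairing and target restriction.

fam3 <- family3_pedigree()
fam3_req <- affected_members(fam3)  # 3-II-2, 3-III-2, 3-III-3

# genotype row helper for family 3 columns
f3row <- function(II1, II2, III1, III2, III3) {
  c(`3-II-1` = II1, `3-II-2` = II2, `3-III-1` = III1,
    `3-III-2` = III2, `3-III-3` = III3)
}

test_that("quality boundary: 34 is excluded, 35 survives", {
  g <- rbind(f3row(0L, 1L, 0L, 1L, 1L), f3row(0L, 1L, 0L, 1L, 1L))
  vt <- toy_vt(g, quality = c(34, 35), gene = "GENE2")
  calls <- filter_variants(vt, panel1(),
                           filter_config(fam3_req), fam3)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$quality, 35)
})

test_that("a TRIM11-shaped novel variant is called het in all affecteds", {
  # novel (AF 0), distance-1 gene, het in the three affecteds, absent in
  # the unaffected mother and sibling
  g <- rbind(f3row(0L, 1L, 0L, 1L, 1L))
  vt <- toy_vt(g, pop_af = 0, gene = "GENE2", consequence = "missense")
  calls <- filter_variants(vt, panel1(), filter_config(fam3_req), fam3)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$zygosity, "het")
  expect_equal(calls$gene_distance, 1L)
  expect_setequal(strsplit(calls$affected_carriers, ",")[[1]], fam3_req)
})

test_that("six-variant truth table: exactly the two qualifying survive", {
  good <- f3row(0L, 1L, 0L, 1L, 1L)
  g <- rbind(good,                      # v1 passes everything
             good,                      # v2 quality too low
             good,                      # v3 too common
             good,                      # v4 consequence not functional
             good,                      # v5 gene too distant
             good)                      # v6 passes everything
  vt <- variant_table(
    data.frame(chrom = "chr1", pos = (1:6) * 1000L, ref = "A", alt = "T",
               quality = c(50, 34, 50, 50, 50, 50),
               pop_af = c(0, 0, 0.05, 0, 0, 0.01),
               consequence = c("missense", "missense", "missense",
                               "noncoding_other", "missense", "splice"),
               gene = c("GENE1", "GENE1", "GENE1", "GENE1", "GENE3",
                        "GENE2"),
               stringsAsFactors = FALSE), g)
  fc <- filter_config(fam3_req, max_gene_distance = 1)
  calls <- filter_variants(vt, panel1(), fc, fam3)
  expect_equal(calls$pos, c(1000L, 6000L))
  # every surviving call re-checks against the four clauses
  expect_true(all(calls$quality >= 35 & calls$pop_af <= 0.03 &
                    calls$gene_distance <= 1))
})

test_that("zygosity classification handles hom-recessive and parents", {
  fam4 <- family4_pedigree()
  req <- affected_members(fam4)
  # affecteds homozygous, unaffected sib het, both parents het
  g <- c(`4-I-1` = 1L, `4-I-2` = 1L, `4-II-1` = 2L, `4-II-2` = 1L,
         `4-II-3` = 2L, `4-II-4` = 2L, `4-II-5` = 2L, `4-II-6` = 2L,
         `4-II-7` = 0L, `4-III-1` = 1L)
  expect_equal(classify_zygosity(g, req, fam4), "hom")
  g2 <- g; g2[["4-I-1"]] <- 0L  # parent not het: recessive pattern broken
  expect_true(is.na(classify_zygosity(g2, req, fam4)))
  # all affecteds het -> het even when one parent is homozygous
  g3 <- c(`3-II-1` = 1L, `3-II-2` = 1L, `3-III-1` = 0L, `3-III-2` = 1L,
          `3-III-3` = 1L)
  expect_equal(classify_zygosity(g3, fam3_req, fam3), "het")
})

test_that("compound hets pair in trans and fall back to unphased", {
  fam5 <- family5_pedigree()
  req <- c("5-III-2", "5-III-3", "5-III-4")  # the CD sibs
  base <- c(`5-II-1` = 0L, `5-II-2` = 0L, `5-II-3` = 0L, `5-III-2` = 0L,
            `5-III-3` = 0L, `5-III-4` = 0L)
  # anchor from the blood parent, two partners from the married-in parent
  vA <- base; vA[c("5-II-1", "5-II-2", "5-III-2", "5-III-3", "5-III-4")] <- 1L
  vB <- base; vB[c("5-II-3", "5-III-3")] <- 1L
  vC <- base; vC[c("5-II-3", "5-III-2", "5-III-4")] <- 1L
  g <- rbind(vA, vB, vC)
  vt <- toy_vt(g, gene = "GENE2", pop_af = c(0.0015, 0.0151, 0.0244))
  calls <- filter_variants(vt, panel1(), filter_config(req), fam5)
  ch <- calls[calls$zygosity == "comp_het", ]
  # two trans pairs: (anchor, partner1) and (anchor, partner2)
  expect_equal(nrow(ch), 4)  # two pairs, each reported from both sides
  anchor_rows <- ch[ch$pos == 1000, ]
  expect_equal(nrow(anchor_rows), 2)
  expect_setequal(anchor_rows$partners, c("chr1:2000:T", "chr1:3000:T"))
  # pairing is symmetric
  expect_true(all(c("chr1:1000:T") %in% ch$partners[ch$pos != 1000]))

  # drop the married-in parent's genotypes: phase becomes unknowable
  g2 <- g[, setdiff(colnames(g), "5-II-3")]
  vt2 <- toy_vt(g2, gene = "GENE2", pop_af = 0.001)
  calls2 <- filter_variants(vt2, panel1(), filter_config(req), fam5)
  expect_true(all(calls2$zygosity[calls2$partners != ""] ==
                    "comp_het_unphased"))

  # a cis pair (both variants from one parent) never pairs
  vD <- base; vD[c("5-II-3", "5-III-3")] <- 1L
  vt3 <- toy_vt(rbind(vB, vD), gene = "GENE2", pop_af = 0.001)
  calls3 <- filter_variants(
    vt3, panel1(),
    filter_config("5-III-3", zygosity_models = "compound_het"), fam5)
  expect_equal(nrow(calls3), 0)
})

test_that("restrict_targets relaxes carriage monotonically", {
  # second variant carried by the mother and two of the three affecteds
  g <- rbind(f3row(0L, 1L, 0L, 1L, 1L),   # all three carry
             f3row(1L, 0L, 0L, 1L, 1L))   # 3-II-2 does not
  vt <- toy_vt(g, gene = "GENE2", pop_af = 0)
  fc <- filter_config(fam3_req)
  before <- filter_variants(vt, panel1(), fc, fam3)
  expect_equal(nrow(before), 1)
  fc2 <- restrict_targets(fc, "3-II-2")
  after <- filter_variants(vt, panel1(), fc2, fam3)
  expect_equal(sum(after$zygosity == "het"), 2)
  key <- function(d) paste(d$pos, d$zygosity, d$partners)
  expect_true(all(key(before) %in% key(after)))  # superset property
  expect_identical(restrict_targets(fc, character(0)), fc)
  expect_error(restrict_targets(fc, "ghost"), "not required")
  expect_error(restrict_targets(fc, fam3_req), "every required carrier")
})

test_that("loosening any clause never removes a candidate", {
  set.seed(88)
  for (rep in 1:5) {
    g <- matrix(sample(0:1, 5 * 8, replace = TRUE, prob = c(0.3, 0.7)),
                8, 5, dimnames = list(NULL, names(f3row(0, 0, 0, 0, 0))))
    vt <- variant_table(
      data.frame(chrom = "chr1", pos = (1:8) * 500L, ref = "A", alt = "T",
                 quality = sample(30:60, 8, TRUE),
                 pop_af = runif(8, 0, 0.06),
                 consequence = sample(CONSEQUENCE_LEVELS, 8, TRUE),
                 gene = sample(c("GENE1", "GENE2", "GENE3", "OTHER"), 8,
                               TRUE),
                 stringsAsFactors = FALSE), g)
    tight <- filter_variants(vt, panel1(), filter_config(fam3_req), fam3)
    loose <- filter_variants(
      vt, panel1(),
      filter_config(fam3_req, min_quality = 30, max_af = 0.1,
                    max_gene_distance = 3L,
                    consequences = CONSEQUENCE_LEVELS),
      fam3)
    key <- function(d) paste(d$pos, d$zygosity, d$partners)
    expect_true(all(key(tight) %in% key(loose)))
  }
})

test_that("missing required genotypes and absent carriers error", {
  g <- rbind(f3row(0L, 1L, 0L, 1L, 1L))
  vt <- toy_vt(g, gene = "GENE2")
  expect_error(
    filter_variants(vt, panel1(), filter_config(c(fam3_req, "ghost")),
                    fam3),
    "not genotyped")
})

test_that("presence in other families is a post-hoc annotation", {
  row <- c(f3row(0L, 1L, 0L, 1L, 1L), `5-III-2` = 1L, `5-III-3` = 0L)
  vt <- toy_vt(matrix(row, 1, dimnames = list(NULL, names(row))),
               gene = "GENE2", pop_af = 0)
  calls <- filter_variants(vt, panel1(), filter_config(fam3_req), fam3)
  fams <- setNames(c(rep("3", 5), "5", "5"), colnames(vt$geno))
  ann <- annotate_presence(calls, vt, fams, own_family = "3")
  expect_equal(ann$other_families, "5")
})
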