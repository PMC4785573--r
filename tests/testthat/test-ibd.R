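# ibd_segments: meiosis counting, exact point-sharing enumeration, the
# genome-wide sharing model and its Monte-Carlo oracle.

test_that("meiosis counts on canonical relationships", {
  expect_equal(count_meioses(ped_trio(), c("f", "c1")), 1)
  expect_equal(count_meioses(ped_sibs(), c("c1", "c2")), 2)
  expect_equal(count_meioses(ped_avuncular(), c("c1", "n1")), 3)
  expect_equal(count_meioses(ped_cousins(), c("c1", "c2")), 4)
  expect_equal(count_meioses(ped_chain6(), c("a2", "b2")), 6)
  two <- pedigree("u", c("a", "b"), NA, NA)
  expect_error(count_meioses(two, c("a", "b")), "no common ancestral couple")
})

test_that("point sharing: exact enumeration matches classical values", {
  expect_equal(as.numeric(point_sharing_probability(ped_trio(),
                                                    c("f", "c1"))), 1)
  expect_equal(as.numeric(point_sharing_probability(ped_sibs(),
                                                    c("c1", "c2"))), 0.75)
  expect_equal(as.numeric(point_sharing_probability(ped_avuncular(),
                                                    c("c1", "n1"))), 0.5)
  expect_equal(as.numeric(point_sharing_probability(ped_cousins(),
                                                    c("c1", "c2"))), 0.25)
  expect_equal(as.numeric(point_sharing_probability(ped_chain6(),
                                                    c("a2", "b2"))), 1 / 16)
})

test_that("point sharing matches a brute-force gene-drop at rho = 0", {
  # rho = 0, one chromosome: the genome IS a single point
  map <- build_genetic_map(c(c1 = 1e8), 0)
  set.seed(31)
  for (case in list(list(ped_cousins(), c("c1", "c2")),
                    list(ped_chain6(), c("a2", "b2")),
                    list(ped_sibs(), c("c1", "c2")))) {
    mc <- gene_drop_sharing_mc(case[[1]], case[[2]], map, n_sims = 800)
    p <- as.numeric(point_sharing_probability(case[[1]], case[[2]]))
    expect_lt(abs(mc$estimate - p), 3 * max(mc$se, 1e-3))
  }
})

test_that("each added meiosis at least halves the point probability", {
  p_prev <- NULL
  for (d in 1:6) {
    p <- as.numeric(point_sharing_probability(ped_lineal(d),
                                              c("f0", paste0("x", d))))
    if (!is.null(p_prev)) expect_lte(p, p_prev / 2 + 1e-12)
    p_prev <- p
  }
})

test_that("genome sharing: parent-child is certain; attributes are sane", {
  map <- build_genetic_map(grch37_autosomes(), 35.3)
  g <- genome_sharing_probability(ped_trio(), c("f", "c1"), map)
  expect_equal(as.numeric(g), 1)
  expect_equal(attr(g, "m_total"), 1L)
  expect_equal(attr(g, "n_segments"), 22 + 35.3)
  gp <- genome_sharing_probability(ped_cousins(), c("c1", "c2"), map,
                                   model = "poisson")
  gb <- genome_sharing_probability(ped_cousins(), c("c1", "c2"), map)
  expect_equal(as.numeric(gp), 1 - exp(-0.25 * (22 + 4 * 35.3)))
  expect_equal(as.numeric(gb), 1 - 0.75^(22 + 4 * 35.3))
})

test_that("analytic model is exact on recombination-free maps", {
  # with rho = 0 chromosomes share independently: 1 - (1-p)^C exactly
  map <- build_genetic_map(c(c1 = 1e8, c2 = 1e8), 0)
  set.seed(17)
  for (case in list(list(ped_sibs(), c("c1", "c2"), 0.75),
                    list(ped_cousins(), c("c1", "c2"), 0.25),
                    list(ped_chain6(), c("a2", "b2"), 1 / 16))) {
    an <- genome_sharing_probability(case[[1]], case[[2]], map)
    expect_equal(as.numeric(an), 1 - (1 - case[[3]])^2)
    mc <- gene_drop_sharing_mc(case[[1]], case[[2]], map, n_sims = 600)
    expect_lt(abs(mc$estimate - as.numeric(an)), 3 * max(mc$se, 2e-3))
  }
})

test_that("independence-model bias stays small on sparse recombining maps", {
  # On maps with few crossovers per path the analytic approximation sits
  # within a few points of the gene-drop truth (the bias is O(rho); it is
  # zero at rho = 0 and grows with map density -- a documented limitation)
  sparse <- build_genetic_map(c(c1 = 1e8, c2 = 1e8), 0.25)
  set.seed(77)
  for (case in list(list(ped_sibs(), c("c1", "c2")),
                    list(ped_avuncular(), c("c1", "n1")),
                    list(ped_chain6(), c("a2", "b2")))) {
    an <- as.numeric(genome_sharing_probability(case[[1]], case[[2]],
                                                sparse))
    mc <- gene_drop_sharing_mc(case[[1]], case[[2]], sparse, n_sims = 1000)
    expect_lt(abs(mc$estimate - an), 0.035 + 3 * mc$se)
  }
})

test_that("enumeration bound directs deep pedigrees to Monte Carlo", {
  deep <- ped_lineal(27)
  expect_error(point_sharing_probability(deep, c("f0", "x27")),
               "gene_drop_sharing_mc")
  # and the bound is adjustable
  expect_silent(point_sharing_probability(ped_lineal(5), c("f0", "x5"),
                                          max_meioses = 5))
  expect_error(point_sharing_probability(ped_lineal(5), c("f0", "x5"),
                                         max_meioses = 4), "exceeds")
})

test_that("family reconstructions reproduce the published probabilities", {
  # the probability check lives in test-acceptance; here only the meiosis
  # counts of the reconstructions
  fams <- cohort_pedigrees()
  expect_equal(count_meioses(fams$fam1, affected_members(fams$fam1)), 15)
  expect_equal(
    count_meioses(fams$fam2,
                  setdiff(affected_members(fams$fam2), "2-V-1")), 19)
})
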