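# synthetic_cohort: genetic map, gene drop, founder models, controls,
# phenotype assignment.

test_that("genetic map allocates crossovers proportionally to length", {
  m1 <- build_genetic_map(c(chrA = 1e8), 35.3)
  expect_equal(m1$chrom$exp_xo, 35.3)
  m2 <- build_genetic_map(c(a = 2e8, b = 1e8), 35.3)
  expect_equal(m2$chrom$exp_xo, c(2 * 35.3 / 3, 35.3 / 3))
  m22 <- build_genetic_map(grch37_autosomes(), 35.3)
  expect_equal(nrow(m22$chrom), 22)
  expect_equal(sum(m22$chrom$exp_xo), 35.3, tolerance = 1e-9)
  expect_error(build_genetic_map(numeric(0), 35.3), "at least one")
  expect_error(build_genetic_map(c(a = 0), 35.3), "positive")
})

test_that("gene drop without recombination copies one parental haplotype", {
  drop <- gene_drop(ped_trio(), build_genetic_map(c(c1 = 1e8), 0), seed = 1)
  child <- drop$genomes[["c1"]][[1]]
  f <- drop$founder_haps
  expect_equal(nrow(child$h1), 1)  # intact single-segment copy
  expect_equal(nrow(child$h2), 1)
  expect_true(child$h1[1, 2] %in% unlist(f[f$id == "f", c("hap1", "hap2")]))
  expect_true(child$h2[1, 2] %in% unlist(f[f$id == "m", c("hap1", "hap2")]))
  expect_error(
    gene_drop(pedigree("x", c("a", "b"), c(NA, "a"), c(NA, NA)),
              build_genetic_map(c(c1 = 1e8), 0)),
    "missing parent")
})

test_that("crossover count per meiosis is Poisson(35.3) on average", {
  # 50-child sibship, 100 drops: 5000 paternal meioses; the paternal gamete
  # of a founder alternates strands at every crossover, so segment count
  # minus one counts crossovers exactly
  n_kids <- 50; n_drops <- 100
  ped <- pedigree("big", c("f", "m", paste0("k", 1:n_kids)),
                  c(NA, NA, rep("f", n_kids)), c(NA, NA, rep("m", n_kids)))
  map <- build_genetic_map(c(c1 = 1e8), 35.3)
  set.seed(42)
  xo <- unlist(lapply(seq_len(n_drops), function(i) {
    drop <- gene_drop(ped, map)
    vapply(paste0("k", 1:n_kids),
           function(k) nrow(drop$genomes[[k]][[1]]$h1) - 1, numeric(1))
  }))
  n <- length(xo)
  se <- sqrt(35.3 / n)
  expect_lt(abs(mean(xo) - 35.3), 3 * se)
})

test_that("full sibs share half the genome identical by descent", {
  map <- build_genetic_map(c(c1 = 1e8), 1)
  set.seed(7)
  fr <- replicate(2000, {
    drop <- gene_drop(ped_sibs(), map)
    ibd_fraction(drop, "c1", "c2")
  })
  expect_lt(abs(mean(fr) - 0.5), 3 * sd(fr) / sqrt(length(fr)))
})

test_that("gene drop is Mendelian-consistent and seed-deterministic", {
  map <- build_genetic_map(c(c1 = 5e7, c2 = 5e7), 2)
  loci <- data.frame(locus_id = paste0("L", 1:40),
                     chrom = rep(c("c1", "c2"), 20),
                     pos = rep(seq(1e6, 4e7, length.out = 20), each = 2),
                     freq = 0.4)
  fm <- founder_model(loci)
  run <- function(s) {
    drop <- gene_drop(ped_sibs(), map, seed = s)
    fa <- draw_founder_alleles(fm, drop$founder_haps)
    drop_genotypes(drop, loci, fa)
  }
  g <- run(5)
  for (k in c("c1", "c2"))
    expect_true(all(vapply(seq_len(nrow(loci)), function(i)
      mendel_ok(g[i, "f"], g[i, "m"], g[i, k]), logical(1))))
  expect_identical(run(5), g)
  expect_false(identical(run(6), g))
})

test_that("control panel is Hardy-Weinberg at the stated frequencies", {
  loci <- data.frame(locus_id = c("a", "b"), chrom = "c1",
                     pos = c(100, 200), freq = c(0.2, 0))
  fm <- founder_model(loci)
  g <- simulate_controls(10000, fm, seed = 3)
  expect_equal(dim(g), c(2, 10000))
  het <- mean(g["a", ] == 1)
  p_het <- 2 * 0.2 * 0.8
  expect_lt(abs(het - p_het),
            3 * sqrt(p_het * (1 - p_het) / 10000))
  expect_true(all(g["b", ] == 0))  # frequency-0 locus never drawn
  g2 <- simulate_controls(1096, fm, seed = 4)
  expect_equal(ncol(g2), 1096)
})

test_that("phenotype assignment follows the logistic liability", {
  s <- rep(0, 10000)
  ph <- assign_phenotypes(s, disease_model(beta0 = -2, beta1 = 0), seed = 1)
  prev <- mean(ph != "unaffected")
  p <- plogis(-2)
  expect_lt(abs(prev - p), 3 * sqrt(p * (1 - p) / 10000))
  # saturated limit: essentially no one affected
  ph2 <- assign_phenotypes(s, disease_model(beta0 = -50, beta1 = 1), seed = 1)
  expect_equal(sum(ph2 != "unaffected"), 0)
  # positive effect: affecteds have higher scores
  set.seed(2)
  sc <- rnorm(5000)
  ph3 <- assign_phenotypes(sc, disease_model(beta0 = 0, beta1 = 1.5))
  expect_gt(mean(sc[ph3 != "unaffected"]), mean(sc[ph3 == "unaffected"]))
})

test_that("locus table bookkeeping and NOD2 augmentation", {
  lw <- make_locus_table(140, 133, 110, seed = 1)
  expect_equal(nrow(lw), 163)
  expect_equal(sum(!is.na(lw$or_cd)), 140)
  expect_equal(sum(!is.na(lw$or_uc)), 133)
  expect_equal(sum(!is.na(lw$or_cd) & !is.na(lw$or_uc)), 110)
  one <- make_locus_table(1, 1, 1, seed = 2)
  expect_equal(nrow(one), 1)
  expect_false(anyNA(one[, c("or_cd", "or_uc")]))
  withnod <- make_locus_table(10, 8, 5, include_nod2 = TRUE, seed = 3)
  expect_true(all(c(2.023, 3.5, 4.255) %in% withnod$or_cd))
  expect_error(make_locus_table(5, 5, 6), "n_shared")
})

test_that("cohort simulation is reproducible and correctly shaped", {
  sim <- simulate_cohort(seed = 9, n_controls = 20, n_cd = 12, n_uc = 10,
                         n_shared = 8, n_rare_per_family = 1)
  expect_equal(ncol(sim$family_vt$geno), 38)  # sequenced study members
  expect_equal(ncol(sim$control_geno), 20)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$family_vt, f1)
  sim2 <- simulate_cohort(seed = 9, n_controls = 20, n_cd = 12, n_uc = 10,
                          n_shared = 8, n_rare_per_family = 1)
  write_vcf(sim2$family_vt, f2)
  expect_identical(readLines(f1), readLines(f2))  # same seed, same bytes
  sim3 <- simulate_cohort(seed = 10, n_controls = 20, n_cd = 12, n_uc = 10,
                          n_shared = 8, n_rare_per_family = 1)
  expect_false(identical(sim3$family_vt$geno, sim$family_vt$geno))
})
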