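# prs_stats: scoring, Wilcoxon, ROC/AUC, Nagelkerke pseudo R-squared.

test_that("risk scores follow the log-product-of-odds-ratios rule", {
  lw <- nod2_loci()
  g <- matrix(0L, 3, 3, dimnames = list(lw$locus_id, c("none", "l1007",
                                                       "all")))
  g["NOD2_L1007fs", "l1007"] <- 1L
  g[, "all"] <- 1L
  s <- compute_prs(g, lw, "CD")
  expect_equal(unname(s["none"]), 0)
  expect_equal(unname(s["l1007"]), log(4.255))   # 1.44809...
  expect_equal(round(unname(s["l1007"]), 4), 1.4481)
  expect_equal(unname(s["all"]), log(2.023 * 3.5 * 4.255))  # 3.40544...
  expect_equal(round(unname(s["all"]), 4), 3.4054)
  # the NOD2 loci carry no UC odds ratio: UC score ignores them
  expect_equal(unname(compute_prs(g, lw, "UC")["all"]), 0)
})

test_that("scoring is linear and doubles with homozygosity", {
  lw <- make_locus_table(6, 5, 4, seed = 2)
  set.seed(3)
  g <- matrix(sample(0:2, nrow(lw) * 4, TRUE), nrow(lw), 4,
              dimnames = list(lw$locus_id, paste0("i", 1:4)))
  s <- compute_prs(g, lw, "CD")
  per_locus <- vapply(seq_len(nrow(lw)), function(i) {
    gi <- matrix(0L, nrow(lw), 4, dimnames = dimnames(g))
    gi[i, ] <- g[i, ]
    compute_prs(gi, lw, "CD")
  }, numeric(4))
  expect_equal(unname(s), unname(rowSums(per_locus)))
  hom <- matrix(2L, nrow(lw), 1, dimnames = list(lw$locus_id, "h"))
  het <- matrix(1L, nrow(lw), 1, dimnames = list(lw$locus_id, "h"))
  expect_equal(unname(compute_prs(hom, lw, "CD")),
               2 * unname(compute_prs(het, lw, "CD")))
})

test_that("variant-table scoring orients the risk allele and errors off-allele", {
  lw <- data.frame(locus_id = c("a", "b"), chrom = "chr1",
                   pos = c(1000L, 2000L), risk_allele = c("T", "A"),
                   or_cd = c(2, 3), or_uc = NA_real_)
  g <- matrix(c(1L, 0L), 2, 1, dimnames = list(NULL, "s"))
  vt <- toy_vt(g)  # ref A, alt T at both sites
  # locus a: risk = alt (count 1); locus b: risk = ref (count 2 - 0 = 2)
  expect_equal(unname(compute_prs(vt, lw, "CD")), log(2) + 2 * log(3))
  lw$risk_allele[2] <- "G"
  expect_error(compute_prs(vt, lw, "CD"), "locus b")
  # missing genotypes contribute nothing
  g2 <- matrix(c(NA, 0L), 2, 1, dimnames = list(NULL, "s"))
  vt2 <- toy_vt(g2)
  lw$risk_allele[2] <- "A"
  expect_equal(unname(compute_prs(vt2, lw, "CD")), 2 * log(3))
})

test_that("odds-scale risk update reproduces the NOD2 worked example", {
  expect_equal(round(100 * odds_update(0.0025, 3.99)), 1)
  expect_equal(odds_update(0.5, 1), 0.5)
})

test_that("one-sided Wilcoxon: exact enumeration and edge cases", {
  r <- wilcoxon_one_sided(c(3, 4), c(1, 2))
  expect_equal(r$p_value, 1 / 6)
  expect_equal(r$method, "exact")
  expect_gte(wilcoxon_one_sided(c(1, 2, 3), c(1, 2, 3))$p_value, 0.5)
  expect_warning(p1 <- wilcoxon_one_sided(rep(2, 3), rep(2, 4))$p_value,
                 "degenerate")
  expect_equal(p1, 1)
})

test_that("Wilcoxon branches agree near the exact/approximate crossover", {
  set.seed(10)
  for (rep in 1:20) {
    x <- rnorm(6, 0.3); y <- rnorm(6)
    pe <- wilcoxon_one_sided(x, y, exact_limit = 12)$p_value
    pa <- wilcoxon_one_sided(x, y, exact_limit = 0)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Wilcoxon holds its type-I error under the null", {
  set.seed(11)
  rej <- mean(replicate(1000, {
    wilcoxon_one_sided(rnorm(25), rnorm(25))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("AUC equals the Mann-Whitney probability with half ties", {
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both label classes")
  # agreement with the brute-force pair count on random fixtures
  set.seed(12)
  for (rep in 1:10) {
    s <- sample(0:5, 20, TRUE)
    l <- sample(c(TRUE, FALSE), 20, TRUE, prob = c(0.4, 0.6))
    if (!any(l) || all(l)) next
    pairs <- outer(s[l], s[!l], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(s, l), mean(pairs))
  }
  # ROC points integrate to the same area
  s <- c(3, 1, 2, 0); l <- c(TRUE, TRUE, FALSE, FALSE)
  rp <- roc_points(s, l)
  trap <- sum(diff(rp$fpr) * (head(rp$tpr, -1) + tail(rp$tpr, -1)) / 2)
  expect_equal(trap, roc_auc(s, l))
})

test_that("Nagelkerke R2: null, saturated and oracle-checked fits", {
  set.seed(13)
  s <- rnorm(5000)
  l <- sample(rep(c(TRUE, FALSE), 2500))  # independent of the score
  expect_lt(nagelkerke_r2(s, l), 0.01)
  expect_warning(r_sat <- nagelkerke_r2(1:20, rep(c(FALSE, TRUE),
                                                  each = 10)),
                 "separation")
  expect_gt(r_sat, 0.95)
  # small printed fixture against an independent likelihood maximization
  s12 <- c(0.1, 0.4, 0.5, 0.9, 1.2, 1.4, 1.7, 2.0, 2.2, 2.6, 2.9, 3.1)
  l12 <- c(F, F, T, F, F, T, T, F, T, T, T, T)
  expect_equal(nagelkerke_r2(s12, l12), oracle_nagelkerke(s12, l12),
               tolerance = 1e-4)
})
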