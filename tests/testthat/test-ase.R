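test_that("het-site filtering requires thresholds in every sample", {
  tab <- rbind(
    alleleTableOneSite(list(s1 = c(12, 7), s2 = c(30, 30)),
                       gene = "g1", site = "g1_s1"),
    alleleTableOneSite(list(s1 = c(15, 10), s2 = c(15, 10)),
                       gene = "g2", site = "g2_s1"))
  # (12,7) totals 19 < 20 in s1 -> dropped even though s2 passes
  expect_equal(filterHetSites(tab, minTotal = 20), "g2_s1")
  # boundary inclusive: (15,10) passes minTotal=20, minPerAllele=10
  expect_equal(filterHetSites(tab, minTotal = 20, minPerAllele = 10),
               "g2_s1")
  expect_equal(filterHetSites(tab, minTotal = 20, minPerAllele = 11),
               character(0))
  # stricter per-allele thresholds retain a subset
  set.seed(51)
  big <- do.call(rbind, lapply(1:40, function(i)
    alleleTableOneSite(list(s1 = rpois(2, 120), s2 = rpois(2, 120)),
                       gene = paste0("g", i), site = paste0("g", i, "_s1"))))
  k10 <- filterHetSites(big, minTotal = 20, minPerAllele = 10)
  k100 <- filterHetSites(big, minTotal = 20, minPerAllele = 100)
  expect_true(all(k100 %in% k10))
})

test_that("per-site binomial p-values match exact enumeration", {
  expect_equal(binomialSiteTest(50, 50)$p.value, 1)
  expect_equal(binomialSiteTest(15, 5)$p.value, binomOracle(15, 20),
               tolerance = 1e-10)
  expect_equal(round(binomialSiteTest(15, 5)$p.value, 4), 0.0414)
  expect_equal(binomialSiteTest(60, 40)$p.value, binomOracle(60, 100),
               tolerance = 1e-10)
  expect_gt(binomialSiteTest(60, 40)$p.value, 0.05)  # 0.0569: not significant
  expect_equal(binomialSiteTest(15, 5)$favoredAllele, 1L)
  expect_equal(binomialSiteTest(5, 15)$favoredAllele, 2L)
  expect_true(is.na(binomialSiteTest(7, 7)$favoredAllele))
  expect_error(binomialSiteTest(0, 0), "zero total")
})

test_that("allele swap flips favored alleles but keeps p-values", {
  set.seed(52)
  tab <- do.call(rbind, lapply(1:30, function(i)
    alleleTableOneSite(list(s1 = rpois(2, 60) + 1, s2 = rpois(2, 60) + 1),
                       gene = paste0("g", i), site = paste0("g", i, "_s1"))))
  swapped <- tab
  swapped$count1 <- tab$count2
  swapped$count2 <- tab$count1
  a <- siteTests(tab); b <- siteTests(swapped)
  expect_equal(a$p, b$p)
  flip <- ifelse(is.na(a$favored), NA_integer_, 3L - a$favored)
  expect_equal(b$favored, flip)
})

test_that("gene-level hybrid ASE needs consistent bias in every hybrid", {
  hyb <- c("h1", "h2", "h3"); par <- c("p1", "p2")
  mk <- function(hcounts, pcounts = list(p1 = c(50, 50), p2 = c(50, 50))) {
    siteTests(alleleTableOneSite(c(hcounts, pcounts)))
  }
  consistent <- mk(list(h1 = c(80, 20), h2 = c(80, 20), h3 = c(80, 20)))
  call1 <- geneASECall(consistent, hyb, par)
  expect_true(call1$hybrid_ase)
  expect_false(call1$parental_ase)
  expect_equal(call1$supporting_site, "g1_s1")
  flipped <- mk(list(h1 = c(80, 20), h2 = c(20, 80), h3 = c(80, 20)))
  expect_false(geneASECall(flipped, hyb, par)$hybrid_ase)
  oneWeak <- mk(list(h1 = c(80, 20), h2 = c(55, 45), h3 = c(80, 20)))
  expect_false(geneASECall(oneWeak, hyb, par)$hybrid_ase)
  parBias <- mk(list(h1 = c(80, 20), h2 = c(80, 20), h3 = c(80, 20)),
                list(p1 = c(80, 20), p2 = c(50, 50)))
  expect_true(geneASECall(parBias, hyb, par)$parental_ase)
  # genes without retained sites are unevaluable, not negative
  noSite <- geneASECall(consistent, hyb, par, genes = c("g1", "gX"))
  expect_true(is.na(noSite$hybrid_ase[noSite$gene == "gX"]))
})

test_that("pseudo-phasing test matches the closed-form single-SNP null", {
  bal <- mbasedGeneTest(10, 10, nSim = 2000, seed = 1)
  expect_equal(bal$statistic, 0.5)
  expect_equal(bal$p.value, 1, tolerance = 0.01)
  skew <- mbasedGeneTest(18, 2, nSim = 1e5, seed = 2)
  exact <- 2 * sum(dbinom(18:20, 20, 0.5))   # P(major count >= 18)
  expect_equal(skew$p.value, exact, tolerance = 0.35)
  expect_equal(round(exact, 5), round(422 / 2^20, 5))
  two <- mbasedGeneTest(c(10, 10), c(10, 10), nSim = 2000, seed = 3)
  expect_equal(two$statistic, 0.5)
  expect_equal(two$p.value, 1, tolerance = 0.01)
  expect_warning(z <- mbasedGeneTest(c(5, 0), c(15, 0), nSim = 2000, seed = 4),
                 "zero total")
  expect_equal(z$nSNP, 1)
  expect_error(suppressWarnings(mbasedGeneTest(0, 0, nSim = 2000)), "no SNP")
  expect_error(mbasedGeneTest(5, 5, nSim = 10), "nSim")
})

test_that("pseudo-phasing p-values are super-uniform under the null", {
  set.seed(53)
  pvals <- replicate(300, {
    depth <- rpois(3, 80) + 20
    k <- rbinom(3, depth, 0.5)
    mbasedGeneTest(k, depth - k, nSim = 2000)$p.value
  })
  # super-uniform: empirical CDF never exceeds the uniform by much
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdfv <- vapply(grid, function(q) mean(pvals <= q), numeric(1))
  expect_true(all(ecdfv <= grid + 2 * sqrt(grid * (1 - grid) / 300)))
})

test_that("ASE power increases with coverage at a fixed true ratio", {
  set.seed(54)
  powerAt <- function(depth) {
    ac <- simulateAlleleCounts(0.7, 400, depth = rep(depth, 400), rho = 0)
    mean(vapply(seq_len(400), function(i)
      binomialSiteTest(ac[i, 1], ac[i, 2])$p.value, numeric(1)) < 0.05)
  }
  p <- vapply(c(25, 50, 100, 200), powerAt, numeric(1))
  expect_true(all(diff(p) >= -0.02))   # monotone up to MC noise
  expect_gt(p[4], p[1])
})

test_that("per-sample ASE proportions count eligible genes only", {
  tab <- rbind(
    alleleTableOneSite(list(h1 = c(90, 10), p1 = c(50, 50)),
                       gene = "g1", site = "g1_s1"),
    alleleTableOneSite(list(h1 = c(51, 49), p1 = c(50, 50)),
                       gene = "g2", site = "g2_s1"))
  tests <- siteTests(tab)
  calls <- sampleGeneASE(tests)
  prop <- aseProportion(calls)
  expect_equal(unname(prop["h1"]), 0.5)
  expect_equal(unname(prop["p1"]), 0)
  expect_error(aseProportion(calls[0, ]), "eligible")
})
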