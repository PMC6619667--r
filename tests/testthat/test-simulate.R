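test_that("simulation is deterministic given the config seed", {
  s1 <- quickSim(nGenes = 50, seed = 9)
  s2 <- quickSim(nGenes = 50, seed = 9)
  expect_identical(simCounts(s1), simCounts(s2))
  expect_identical(alleleCounts(s1), alleleCounts(s2))
  expect_identical(truthTable(s1), truthTable(s2))
  expect_identical(coverageProfiles(s1), coverageProfiles(s2))
  s3 <- quickSim(nGenes = 50, seed = 10)
  expect_false(identical(simCounts(s1), simCounts(s3)))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(architectureMix = c(conserved = 0.5, cis = 0.2,
                                             trans = 0.2, compensatory = 0.2)),
               "sum")
  expect_error(simConfig(nPerGroup = c(parent1 = 1L, parent2 = 6L,
                                       hybrid = 4L)),
               "parent")
  expect_error(simConfig(aseOverdispersionRho = 1), "rho|\\[0, 1\\)")
  expect_error(simConfig(compensatoryRatio = 0.5), "0.5")
})

test_that("all-conserved architecture gives a common mean across groups", {
  sim <- quickSim(nGenes = 500, seed = 21,
                  architectureMix = c(conserved = 1, cis = 0, trans = 0,
                                      compensatory = 0))
  tr <- truthTable(sim)
  expect_true(all(tr$architecture == "conserved"))
  expect_true(all(tr$mu_p1 == tr$mu_p2))
  expect_true(all(tr$hybrid_allelic_ratio == 0.5))
  cnt <- simCounts(sim)
  grp <- simSheet(sim)$group
  # group means agree with the generating mean within 3 SE (NB variance)
  for (g in c("parent1", "parent2", "hybrid")) {
    m <- rowMeans(cnt[, grp == g, drop = FALSE])
    n <- sum(grp == g)
    se <- sqrt((tr$mu_p1 + tr$dispersion * tr$mu_p1^2) / n)
    expect_gt(mean(abs(m - tr$mu_p1) <= 3 * se), 0.98)
  }
})

test_that("architecture contracts hold in the truth table", {
  sim <- quickSim(nGenes = 600, seed = 22,
                  architectureMix = c(conserved = 0.25, cis = 0.25,
                                      trans = 0.25, compensatory = 0.25))
  tr <- truthTable(sim)
  cis <- tr[tr$architecture == "cis", ]
  expect_equal(cis$hybrid_allelic_ratio,
               cis$mu_p1 / (cis$mu_p1 + cis$mu_p2))
  trans <- tr[tr$architecture == "trans", ]
  expect_true(all(trans$hybrid_allelic_ratio == 0.5))
  expect_true(all(trans$mu_p1 != trans$mu_p2))
  comp <- tr[tr$architecture == "compensatory", ]
  expect_true(all(comp$mu_p1 == comp$mu_p2))
  expect_true(all(comp$hybrid_allelic_ratio != 0.5))
  expect_setequal(unique(tr$gene), tr$gene)  # each gene exactly once
})

test_that("compensatory hybrids show the configured allelic fraction", {
  sim <- quickSim(nGenes = 150, seed = 23,
                  architectureMix = c(conserved = 0, cis = 0, trans = 0,
                                      compensatory = 1),
                  aseDepth = 200)
  tr <- truthTable(sim)
  ac <- alleleCounts(sim)
  hyb <- ac[grepl("^hyb", ac$sample), ]
  byGene <- tapply(hyb$count1 / (hyb$count1 + hyb$count2),
                   hyb$gene, mean)
  expect_equal(as.numeric(byGene[tr$gene]), tr$hybrid_allelic_ratio,
               tolerance = 0.05)
  # parents stay balanced
  par <- ac[!grepl("^hyb", ac$sample), ]
  expect_equal(mean(par$count1 / (par$count1 + par$count2)), 0.5,
               tolerance = 0.01)
})

test_that("simulateGeneCounts matches NB/Poisson moments", {
  set.seed(31)
  y <- simulateGeneCounts(1000, dispersion = 0, n = 10000)
  expect_equal(var(y) / mean(y), 1, tolerance = 0.05)
  y2 <- simulateGeneCounts(100, dispersion = 0.5, n = 10000)
  # NB moment identity: var = mu + alpha mu^2 = 5100
  expect_equal(var(y2), 100 + 0.5 * 100^2, tolerance = 0.1)
  expect_error(simulateGeneCounts(0), "positive")
  expect_error(simulateGeneCounts(-5), "positive")
})

test_that("simulateAlleleCounts respects the beta-binomial variance", {
  set.seed(32)
  ac <- simulateAlleleCounts(0.5, 10000, depth = rep(1000L, 10000), rho = 0)
  expect_equal(mean(ac[, "count1"] / 1000), 0.5, tolerance = 0.01)
  ac2 <- simulateAlleleCounts(0.5, 20000, depth = rep(100L, 20000), rho = 0.1)
  vb <- 100 * 0.25                     # binomial variance at depth 100
  infl <- 1 + (100 - 1) * 0.1          # 10.9
  expect_equal(var(ac2[, "count1"]) / vb, infl, tolerance = 0.06)
  expect_error(simulateAlleleCounts(1.0, 10, 100), "ratio")
  expect_error(simulateAlleleCounts(0.5, 10, 100, rho = 1), "rho")
  # totals are conserved
  expect_true(all(rowSums(ac2) == 100))
})

test_that("batch effect is a pure between-batch contrast", {
  sim <- quickSim(nGenes = 400, seed = 33)
  cnt <- simCounts(sim)
  samples <- colnames(cnt)
  oneKit <- setNames(rep("kitA", length(samples)), samples)
  expect_identical(applyBatchEffect(cnt, oneKit, sigma = 0.5, seed = 1), cnt)
  twoKit <- setNames(rep(c("kitA", "kitB"), length.out = length(samples)),
                     samples)
  expect_identical(applyBatchEffect(cnt, twoKit, sigma = 0), cnt)
  expect_error(applyBatchEffect(cnt, twoKit[-1], sigma = 0.1), "missing")

  pert <- applyBatchEffect(cnt, twoKit, sigma = 0.5, seed = 2)
  a <- names(twoKit)[twoKit == "kitA"]; b <- names(twoKit)[twoKit == "kitB"]
  keep <- rowMeans(cnt) > 100
  lr <- log(rowMeans(pert[keep, a]) + 0.5) - log(rowMeans(pert[keep, b]) + 0.5)
  lr0 <- log(rowMeans(cnt[keep, a]) + 0.5) - log(rowMeans(cnt[keep, b]) + 0.5)
  # centred factors: log-ratio of batch means gains variance ~ 2 sigma^2
  extra <- var(lr) - var(lr0)
  expect_equal(extra, 2 * 0.5^2, tolerance = 0.25)
})

test_that("degradation decays the 5' end and biases one allele", {
  prof <- rep(100, 200)
  out0 <- applyDegradation(prof, lambda = 0)
  expect_equal(out0$depth, prof)
  expect_equal(tin(out0$depth), 100)
  out <- applyDegradation(prof, lambda = 3)
  expect_lt(tin(out$depth), tin(prof))
  expect_equal(out$depth[200], 100)            # 3' end preserved
  expect_lt(out$depth[1], 100 * exp(-2.9))     # 5' end decayed
  ac <- data.frame(count1 = 100, count2 = 100)
  outA <- applyDegradation(prof, lambda = 0, alleleCounts = ac,
                           alleleBias = 0.5)
  expect_equal(outA$alleleCounts$count1, 100)
  expect_equal(outA$alleleCounts$count2, 50)
  expect_error(applyDegradation(prof, lambda = -1), "lambda")
})

test_that("hybrid totals follow the mode-implied means", {
  sim <- quickSim(nGenes = 400, seed = 34,
                  architectureMix = c(conserved = 0, cis = 0.5, trans = 0.5,
                                      compensatory = 0),
                  totalModeMix = c(additive = 1, dominant_p1 = 0,
                                   dominant_p2 = 0, overdominant = 0,
                                   underdominant = 0))
  tr <- truthTable(sim)
  expect_equal(tr$mu_hybrid, (tr$mu_p1 + tr$mu_p2) / 2)
  cnt <- simCounts(sim)
  hm <- rowMeans(cnt[, grepl("^hyb", colnames(cnt))])
  se <- sqrt((tr$mu_hybrid + tr$dispersion * tr$mu_hybrid^2) / 4)
  expect_gt(mean(abs(hm - tr$mu_hybrid) <= 3.5 * se), 0.97)
})

test_that("simulation files round-trip through the TSV writers", {
  sim <- quickSim(nGenes = 20, seed = 35, nCoverageTranscripts = 5L,
                  transcriptLength = 50L)
  dir <- tempfile("simout")
  paths <- writeSimulation(sim, dir)
  expect_true(all(file.exists(paths)))
  cnt <- readCountsTSV(file.path(dir, "counts.tsv"))
  expect_identical(cnt, simCounts(sim))
  ss <- readSampleSheet(file.path(dir, "samples.tsv"))
  expect_identical(ss$group, simSheet(sim)$group)
  ac <- readAlleleCounts(file.path(dir, "allele_counts.tsv"))
  expect_equal(nrow(ac), nrow(alleleCounts(sim)))
  cov <- readCoverageTSV(file.path(dir, "coverage.tsv"))
  expect_equal(cov[[1]][1, ], unname(coverageProfiles(sim)[[1]][1, ]))
  unlink(dir, recursive = TRUE)
})
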