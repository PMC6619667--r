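# builds the three DE tables from a compact layout: for each gene,
# (padj vs P1, lfc vs P1, padj vs P2, lfc vs P2, padj P1P2, lfc P1P2)
callsFrom <- function(m, ...) {
  g <- rownames(m)
  classifyInheritance(deTable(g, m[, 2], m[, 1]),
                      deTable(g, m[, 4], m[, 3]),
                      deTable(g, m[, 6], m[, 5]), ...)
}

test_that("the inheritance decision table follows the classification scheme", {
  m <- rbind(
    cons  = c(0.9, 0.1,  0.9, -0.1, 0.9, 0.2),   # sig vs neither
    dom1  = c(0.8, 0.1,  0.01, 1.0, 0.01, -1.5), # sig vs P2 only -> p1-like
    dom2  = c(0.01, -1.0, 0.8, 0.1, 0.01, 1.5),  # sig vs P1 only -> p2-like
    over  = c(0.01, 1.2,  0.01, 0.8, 0.9, 0.3),  # above both parents
    under = c(0.01, -1.2, 0.01, -0.8, 0.9, 0.3), # below both parents
    addv  = c(0.01, 1.0,  0.01, -1.0, 0.01, 2.0) # between parents
  )
  calls <- callsFrom(m)
  expect_equal(as.character(calls$mode),
               c("conserved", "dominant_p1", "dominant_p2",
                 "overdominant", "underdominant", "additive"))
  # every gene gets exactly one mode
  expect_false(anyNA(calls$mode))
})

test_that("additive can require parental differential expression", {
  m <- rbind(between_sig   = c(0.01, 1, 0.01, -1, 0.01, 2),
             between_nosig = c(0.01, 1, 0.01, -1, 0.50, 2))
  strict <- callsFrom(m, requireParentalDE = TRUE)
  expect_equal(as.character(strict$mode), c("additive", "ambiguous"))
  lax <- callsFrom(m, requireParentalDE = FALSE)
  expect_equal(as.character(lax$mode), c("additive", "additive"))
})

test_that("gene universes must match across the three DE tables", {
  d1 <- deTable(c("g1", "g2"), c(0, 0), c(1, 1))
  d2 <- deTable(c("g1"), 0, 1)
  expect_error(classifyInheritance(d1, d2, d1), "g2")
})

test_that("swapping parent labels swaps the dominant calls only", {
  set.seed(41)
  g <- paste0("g", 1:200)
  hp1 <- deTable(g, rnorm(200), runif(200)^2)
  hp2 <- deTable(g, rnorm(200), runif(200)^2)
  p12 <- deTable(g, rnorm(200), runif(200))
  a <- classifyInheritance(hp1, hp2, p12)
  # parent swap: H-vs-P1 and H-vs-P2 exchange; P1P2 flips sign
  b <- classifyInheritance(hp2, hp1,
                           deTable(g, -p12$log2FC, p12$padj))
  map <- c(conserved = "conserved", additive = "additive",
           dominant_p1 = "dominant_p2", dominant_p2 = "dominant_p1",
           overdominant = "overdominant", underdominant = "underdominant",
           ambiguous = "ambiguous")
  expect_equal(as.character(b$mode), unname(map[as.character(a$mode)]))
  # sign symmetry: negating hybrid contrasts swaps over/under
  c_ <- classifyInheritance(deTable(g, -hp1$log2FC, hp1$padj),
                            deTable(g, -hp2$log2FC, hp2$padj), p12)
  map2 <- c(conserved = "conserved", additive = "additive",
            dominant_p1 = "dominant_p1", dominant_p2 = "dominant_p2",
            overdominant = "underdominant", underdominant = "overdominant",
            ambiguous = "ambiguous")
  expect_equal(as.character(c_$mode), unname(map2[as.character(a$mode)]))
})

test_that("pooled-parent misregulation flags follow padj and direction", {
  de <- deTable(c("a", "b", "c"), c(1.5, -2, 0.4), c(0.01, 0.04, 0.2))
  m <- misregulatedPooled(de, fdr = 0.05)
  expect_equal(m$misregulated, c(TRUE, TRUE, FALSE))
  expect_equal(as.character(m$direction), c("up", "down", "none"))
})

test_that("summaries report percentages against the stated denominator", {
  calls <- data.frame(mode = factor(
    rep(c("conserved", "underdominant"), c(3, 1)),
    levels = levels(callsFrom(rbind(x = rep(0.5, 6)))$mode)))
  s <- summarizeInheritance(calls, 4)
  expect_equal(s$percent[s$mode == "conserved"], 75)
  expect_equal(sum(s$n), 4)
  expect_error(summarizeInheritance(calls, 0), "positive")
  # report-style arithmetic: misregulated counts over filtered genes
  expect_equal(round(proportionSummary(370, 17705)$percent, 1), 2.1)
  expect_equal(round(proportionSummary(209, 17705)$percent, 1), 1.2)
  empty <- calls[0, , drop = FALSE]
  s0 <- summarizeInheritance(empty, 100)
  expect_true(all(s0$n == 0) && all(s0$percent == 0))
})

test_that("magnitude comparison uses a two-sided rank-sum test", {
  set.seed(42)
  x <- rnorm(30, 0, 1)
  same <- magnitudeComparison(x, x)
  expect_gt(same$p.value, 0.9)
  over <- rnorm(100, 0, 0.5); under <- rnorm(100, 0, 2)
  diff <- magnitudeComparison(over, under)
  expect_lt(diff$p.value, 1e-4)
  expect_error(magnitudeComparison(numeric(0), x), "empty")
  # two singletons can never be significant: exact two-sided p is 1
  expect_equal(magnitudeComparison(1.0, 2.0)$p.value, 1)
})
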