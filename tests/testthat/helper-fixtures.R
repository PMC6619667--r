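# shared in-code fixtures; everything is generated, nothing read from disk

toySampleNames <- function(n1 = 3, n2 = 3, nh = 2) {
  c(paste0("p1_", seq_len(n1)), paste0("p2_", seq_len(n2)),
    paste0("hyb_", seq_len(nh)))
}

toySampleSheet <- function(n1 = 3, n2 = 3, nh = 2) {
  s <- toySampleNames(n1, n2, nh)
  data.frame(sample = s,
             group = rep(c("parent1", "parent2", "hybrid"), c(n1, n2, nh)),
             stage = "stage1", batch = "kitA", population = "popA",
             row.names = s, stringsAsFactors = FALSE)
}

# DE-style table for classifier tests
deTable <- function(genes, lfc, padj) {
  data.frame(gene = genes, log2FC = lfc, padj = padj,
             stringsAsFactors = FALSE)
}

# one-gene allele table across samples: counts is a list sample -> c(a1, a2)
alleleTableOneSite <- function(counts, gene = "g1", site = "g1_s1") {
  do.call(rbind, lapply(names(counts), function(s)
    data.frame(gene = gene, site_id = site, position = 101L,
               allele1 = "A", allele2 = "G", sample = s,
               count1 = counts[[s]][1], count2 = counts[[s]][2],
               stringsAsFactors = FALSE)))
}

quickSim <- function(nGenes = 200, seed = 1, ...) {
  simulateExperiment(simConfig(nGenes = nGenes, seed = seed, ...))
}

simCounts <- function(sim) SummarizedExperiment::assay(countsSE(sim), "counts")
simSheet <- function(sim) as.data.frame(SummarizedExperiment::colData(countsSE(sim)))

# independent BH step-up oracle (kept deliberately naive)
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# minimum-likelihood two-sided exact binomial oracle
binomOracle <- function(k, n) {
  d <- dbinom(0:n, n, 0.5)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}
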